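jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Match detected PCGs against planted phylo-niche clades
#'
#' Greedy one-to-one matching by descending Jaccard index between detected
#' member sets and the planted clades of one regime (ties broken towards the
#' pair whose detected group has the smaller first member label, then the
#' earlier planted clade). Recall is the fraction of planted clades whose
#' matched Jaccard reaches `tau` (`tau = 1` demands exact clade recovery);
#' precision is the fraction of detected PCGs whose best Jaccard against any
#' planted clade reaches `tau`. Scattered (non-phylo) planted sets are never
#' counted as true positives; minimal core nodes induced by them surface in
#' the unmatched list. An empty detected set gives recall 0 and, by
#' convention, precision 1 with the `zero_detected` flag.
#'
#' @param detected a `pcg_set` from [find_pcgs()].
#' @param truth a `pcg_truth` (from [simulate_dataset()] or [read_truth()]).
#' @param regime regime id present in `truth` (default the first).
#' @param tau Jaccard threshold in `(0, 1]`, default 1 (exact).
#' @return object of class `recovery_report`: `per_clade` data frame
#'   (`clade_id`, `size`, `best_pcg`, `jaccard`), `n_exact`, `recall`
#'   (at `tau`), `recall_exact`, `precision`, `tau`, `zero_detected`,
#'   `unmatched_detected` data frame (`pcg_id`, `n_taxa`, `best_jaccard`).
#' @export
match_pcgs <- function(detected, truth, regime = NULL, tau = 1.0) {
  stopifnot(inherits(detected, "pcg_set"), inherits(truth, "pcg_truth"))
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  if (is.null(regime)) regime <- names(truth$regimes)[1L]
  if (!regime %in% names(truth$regimes))
    stop("unknown regime '", regime, "'; available: ",
         paste(names(truth$regimes), collapse = ", "), call. = FALSE)
  niches <- truth$regimes[[regime]]$niches
  planted <- Filter(function(nn) identical(nn$kind, "phylo"), niches)
  k_phylo <- length(planted)
  psets <- lapply(planted, function(nn) unlist(nn$taxa))
  dsets <- lapply(detected$pcgs, `[[`, "member_taxa")
  dids <- vapply(detected$pcgs, `[[`, character(1), "pcg_id")
  nd <- length(dsets)
  per_clade <- data.frame(
    clade_id = if (k_phylo) sprintf("clade_%d", seq_len(k_phylo))
               else character(0),
    size = vapply(psets, length, integer(1)),
    best_pcg = rep(NA_character_, k_phylo),
    jaccard = rep(0, k_phylo),
    stringsAsFactors = FALSE)
  best_j_det <- rep(0, nd)
  if (nd > 0 && k_phylo > 0) {
    J <- matrix(0, nd, k_phylo)
    for (i in seq_len(nd)) for (j in seq_len(k_phylo))
      J[i, j] <- jaccard(dsets[[i]], psets[[j]])
    best_j_det <- apply(J, 1L, max)
    first_lab <- vapply(dsets, `[[`, character(1), 1L)
    Jw <- J
    while (any(Jw > 0)) {
      mx <- max(Jw)
      cand <- which(Jw == mx, arr.ind = TRUE)
      ord <- order(first_lab[cand[, 1L]], cand[, 2L], method = "radix")
      pickr <- cand[ord[1L], 1L]; pickc <- cand[ord[1L], 2L]
      per_clade$best_pcg[pickc] <- dids[pickr]
      per_clade$jaccard[pickc] <- J[pickr, pickc]
      Jw[pickr, ] <- 0; Jw[, pickc] <- 0
    }
  }
  n_exact <- sum(per_clade$jaccard >= 1 - 1e-12)
  recall <- if (k_phylo) sum(per_clade$jaccard >= tau - 1e-12) / k_phylo
            else NA_real_
  zero_detected <- nd == 0L
  precision <- if (zero_detected) 1.0 else mean(best_j_det >= tau - 1e-12)
  matched_ids <- per_clade$best_pcg[per_clade$jaccard >= tau - 1e-12]
  unmatched <- setdiff(dids, matched_ids)
  unmatched_df <- data.frame(
    pcg_id = unmatched,
    n_taxa = vapply(dsets[match(unmatched, dids)], length, integer(1)),
    best_jaccard = best_j_det[match(unmatched, dids)],
    stringsAsFactors = FALSE)
  structure(list(regime = regime, per_clade = per_clade, n_exact = n_exact,
                 recall = recall, recall_exact = if (k_phylo)
                   n_exact / k_phylo else NA_real_,
                 precision = precision, tau = tau,
                 zero_detected = zero_detected,
                 unmatched_detected = unmatched_df),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery_report [%s]: recall(tau=%g) %.3f, exact recall %.3f, precision %.3f%s\n",
    x$regime, x$tau, x$recall, x$recall_exact, x$precision,
    if (x$zero_detected) " (zero detected)" else ""))
  print(x$per_clade)
  invisible(x)
}

#' Planted clades exclusive to one regime
#'
#' Returns the indices (within the regime's phylo niches) of planted clades
#' whose taxa appear in no eligible set — phylo or non-phylo — of any other
#' regime. Under `prevalence = 1` detection on a pooled multi-regime dataset
#' such clades can never be recovered (their counts are exactly zero in
#' other-regime samples), while per-regime detection can recover them.
#'
#' @param truth a `pcg_truth`.
#' @param regime regime id.
#' @return integer indices into the regime's phylo-niche list.
#' @export
regime_specific_clades <- function(truth, regime) {
  stopifnot(inherits(truth, "pcg_truth"))
  if (!regime %in% names(truth$regimes))
    stop("unknown regime '", regime, "'", call. = FALSE)
  other <- setdiff(names(truth$regimes), regime)
  other_taxa <- unique(unlist(lapply(other, function(r)
    lapply(truth$regimes[[r]]$niches, function(nn) unlist(nn$taxa)))))
  phylo <- Filter(function(nn) identical(nn$kind, "phylo"),
                  truth$regimes[[regime]]$niches)
  which(vapply(phylo, function(nn)
    length(intersect(unlist(nn$taxa), other_taxa)) == 0L, logical(1)))
}

#' End-to-end simulate–detect–evaluate experiment grid
#'
#' For every grid cell and replicate: simulate a dataset, run [find_pcgs()]
#' on each regime's samples separately, and score recovery with
#' [match_pcgs()]. The grid typically varies the number of samples, exposing
#' the claim that enough samples are needed to capture within-niche
#' occupancy stochasticity as a measurable recall-versus-S curve.
#'
#' @param grid data frame; columns must be [sim_config()] field names
#'   (e.g. `n_samples`), one row per cell.
#' @param n_reps replicates per cell (>= 1).
#' @param master_seed integer; replicate seeds derive deterministically.
#' @param base_config `sim_config` supplying all non-gridded fields.
#' @param params [presence_params()] used for detection.
#' @param tau Jaccard threshold for recall/precision.
#' @return object of class `recovery_experiment`: `results` (one row per
#'   cell x replicate x regime) and `summary` (mean/sd of recall and
#'   precision per cell).
#' @export
recovery_experiment <- function(grid, n_reps, master_seed,
                                base_config = sim_config(),
                                params = presence_params(), tau = 1.0) {
  if (missing(n_reps) || length(n_reps) != 1L || n_reps < 1)
    stop("n_reps must be a positive integer", call. = FALSE)
  grid <- as.data.frame(grid)
  if (nrow(grid) < 1L) stop("empty grid", call. = FALSE)
  unknown <- setdiff(names(grid), names(formals(sim_config)))
  if (length(unknown))
    stop("grid column(s) not sim_config fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    over <- as.list(grid[cell, , drop = FALSE])
    for (rep in seq_len(n_reps)) {
      cfg_args <- modifyList(unclass(base_config), over)
      cfg_args$seed <- child_seed(master_seed, 10L + cell, rep)
      cfg_args$tree_model <- base_config$tree_model
      cfg <- do.call(sim_config, cfg_args)
      sim <- simulate_dataset(cfg)
      for (rg in names(sim$truth$regimes)) {
        idx <- names(sim$truth$sample_regime)[
          sim$truth$sample_regime == rg]
        if (length(idx) == 0L) next
        det <- find_pcgs(sim$tree, sim$table[idx, , drop = FALSE], params)
        rep_row <- match_pcgs(det, sim$truth, regime = rg, tau = tau)
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cell, over, rep = rep, regime = rg,
          n_regime_samples = length(idx),
          n_detected = length(det$pcgs),
          recall = rep_row$recall, recall_exact = rep_row$recall_exact,
          precision = rep_row$precision,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(
    results[, c("recall", "recall_exact", "precision")],
    by = results[, c("cell", names(grid)), drop = FALSE],
    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  structure(list(results = results, summary = agg, tau = tau,
                 n_reps = n_reps),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("recovery_experiment: %d result row(s), tau=%g\n",
              nrow(x$results), x$tau))
  print(x$summary)
  invisible(x)
}
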