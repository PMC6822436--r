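#' Presence thresholds for core-group detection
#'
#' A clade counts as present in a sample when its pooled read count is at
#' least `min_count` and its pooled relative abundance is at least
#' `min_relabund`; it is core when it is present in at least
#' `ceiling(prevalence * S)` of the `S` samples. The defaults encode the
#' strict reading of a core group — presence (>= 1 read) in every sample —
#' while `min_relabund` offers sequencing-depth-robust detection and
#' `prevalence < 1` admits ecosystems with known exceptions.
#'
#' At least one of `min_count >= 1` or `min_relabund > 0` must hold,
#' otherwise a clade with zero signal would count as present.
#'
#' @param min_count non-negative integer, reads.
#' @param min_relabund real in `[0, 1)`.
#' @param prevalence real in `(0, 1]`, fraction of samples.
#' @return object of class `presence_params`.
#' @export
presence_params <- function(min_count = 1L, min_relabund = 0,
                            prevalence = 1.0) {
  if (length(min_count) != 1L || min_count < 0 ||
      abs(min_count - round(min_count)) > 0)
    stop("min_count must be a non-negative integer", call. = FALSE)
  if (length(min_relabund) != 1L || min_relabund < 0 || min_relabund >= 1)
    stop("min_relabund must lie in [0, 1)", call. = FALSE)
  if (length(prevalence) != 1L || prevalence <= 0 || prevalence > 1)
    stop("prevalence must lie in (0, 1]", call. = FALSE)
  if (min_count < 1 && min_relabund <= 0)
    stop("need min_count >= 1 or min_relabund > 0: a clade with zero pooled ",
         "signal can never be 'present'", call. = FALSE)
  structure(list(min_count = as.integer(min_count),
                 min_relabund = as.numeric(min_relabund),
                 prevalence = as.numeric(prevalence)),
            class = "presence_params")
}

#' @export
print.presence_params <- function(x, ...) {
  cat(sprintf(
    "presence_params: min_count=%d, min_relabund=%g, prevalence=%g\n",
    x$min_count, x$min_relabund, x$prevalence))
  invisible(x)
}

# Drop (or reject) samples with zero total reads before detection.
handle_empty_samples <- function(table, allow_empty_samples) {
  tot <- rowSums(table)
  if (any(tot == 0)) {
    bad <- rownames(table)[tot == 0]
    if (!allow_empty_samples)
      stop("sample(s) with zero total reads: ",
           paste(head(bad, 10L), collapse = ", "),
           " (use allow_empty_samples to drop them)", call. = FALSE)
    log_msg("WARN", "dropping ", length(bad),
            " empty sample(s): ", paste(head(bad, 10L), collapse = ", "))
    table <- table[tot > 0, , drop = FALSE]
    if (nrow(table) == 0L)
      stop("all samples are empty", call. = FALSE)
  }
  table
}

#' Per-taxon presence/absence matrix
#'
#' @param table samples x taxa count matrix; every sample total must be
#'   positive (empty samples are handled upstream).
#' @param params a [presence_params()] object.
#' @return logical samples x taxa matrix; entry (s, t) is `TRUE` iff
#'   `counts[s, t] >= min_count` and
#'   `counts[s, t] / total(s) >= min_relabund`.
#' @export
presence_matrix <- function(table, params = presence_params()) {
  table <- abundance_table(table)
  stopifnot(inherits(params, "presence_params"))
  tot <- rowSums(table)
  if (any(tot == 0))
    stop("sample(s) with zero total reads reached presence_matrix",
         call. = FALSE)
  table >= params$min_count & table / tot >= params$min_relabund
}

# Pooled clade counts for every tree node: samples x (Ntip + Nnode) matrix,
# column k = summed counts of the tips under node k. One postorder pass.
pooled_clade_counts <- function(tree, table) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  P <- matrix(0, nrow(table), n)
  P[, seq_len(ntip)] <- table[, tree$tip.label, drop = FALSE]
  ed <- postorder_edges(tree)
  for (i in seq_len(nrow(ed)))
    P[, ed[i, 1L]] <- P[, ed[i, 1L]] + P[, ed[i, 2L]]
  rownames(P) <- rownames(table)
  P
}

check_aligned <- function(tree, table) {
  if (!identical(tree$tip.label, colnames(table)))
    stop("tree and table are not aligned; run align_tree_and_table() first",
         call. = FALSE)
}

#' Core nodes of a phylogeny given a community table
#'
#' A node is core when the pooled counts of its leaf set pass the presence
#' thresholds in at least `ceiling(prevalence * S)` samples. Pooling precedes
#' thresholding, so coreness is monotone rootward: every ancestor of a core
#' node is core.
#'
#' @inheritParams presence_matrix
#' @param tree [ape::phylo] tree aligned to `table`
#'   (see [align_tree_and_table()]).
#' @return integer vector of core node numbers (ape numbering), with
#'   attributes `n_present` (per-node sample tally) and `needed` (the
#'   prevalence threshold in samples).
#' @export
core_nodes <- function(tree, table, params = presence_params()) {
  table <- abundance_table(table)
  check_aligned(tree, table)
  stopifnot(inherits(params, "presence_params"))
  tot <- rowSums(table)
  if (any(tot == 0))
    stop("sample(s) with zero total reads: drop them or pass ",
         "allow_empty_samples to find_pcgs()", call. = FALSE)
  S <- nrow(table)
  P <- pooled_clade_counts(tree, table)
  pres <- P >= params$min_count & P / tot >= params$min_relabund
  n_present <- colSums(pres)
  needed <- as.integer(ceiling(params$prevalence * S - 1e-9))
  core <- which(n_present >= needed)
  structure(core, n_present = n_present, needed = needed)
}

#' Find phylogenetic core groups (PCGs)
#'
#' Identifies PCGs as the minimal portions of the phylogeny present across
#' the samples of a community table: the core nodes (see [core_nodes()])
#' none of whose proper descendants is core. Because clade leaf sets are
#' nested or disjoint and coreness is monotone rootward, the reported groups
#' are pairwise disjoint and cover each core lineage at its finest
#' core-supported resolution. Runs in one postorder pass over the tree.
#'
#' @inheritParams core_nodes
#' @param allow_empty_samples drop zero-total samples with a warning instead
#'   of raising an error. Retaining them is impossible: an empty sample can
#'   never show presence, so any `prevalence = 1` search would be vacuously
#'   empty.
#' @return object of class `pcg_set`: list with `pcgs` (one record per PCG:
#'   `pcg_id`, `node`, `member_taxa`, `depth`, `prevalence`,
#'   `pooled_relabund`), the detection `params`, `n_samples`, and
#'   `taxon_ids`. PCGs are ordered by their lexicographically first member
#'   taxon.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' tab <- matrix(c(5,0,2, 0,3,0, 2,1,0, 0,0,4), nrow = 3,
#'               dimnames = list(c("s1","s2","s3"), c("A","B","C","D")))
#' find_pcgs(tr, tab)
#' @export
find_pcgs <- function(tree, table, params = presence_params(),
                      allow_empty_samples = FALSE) {
  table <- abundance_table(table)
  check_aligned(tree, table)
  table <- handle_empty_samples(table, allow_empty_samples)
  S <- nrow(table)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  cn <- core_nodes(tree, table, params)
  core <- logical(nn); core[cn] <- TRUE
  children <- node_children(tree)
  # structural guarantees, asserted on every run
  for (k in seq_len(nn)) for (ch in children[[k]])
    if (core[ch] && !core[k])
      stop("internal error: coreness monotonicity violated", call. = FALSE)
  minimal <- which(core & !vapply(children, function(ch) any(core[ch]),
                                  logical(1)))
  tips <- clade_tips(tree)
  h <- node_heights(tree)
  tot <- rowSums(table)
  P <- pooled_clade_counts(tree, table)
  n_present <- attr(cn, "n_present")
  recs <- lapply(minimal, function(nd) {
    members <- sort_ids(tree$tip.label[tips[[nd]]])
    list(node = nd,
         member_taxa = members,
         depth = unname(h[nd]),
         prevalence = unname(n_present[nd]) / S,
         pooled_relabund = setNames(P[, nd] / tot, rownames(table)))
  })
  ord <- order(vapply(recs, function(r) r$member_taxa[1L], character(1)),
               method = "radix")
  recs <- recs[ord]
  for (i in seq_along(recs)) recs[[i]]$pcg_id <- sprintf("pcg_%d", i)
  # disjointness assertion
  all_members <- unlist(lapply(recs, `[[`, "member_taxa"))
  if (anyDuplicated(all_members))
    stop("internal error: PCG member sets overlap", call. = FALSE)
  structure(list(pcgs = recs, params = params, n_samples = S,
                 taxon_ids = colnames(table), sample_ids = rownames(table)),
            class = "pcg_set")
}

#' @export
print.pcg_set <- function(x, ...) {
  cat(sprintf("pcg_set: %d PCG(s) across %d sample(s), %d taxa\n",
              length(x$pcgs), x$n_samples, length(x$taxon_ids)))
  for (p in x$pcgs)
    cat(sprintf("  %s: %d taxa, depth %.4g, prevalence %.3g [%s%s]\n",
                p$pcg_id, length(p$member_taxa), p$depth, p$prevalence,
                paste(head(p$member_taxa, 4L), collapse = ","),
                if (length(p$member_taxa) > 4L) ",..." else ""))
  invisible(x)
}

#' Summarize a set of detected PCGs
#'
#' @param pcgs a `pcg_set` from [find_pcgs()].
#' @param table the samples x taxa table the set was detected on.
#' @param tree the aligned tree.
#' @return object of class `pcg_summary`: `per_pcg` data frame (`pcg_id`,
#'   `n_taxa`, `depth`, `prevalence`, `mean_pooled_relabund`), a
#'   `pooled_relabund` PCG x sample matrix, a `dominants` PCG x sample
#'   character matrix (per-sample argmax member, ties to the
#'   lexicographically smallest label), per-sample `coverage` (fraction of
#'   reads under the union of all PCGs) and its mean.
#' @export
pcg_summary <- function(pcgs, table, tree) {
  stopifnot(inherits(pcgs, "pcg_set"))
  table <- abundance_table(table)
  table <- table[pcgs$sample_ids, , drop = FALSE]
  tot <- rowSums(table)
  k <- length(pcgs$pcgs)
  ids <- vapply(pcgs$pcgs, `[[`, character(1), "pcg_id")
  per_pcg <- data.frame(
    pcg_id = ids,
    n_taxa = vapply(pcgs$pcgs, function(p) length(p$member_taxa), integer(1)),
    depth = vapply(pcgs$pcgs, `[[`, numeric(1), "depth"),
    prevalence = vapply(pcgs$pcgs, `[[`, numeric(1), "prevalence"),
    mean_pooled_relabund = vapply(pcgs$pcgs,
                                  function(p) mean(p$pooled_relabund),
                                  numeric(1)),
    stringsAsFactors = FALSE)
  relab <- matrix(0, k, nrow(table),
                  dimnames = list(ids, rownames(table)))
  dom <- matrix(NA_character_, k, nrow(table),
                dimnames = list(ids, rownames(table)))
  for (i in seq_len(k)) {
    p <- pcgs$pcgs[[i]]
    relab[i, ] <- p$pooled_relabund[rownames(table)]
    sub <- table[, p$member_taxa, drop = FALSE]  # member columns sorted
    dom[i, ] <- p$member_taxa[apply(sub, 1L, which.max)]
  }
  union_taxa <- unlist(lapply(pcgs$pcgs, `[[`, "member_taxa"))
  coverage <- if (length(union_taxa))
    rowSums(table[, union_taxa, drop = FALSE]) / tot else setNames(
      rep(0, nrow(table)), rownames(table))
  structure(list(per_pcg = per_pcg, pooled_relabund = relab,
                 dominants = dom, coverage = coverage,
                 mean_coverage = mean(coverage),
                 taxon_ids = pcgs$taxon_ids),
            class = "pcg_summary")
}

#' @export
print.pcg_summary <- function(x, ...) {
  cat(sprintf("pcg_summary: %d PCG(s), mean community coverage %.4g\n",
              nrow(x$per_pcg), x$mean_coverage))
  print(x$per_pcg)
  invisible(x)
}
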