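#' Standardized effect size of mean pairwise phylogenetic distance (SES-MPD)
#'
#' For each sample, the observed mean pairwise patristic distance among its
#' present taxa (count > 0) is compared against a null obtained by shuffling
#' taxon labels on the patristic distance matrix (all taxa in the tree form
#' the shuffle pool, so per-sample richness is preserved by construction).
#' `SES = (observed - null_mean) / null_sd`; negative values indicate
#' phylogenetic clustering, positive values overdispersion.
#'
#' Samples with fewer than two present taxa are flagged `undefined` rather
#' than raising an error; samples whose null has zero spread (e.g. all taxa
#' present, so every shuffle is the identity on the pair set) get `SES = 0`
#' and the `degenerate` flag.
#'
#' @param table samples x taxa count matrix, aligned to `tree`.
#' @param tree [ape::phylo] tree with branch lengths.
#' @param permutations number of label shuffles (default 999).
#' @param weighted if `TRUE`, pairs are weighted by the product of the two
#'   taxa's relative abundances in the sample.
#' @param seed integer seed; results are bit-reproducible for a fixed seed.
#' @return data frame of class `ses_mpd` with one row per sample:
#'   `sample_id`, `ntaxa`, `mpd_obs`, `null_mean`, `null_sd`, `ses`,
#'   `degenerate`, `undefined`.
#' @export
ses_mpd <- function(table, tree, permutations = 999L, weighted = FALSE,
                    seed) {
  table <- abundance_table(table)
  check_aligned(tree, table)
  if (length(permutations) != 1L || permutations < 1)
    stop("permutations must be a positive integer", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducibility",
                          call. = FALSE)
  set.seed(seed)
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  n_all <- ncol(D)
  S <- nrow(table)
  out <- data.frame(sample_id = rownames(table), ntaxa = 0L,
                    mpd_obs = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, ses = NA_real_,
                    degenerate = FALSE, undefined = FALSE,
                    stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    present <- which(table[s, ] > 0)
    k <- length(present)
    out$ntaxa[s] <- k
    if (k < 2L) { out$undefined[s] <- TRUE; next }
    if (weighted) {
      w <- table[s, present] / sum(table[s, present])
      W <- outer(w, w); diag(W) <- 0
      sw <- sum(W)
      mpd_of <- function(idx) sum(D[idx, idx] * W) / sw
    } else {
      denom <- k * (k - 1)
      mpd_of <- function(idx) sum(D[idx, idx]) / denom
    }
    obs <- mpd_of(present)
    nulls <- vapply(seq_len(permutations),
                    function(b) mpd_of(sample.int(n_all, k)),
                    numeric(1))
    mu <- mean(nulls); sdev <- sd(nulls)
    out$mpd_obs[s] <- obs
    out$null_mean[s] <- mu
    out$null_sd[s] <- sdev
    if (is.na(sdev) || sdev == 0) {
      out$ses[s] <- 0; out$degenerate[s] <- TRUE
    } else out$ses[s] <- (obs - mu) / sdev
  }
  attr(out, "permutations") <- as.integer(permutations)
  attr(out, "seed") <- seed
  attr(out, "weighted") <- weighted
  class(out) <- c("ses_mpd", "data.frame")
  out
}

#' Intra-PCG occupant turnover across samples
#'
#' Within each PCG the per-sample dominant member is the member taxon with
#' the highest count (ties resolved to the lexicographically smallest label).
#' Turnover is `1 - f_mode`, where `f_mode` is the frequency of the most
#' common dominant across the samples in which the PCG has nonzero pooled
#' counts. High turnover is the signature of neutral (lottery-like) occupancy
#' of a niche by alternative members; turnover 0 means a single member
#' dominates everywhere.
#'
#' @param pcgs a `pcg_set` from [find_pcgs()].
#' @param table the samples x taxa table the set was detected on.
#' @return data frame of class `pcg_turnover`, one row per PCG: `pcg_id`,
#'   `S_effective` (samples with nonzero pooled counts), `f_mode`,
#'   `turnover`, `dominants` (semicolon-joined per-sample dominants).
#' @export
pcg_turnover <- function(pcgs, table) {
  stopifnot(inherits(pcgs, "pcg_set"))
  if (length(pcgs$pcgs) == 0L)
    stop("pcg set is empty", call. = FALSE)
  table <- abundance_table(table)
  table <- table[pcgs$sample_ids, , drop = FALSE]
  rows <- lapply(pcgs$pcgs, function(p) {
    sub <- table[, p$member_taxa, drop = FALSE]
    pooled <- rowSums(sub)
    eff <- which(pooled > 0)
    if (length(eff) == 0L)
      stop("PCG ", p$pcg_id, " has zero pooled counts in every sample",
           call. = FALSE)
    dom <- p$member_taxa[apply(sub[eff, , drop = FALSE], 1L, which.max)]
    f_mode <- max(base::table(dom)) / length(eff)
    data.frame(pcg_id = p$pcg_id, S_effective = length(eff),
               f_mode = f_mode, turnover = 1 - f_mode,
               dominants = paste(dom, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pcg_turnover", "data.frame")
  out
}
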