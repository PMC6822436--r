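# Independent oracles and fixture generators shared across test files.
# Everything here is deliberately written by a different route than the
# package internals (ancestor walks instead of postorder accumulation,
# exhaustive enumeration instead of Monte-Carlo, naive re-averaging instead
# of linkage updates).

# Leaf sets of every node computed by walking each tip up to the root.
oracle_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  parent <- rep(NA_integer_, n)
  for (i in seq_len(nrow(tree$edge)))
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  lapply(seq_len(n), function(nd) {
    Filter(function(tp) {
      x <- tp
      repeat {
        if (x == nd) return(TRUE)
        x <- parent[x]
        if (is.na(x)) return(FALSE)
      }
    }, seq_len(ntip))
  })
}

# Brute-force PCG detection: test the core criterion on every clade
# independently; keep clades with no core proper descendant. Returns a list
# of sorted member-label sets, ordered by first label.
oracle_find_pcgs <- function(tree, tab, params) {
  clades <- oracle_clades(tree)
  S <- nrow(tab)
  tot <- rowSums(tab)
  needed <- ceiling(params$prevalence * S - 1e-9)
  is_core <- vapply(clades, function(m) {
    pooled <- rowSums(tab[, tree$tip.label[unlist(m)], drop = FALSE])
    sum(pooled >= params$min_count &
          pooled / tot >= params$min_relabund) >= needed
  }, logical(1))
  core_sets <- lapply(clades[is_core], unlist)
  minimal <- Filter(function(m) {
    !any(vapply(core_sets, function(o)
      length(o) < length(m) && all(o %in% m), logical(1)))
  }, core_sets)
  sets <- lapply(minimal, function(m)
    sort(tree$tip.label[m], method = "radix"))
  sets[order(vapply(sets, `[[`, character(1), 1L), method = "radix")]
}

pcg_member_sets <- function(pcgs) lapply(pcgs$pcgs, `[[`, "member_taxa")

# Random detection instance: bifurcating tree (<=12 taxa), sparse counts
# (<=8 samples, every sample nonempty), randomized presence parameters.
random_instance <- function(seed, force_defaults = FALSE) {
  set.seed(seed)
  nt <- sample(2:12, 1L)
  S <- sample(1:8, 1L)
  tree <- ape::rtree(nt)
  tab <- matrix(rbinom(S * nt, size = 30L, prob = 0.1) *
                  rbinom(S * nt, 1L, 0.6),
                S, nt,
                dimnames = list(paste0("s", seq_len(S)), tree$tip.label))
  empty <- rowSums(tab) == 0
  if (any(empty)) tab[empty, sample.int(nt, 1L)] <- 1L
  params <- if (force_defaults) presence_params() else
    presence_params(min_count = sample(1:3, 1L),
                    min_relabund = sample(c(0, 0.01, 0.05), 1L),
                    prevalence = sample(c(0.5, 0.75, 1), 1L))
  list(tree = tree, tab = abundance_table(tab), params = params)
}

# Exhaustive label-shuffle null for unweighted MPD: enumerate all k-subsets.
oracle_mpd_null <- function(D, k) {
  n <- ncol(D)
  subs <- combn(n, k)
  mpds <- apply(subs, 2L, function(idx) sum(D[idx, idx]) / (k * (k - 1)))
  c(mean = mean(mpds), sd = sqrt(mean((mpds - mean(mpds))^2)))
}

# Brute-force threshold agglomeration: merge the closest pair of clusters
# (linkage recomputed from the ORIGINAL distances each time) while the
# minimum linkage distance is <= t. Returns membership vector.
oracle_flat_clusters <- function(d, t, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1L) break
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      lk <- if (linkage == "average") mean(dd) else max(dd)
      if (lk < best) { best <- lk; bi <- i; bj <- j }
    }
    if (best > t + 1e-12) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters <- clusters[-bj]
  }
  memb <- integer(n)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  setNames(memb, rownames(d))
}

# Same partition up to cluster relabelling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Hand-built niche map for unit tests that need exact weights.
manual_niche_map <- function(tip_labels, niches, regime_id = "regime_1") {
  structure(list(niches = niches, regime_id = regime_id,
                 tip_labels = tip_labels),
            class = "niche_map")
}

# Hand-built pcg_set wrapping given member sets (used to probe statistics of
# planted groups independently of detection).
manual_pcg_set <- function(member_sets, sample_ids, taxon_ids) {
  recs <- lapply(seq_along(member_sets), function(i)
    list(pcg_id = sprintf("pcg_%d", i),
         member_taxa = sort(member_sets[[i]], method = "radix"),
         depth = NA_real_, prevalence = NA_real_,
         pooled_relabund = NULL))
  structure(list(pcgs = recs, params = presence_params(),
                 n_samples = length(sample_ids),
                 taxon_ids = taxon_ids, sample_ids = sample_ids),
            class = "pcg_set")
}
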