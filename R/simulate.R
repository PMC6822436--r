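#' Configuration for the phylogenetically constrained assembly simulator
#'
#' The generative model plants niches on a simulated phylogeny and assembles
#' each sample by pooling several local communities (patches):
#' phylo-niches are bound to clades (their eligible occupants are exactly one
#' node's leaf set), non-phylo-niches to scattered taxon sets; within a patch
#' each niche is occupied neutrally — a single uniform-random winner
#' (`winner_take_all`) or a small Dirichlet-weighted guild
#' (`guild_lottery`) — and receives the niche's weight; patch compositions
#' are pooled with Dirichlet weights (higher-scale sampling) and sequenced
#' as a multinomial draw of `depth` reads. Alternative microbial regimes are
#' modeled as independently planted niche maps on the same tree.
#'
#' Defaults describe a benchmark ecosystem of 64 taxa carrying 4 clade-bound
#' niches of 4–8 leaves and 2 scattered niches, every niche holding at least
#' 10% of the community, 30 samples of 3 patches each at 10,000 reads.
#'
#' @param n_taxa number of tree leaves (>= 2).
#' @param tree_model only `"yule"` (pure-birth) is implemented.
#' @param k_phylo number of clade-bound (phylo) niches.
#' @param k_nonphylo number of scattered (non-phylo) niches.
#' @param clade_size_range integer `[min, max]` for clade leaf counts and
#'   scattered-set sizes.
#' @param max_clade_height phylo-niche clades must have node height at most
#'   this value (the tree has root height 1, so e.g. 0.35 restricts niches
#'   to phylogenetically tight clades); `Inf` (default) disables.
#' @param niche_weight_alpha symmetric Dirichlet concentration for niche
#'   weights.
#' @param min_niche_weight niche weights are redrawn (rejection) until all
#'   are at least this value; 0 disables.
#' @param occupancy_model `"winner_take_all"` or `"guild_lottery"`.
#' @param guild_size occupants per niche under `guild_lottery`.
#' @param lottery_alpha symmetric Dirichlet concentration for guild shares.
#' @param n_samples number of samples S.
#' @param patches_per_sample patches pooled into each sample (P).
#' @param patch_pool_alpha symmetric Dirichlet concentration for patch
#'   pooling weights.
#' @param depth reads per sample (multinomial size).
#' @param n_regimes number of alternative regimes (independent niche maps).
#' @param regime_mix per-regime sample probabilities (sums to 1); default
#'   uniform.
#' @param seed master seed; all child seeds derive deterministically from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 64L, tree_model = "yule",
                       k_phylo = 4L, k_nonphylo = 2L,
                       clade_size_range = c(4L, 8L),
                       max_clade_height = Inf,
                       niche_weight_alpha = 1, min_niche_weight = 0.10,
                       occupancy_model = c("winner_take_all",
                                           "guild_lottery"),
                       guild_size = 3L, lottery_alpha = 1,
                       n_samples = 30L, patches_per_sample = 3L,
                       patch_pool_alpha = 1, depth = 10000L,
                       n_regimes = 1L, regime_mix = NULL, seed = 1L) {
  occupancy_model <- match.arg(occupancy_model)
  tree_model <- match.arg(tree_model, "yule")
  stopifnot(n_taxa >= 2, k_phylo >= 0, k_nonphylo >= 0,
            length(clade_size_range) == 2L,
            clade_size_range[1] >= 1,
            clade_size_range[1] <= clade_size_range[2],
            max_clade_height > 0,
            guild_size >= 1, lottery_alpha > 0, niche_weight_alpha > 0,
            min_niche_weight >= 0, min_niche_weight < 1,
            n_samples >= 1, patches_per_sample >= 1, patch_pool_alpha > 0,
            depth >= 1, n_regimes >= 1)
  if (k_phylo + k_nonphylo < 1)
    stop("need at least one niche", call. = FALSE)
  if (clade_size_range[2] > n_taxa)
    stop("clade_size_range exceeds n_taxa", call. = FALSE)
  if (is.null(regime_mix)) regime_mix <- rep(1 / n_regimes, n_regimes)
  if (length(regime_mix) != n_regimes)
    stop("regime_mix must have one entry per regime", call. = FALSE)
  if (abs(sum(regime_mix) - 1) > 1e-9)
    stop("regime_mix must sum to 1 (got ", sum(regime_mix), ")",
         call. = FALSE)
  if (min_niche_weight * (k_phylo + k_nonphylo) >= 1)
    stop("min_niche_weight infeasible for ", k_phylo + k_nonphylo, " niches",
         call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa), tree_model = tree_model,
                 k_phylo = as.integer(k_phylo),
                 k_nonphylo = as.integer(k_nonphylo),
                 clade_size_range = as.integer(clade_size_range),
                 max_clade_height = as.numeric(max_clade_height),
                 niche_weight_alpha = niche_weight_alpha,
                 min_niche_weight = min_niche_weight,
                 occupancy_model = occupancy_model,
                 guild_size = as.integer(guild_size),
                 lottery_alpha = lottery_alpha,
                 n_samples = as.integer(n_samples),
                 patches_per_sample = as.integer(patches_per_sample),
                 patch_pool_alpha = patch_pool_alpha,
                 depth = as.integer(depth),
                 n_regimes = as.integer(n_regimes),
                 regime_mix = as.numeric(regime_mix),
                 seed = as.numeric(seed)),
            class = "sim_config")
}

#' Read a simulator configuration from YAML or JSON
#'
#' The file's keys mirror [sim_config()] arguments field-for-field; absent
#' keys take the defaults.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Rooted bifurcating tree with `n_taxa` leaves labelled `t0001`, `t0002`,
#' ..., branch lengths rescaled so the root height is exactly 1.0.
#' Deterministic for a fixed seed.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(node_heights(tr))
  tr$tip.label <- sprintf("t%04d", seq_len(n_taxa))
  tr
}

#' Plant niches on a phylogeny
#'
#' Chooses `k_phylo` pairwise-disjoint internal clades with leaf counts in
#' `clade_size_range` uniformly at random (rejection sampling, at most
#' 10,000 attempts), then draws `k_nonphylo` scattered eligible sets from
#' the taxa outside all phylo clades (sizes uniform in the same range,
#' sets mutually disjoint so planted truth is unambiguous). Niche weights
#' are a symmetric Dirichlet draw, redrawn until all weights reach
#' `min_niche_weight`, and assigned in niche index order (phylo niches
#' first).
#'
#' @param tree an [ape::phylo] tree.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param regime_id label stored on the map.
#' @return object of class `niche_map`: list with `niches` (each with
#'   `kind`, `taxa`, `weight`, `occupancy_model`, and for phylo niches the
#'   tree `node`), plus `regime_id`.
#' @export
plant_niches <- function(tree, config, seed, regime_id = "regime_1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  rng <- config$clade_size_range
  tips <- clade_tips(tree)
  k <- config$k_phylo + config$k_nonphylo
  phylo_nodes <- integer(0)
  if (config$k_phylo > 0) {
    sz <- vapply(tips, length, integer(1))
    h <- node_heights(tree)
    cand <- which(sz >= rng[1] & sz <= rng[2] & h <= config$max_clade_height)
    cand <- cand[cand > ntip | rng[1] == 1]  # leaves admissible only if min=1
    if (length(cand) < config$k_phylo)
      stop("infeasible: only ", length(cand), " clades of size ",
           rng[1], "-", rng[2],
           if (is.finite(config$max_clade_height))
             paste0(" and height <= ", config$max_clade_height) else "",
           " exist for k_phylo=", config$k_phylo, call. = FALSE)
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      pick <- cand[sample.int(length(cand), config$k_phylo)]
      memb <- unlist(tips[pick])
      if (!anyDuplicated(memb)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible: no ", config$k_phylo,
           " pairwise-disjoint clades of size ", rng[1], "-", rng[2],
           " found in 10000 attempts", call. = FALSE)
    phylo_nodes <- pick
  }
  used <- if (length(phylo_nodes)) unlist(tips[phylo_nodes]) else integer(0)
  pool <- setdiff(seq_len(ntip), used)
  niches <- vector("list", k)
  for (i in seq_along(phylo_nodes))
    niches[[i]] <- list(kind = "phylo",
                        taxa = sort_ids(tree$tip.label[tips[[phylo_nodes[i]]]]),
                        node = phylo_nodes[i])
  if (config$k_nonphylo > 0) {
    for (j in seq_len(config$k_nonphylo)) {
      size <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      if (length(pool) < size)
        stop("infeasible: only ", length(pool), " taxa left outside planted ",
             "niches for a scattered set of size ", size, call. = FALSE)
      sel <- pool[sample.int(length(pool), size)]
      pool <- setdiff(pool, sel)
      niches[[config$k_phylo + j]] <-
        list(kind = "non_phylo", taxa = sort_ids(tree$tip.label[sel]),
             node = NA_integer_)
    }
  }
  w <- NULL
  for (attempt in seq_len(10000L)) {
    w <- rdirichlet1(rep(config$niche_weight_alpha, k))
    if (all(w >= config$min_niche_weight)) break
    w <- NULL
  }
  if (is.null(w))
    stop("infeasible: could not draw niche weights >= ",
         config$min_niche_weight, " in 10000 attempts", call. = FALSE)
  for (i in seq_len(k)) {
    niches[[i]]$weight <- w[i]
    niches[[i]]$occupancy_model <- config$occupancy_model
    if (config$occupancy_model == "guild_lottery") {
      niches[[i]]$guild_size <- config$guild_size
      niches[[i]]$lottery_alpha <- config$lottery_alpha
    }
  }
  structure(list(niches = niches, regime_id = regime_id,
                 tip_labels = tree$tip.label),
            class = "niche_map")
}

#' @export
print.niche_map <- function(x, ...) {
  cat(sprintf("niche_map '%s': %d niche(s)\n", x$regime_id,
              length(x$niches)))
  for (i in seq_along(x$niches)) {
    nn <- x$niches[[i]]
    cat(sprintf("  [%d] %s, %d taxa, weight %.3f\n", i, nn$kind,
                length(nn$taxa), nn$weight))
  }
  invisible(x)
}

#' Simulate one patch (local community)
#'
#' Within each niche, occupancy is neutral among the eligible taxa:
#' `winner_take_all` gives the whole niche weight to a single occupant drawn
#' uniformly; `guild_lottery` splits it across `guild_size` occupants drawn
#' without replacement with symmetric-Dirichlet shares. The composition over
#' all niches sums to 1.
#'
#' @param map a `niche_map`.
#' @param seed optional integer seed; when omitted the current RNG stream is
#'   used (as when called from [simulate_sample()]).
#' @return list with `composition` (named relative-abundance vector over all
#'   tree taxa, summing to 1) and `occupants` (per-niche list of occupant
#'   taxa and shares).
#' @export
simulate_patch <- function(map, seed = NULL) {
  stopifnot(inherits(map, "niche_map"))
  if (!is.null(seed)) set.seed(seed)
  comp <- setNames(rep(0, length(map$tip_labels)), map$tip_labels)
  occ <- vector("list", length(map$niches))
  for (i in seq_along(map$niches)) {
    nn <- map$niches[[i]]
    if (identical(nn$occupancy_model, "guild_lottery")) {
      if (nn$guild_size > length(nn$taxa))
        stop("guild_size (", nn$guild_size, ") exceeds eligible taxa (",
             length(nn$taxa), ") in niche ", i, call. = FALSE)
      who <- if (length(nn$taxa) == 1L) nn$taxa else
        sample(nn$taxa, nn$guild_size)
      shares <- rdirichlet1(rep(nn$lottery_alpha, length(who))) * nn$weight
    } else {
      who <- if (length(nn$taxa) == 1L) nn$taxa else sample(nn$taxa, 1L)
      shares <- nn$weight
    }
    comp[who] <- comp[who] + shares
    occ[[i]] <- list(taxa = who, shares = unname(shares))
  }
  list(composition = comp / sum(comp), occupants = occ)
}

#' Simulate one pooled sample
#'
#' Draws `patches_per_sample` independent patches, pools their compositions
#' with symmetric-Dirichlet weights (the higher-scale-sampling step: samples
#' aggregate local communities biased by patch preeminence), and sequences
#' the pooled composition as one multinomial draw of `depth` reads.
#'
#' @param map a `niche_map`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `counts` (named integer vector summing to `depth`) and
#'   `record` (pool weights and per-patch occupant draws).
#' @export
simulate_sample <- function(map, config, seed) {
  stopifnot(inherits(map, "niche_map"), inherits(config, "sim_config"))
  if (config$depth < 1) stop("depth must be >= 1", call. = FALSE)
  set.seed(seed)
  P <- config$patches_per_sample
  patches <- lapply(seq_len(P), function(i) simulate_patch(map))
  pw <- rdirichlet1(rep(config$patch_pool_alpha, P))
  pooled <- Reduce(`+`, Map(function(p, w) p$composition * w, patches,
                            as.list(pw)))
  counts <- as.integer(rmultinom(1L, config$depth, pooled))
  names(counts) <- names(pooled)
  list(counts = counts,
       record = list(pool_weights = pw,
                     patches = lapply(patches, `[[`, "occupants")))
}

#' Simulate a full community dataset with ground truth
#'
#' One Yule tree; `n_regimes` independently planted niche maps on it; each
#' sample is assigned a regime by `regime_mix` and simulated by
#' [simulate_sample()]. All child seeds derive deterministically from the
#' master seed (`child_seed(master, stream, index)` with fixed streams for
#' tree, niche maps, regime assignment and samples), so identical configs
#' give bit-identical outputs and any part can be re-derived.
#'
#' @param config a [sim_config()].
#' @return object of class `pcg_sim`: list with `table` (samples x taxa
#'   counts, samples `s001`...), `tree`, and `truth` (a `pcg_truth`: config
#'   echo, niche maps per regime, per-sample regime assignment and per-patch
#'   occupant records — sufficient to re-derive every count's expectation).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  master <- config$seed
  tree <- simulate_tree(config$n_taxa, child_seed(master, 1L))
  maps <- lapply(seq_len(config$n_regimes), function(r)
    plant_niches(tree, config, child_seed(master, 2L, r),
                 regime_id = sprintf("regime_%d", r)))
  set.seed(child_seed(master, 3L))
  regimes <- sample.int(config$n_regimes, config$n_samples, replace = TRUE,
                        prob = config$regime_mix)
  S <- config$n_samples
  tab <- matrix(0L, S, config$n_taxa,
                dimnames = list(sprintf("s%03d", seq_len(S)),
                                tree$tip.label))
  sample_recs <- vector("list", S)
  for (i in seq_len(S)) {
    sim <- simulate_sample(maps[[regimes[i]]], config,
                           child_seed(master, 4L, i))
    tab[i, names(sim$counts)] <- sim$counts
    sample_recs[[i]] <- list(sample_id = rownames(tab)[i],
                             regime = maps[[regimes[i]]]$regime_id,
                             record = sim$record)
  }
  truth <- structure(
    list(config = unclass(config),
         regimes = setNames(lapply(maps, function(m)
           list(regime_id = m$regime_id,
                niches = lapply(m$niches, function(nn)
                  list(kind = nn$kind, taxa = nn$taxa,
                       weight = nn$weight,
                       occupancy_model = nn$occupancy_model)))),
           vapply(maps, `[[`, character(1), "regime_id")),
         sample_regime = setNames(sprintf("regime_%d", regimes),
                                  rownames(tab)),
         samples = sample_recs),
    class = "pcg_truth")
  structure(list(table = tab, tree = tree, truth = truth),
            class = "pcg_sim")
}

#' Write / read simulation ground truth as JSON
#' @param truth a `pcg_truth` object.
#' @param path output `.json` path.
#' @return `path` invisibly; `read_truth` returns the `pcg_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "pcg_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$sample_regime <- unlist(x$sample_regime)
  for (r in names(x$regimes))
    for (i in seq_along(x$regimes[[r]]$niches))
      x$regimes[[r]]$niches[[i]]$taxa <-
        unlist(x$regimes[[r]]$niches[[i]]$taxa)
  structure(x, class = "pcg_truth")
}
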