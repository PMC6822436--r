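test_that("Yule tree simulation is deterministic, labelled and unit-height", {
  tr <- simulate_tree(2, 1)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(max(node_heights(tr)), 1.0)

  a <- ape::write.tree(simulate_tree(16, 42))
  b <- ape::write.tree(simulate_tree(16, 42))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(16, 43))))

  for (seed in 1:20) {
    tr <- simulate_tree(64, seed)
    expect_equal(ape::Ntip(tr), 64L)
    expect_identical(tr$tip.label, sprintf("t%04d", 1:64))
    h <- node_heights(tr)
    expect_equal(max(h), 1.0)
    for (e in seq_len(nrow(tr$edge)))   # heights non-decreasing rootward
      expect_gte(h[tr$edge[e, 1]], h[tr$edge[e, 2]])
  }
  expect_error(simulate_tree(1, 1), ">= 2")
})

test_that("planting niches respects clade constraints, disjointness and weights", {
  tr <- simulate_tree(6, 2)
  # forced case: one phylo niche spanning the whole tree -> the root clade
  cfg <- sim_config(n_taxa = 6, k_phylo = 1, k_nonphylo = 0,
                    clade_size_range = c(6, 6), min_niche_weight = 0)
  map <- plant_niches(tr, cfg, seed = 5)
  expect_identical(map$niches[[1]]$taxa, sort(tr$tip.label))
  expect_equal(map$niches[[1]]$weight, 1.0)

  # pigeonhole infeasibility: 3 disjoint clades of 4-8 leaves on 6 leaves
  cfg_bad <- sim_config(n_taxa = 6, k_phylo = 3, k_nonphylo = 0,
                        clade_size_range = c(4, 6), min_niche_weight = 0)
  expect_error(plant_niches(tr, cfg_bad, seed = 1), "infeasible")

  # invariants across seeds at the default configuration
  tr64 <- simulate_tree(64, 3)
  cfg64 <- sim_config()
  for (seed in 1:25) {
    map <- plant_niches(tr64, cfg64, seed = seed)
    expect_length(map$niches, 6L)
    kinds <- vapply(map$niches, `[[`, character(1), "kind")
    expect_equal(sum(kinds == "phylo"), 4L)
    sizes <- vapply(map$niches, function(x) length(x$taxa), integer(1))
    expect_true(all(sizes >= 4 & sizes <= 8))
    members <- unlist(lapply(map$niches, `[[`, "taxa"))
    expect_equal(anyDuplicated(members), 0L)  # all eligible sets disjoint
    w <- vapply(map$niches, `[[`, numeric(1), "weight")
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= cfg64$min_niche_weight))
    # phylo niches are exactly clades
    tips <- pcgkit:::clade_tips(tr64)
    for (nn in map$niches[kinds == "phylo"])
      expect_identical(nn$taxa,
                       sort(tr64$tip.label[tips[[nn$node]]], method = "radix"))
  }
})

test_that("tight-clade planting respects the height ceiling", {
  tr <- simulate_tree(64, 8)
  cfg <- sim_config(k_phylo = 4, k_nonphylo = 0, max_clade_height = 0.35)
  h <- node_heights(tr)
  for (seed in 1:10) {
    map <- plant_niches(tr, cfg, seed = seed)
    nodes <- vapply(map$niches, `[[`, integer(1), "node")
    expect_true(all(h[nodes] <= 0.35))
  }
})

test_that("patch composition is a within-niche lottery over the niche weights", {
  tipl <- c("A", "B", "C", "D", "E")
  map <- manual_niche_map(tipl, list(
    list(kind = "phylo", taxa = c("A", "B", "C", "D"), weight = 0.7,
         occupancy_model = "winner_take_all"),
    list(kind = "non_phylo", taxa = "E", weight = 0.3,
         occupancy_model = "winner_take_all")))
  p <- simulate_patch(map, seed = 1)
  expect_equal(sum(p$composition), 1, tolerance = 1e-9)
  expect_equal(sort(unname(p$composition[p$composition > 0])), c(0.3, 0.7))
  expect_equal(unname(p$composition["E"]), 0.3)

  # single niche, single taxon
  map1 <- manual_niche_map("A", list(list(kind = "phylo", taxa = "A",
                                          weight = 1,
                                          occupancy_model = "winner_take_all")))
  expect_equal(unname(simulate_patch(map1, seed = 1)$composition["A"]), 1.0)

  # winner-take-all draws occupants uniformly
  set.seed(99)
  wins <- table(vapply(1:2000, function(i) {
    p <- simulate_patch(map)
    names(which.max(p$composition))  # the 0.7-niche winner
  }, character(1)))
  freq <- as.numeric(wins) / 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(freq - 0.25) < 3.5 * se))

  # guild lottery: guild_size occupants share the niche weight
  mapg <- manual_niche_map(tipl, list(
    list(kind = "phylo", taxa = c("A", "B", "C", "D"), weight = 1,
         occupancy_model = "guild_lottery", guild_size = 3,
         lottery_alpha = 1)))
  pg <- simulate_patch(mapg, seed = 3)
  expect_equal(sum(pg$composition > 0), 3L)
  expect_equal(sum(pg$composition), 1, tolerance = 1e-9)
  mapg$niches[[1]]$guild_size <- 5
  expect_error(simulate_patch(mapg, seed = 1), "guild_size")
})

test_that("sample simulation pools patches and conserves depth", {
  tipl <- c("A", "B", "C")
  map <- manual_niche_map(tipl, list(
    list(kind = "phylo", taxa = c("A", "B"), weight = 0.8,
         occupancy_model = "winner_take_all"),
    list(kind = "non_phylo", taxa = "C", weight = 0.2,
         occupancy_model = "winner_take_all")))
  cfg <- sim_config(n_taxa = 3, k_phylo = 1, k_nonphylo = 1,
                    clade_size_range = c(1, 2), min_niche_weight = 0,
                    patches_per_sample = 1, depth = 500)
  s <- simulate_sample(map, cfg, seed = 4)
  expect_equal(sum(s$counts), 500L)
  # P=1: pooled composition equals the patch composition, so observed
  # proportions are a multinomial around (0.8, 0.2)
  expect_lt(abs(unname(s$counts["C"]) / 500 - 0.2), 0.07)

  # degenerate one-taxon community: the taxon takes every read
  map1 <- manual_niche_map("A", list(list(kind = "phylo", taxa = "A",
                                          weight = 1,
                                          occupancy_model = "winner_take_all")))
  cfg1 <- sim_config(n_taxa = 2, k_phylo = 1, k_nonphylo = 0,
                     clade_size_range = c(1, 1), min_niche_weight = 0,
                     depth = 100)
  s1 <- simulate_sample(map1, cfg1, seed = 1)
  expect_equal(unname(s1$counts["A"]), 100L)
})

test_that("dataset simulation conserves depth, echoes truth and is deterministic", {
  cfg <- sim_config(n_samples = 12, depth = 2000, seed = 77)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$table), c(12L, 64L))
  expect_true(all(rowSums(sim$table) == 2000))
  expect_identical(rownames(sim$table), sprintf("s%03d", 1:12))
  expect_length(sim$truth$samples, 12L)
  expect_identical(sim$truth$config$seed, 77)

  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$table, sim2$table)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))

  # byte-identical on-disk outputs for identical master seeds
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_abundance_table(sim$table, file.path(d1, "table.tsv"))
  write_abundance_table(sim2$table, file.path(d2, "table.tsv"))
  write_truth(sim$truth, file.path(d1, "truth.json"))
  write_truth(sim2$truth, file.path(d2, "truth.json"))
  expect_identical(readLines(file.path(d1, "table.tsv")),
                   readLines(file.path(d2, "table.tsv")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))

  # truth JSON round-trips the niche structure
  tr <- read_truth(file.path(d1, "truth.json"))
  expect_identical(names(tr$regimes), "regime_1")
  expect_identical(
    lapply(tr$regimes$regime_1$niches, `[[`, "taxa"),
    lapply(sim$truth$regimes$regime_1$niches, `[[`, "taxa"))
})

test_that("pooled niche abundance matches its weight in expectation", {
  # with winner_take_all the whole niche weight lands on clade members in
  # every patch, so each sample's pooled clade share is the niche weight up
  # to multinomial noise
  for (seed in c(5, 6)) {
    cfg <- sim_config(n_samples = 20, seed = seed)
    sim <- simulate_dataset(cfg)
    niches <- sim$truth$regimes$regime_1$niches
    for (nn in niches) {
      share <- rowSums(sim$table[, nn$taxa, drop = FALSE]) /
        rowSums(sim$table)
      expect_lt(abs(mean(share) - nn$weight), 0.005)
    }
  }
})

test_that("simulator configs validate and round-trip through YAML/JSON", {
  expect_error(sim_config(n_regimes = 2, regime_mix = c(0.6, 0.5)),
               "sum to 1")
  expect_error(sim_config(clade_size_range = c(10, 80)), "n_taxa")
  expect_error(sim_config(k_phylo = 0, k_nonphylo = 0), "at least one")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_taxa: 32", "k_phylo: 2", "n_samples: 5", "seed: 9"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n_taxa, 32L)
  expect_equal(cfg$k_phylo, 2L)
  expect_equal(cfg$k_nonphylo, 2L)  # default retained
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_taxa = 16, depth = 100), f2, auto_unbox = TRUE)
  expect_equal(read_sim_config(f2)$depth, 100L)
  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 3", f3)
  expect_error(read_sim_config(f3), "unknown config")
})
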