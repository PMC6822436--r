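worked_example <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tab <- matrix(c(5L, 0L, 2L, 0L, 3L, 0L, 2L, 1L, 0L, 0L, 0L, 4L), nrow = 3,
                dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C", "D")))
  list(tree = tree, tab = abundance_table(tab))
}

test_that("presence thresholds combine count and relative abundance", {
  tab <- matrix(c(0L, 1L, 5L, 100L, 99L, 995L), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  p0 <- presence_matrix(tab, presence_params(min_count = 1))
  expect_false(p0["s1", "A"])   # zero reads never present
  expect_true(p0["s2", "A"])    # 1 read of 100 passes at min_relabund 0
  p1 <- presence_matrix(tab, presence_params(min_relabund = 0.01))
  expect_false(p1["s3", "A"])   # 5/1000 = 0.005 < 0.01
  expect_error(presence_params(min_count = 0, min_relabund = 0), "never")
})

test_that("pooled presence makes a clade core when no single member is", {
  ex <- worked_example()
  # clade {A,B}: A = [5,0,2], B = [0,3,0]; pooled [5,3,2] all >= 1
  cn <- core_nodes(ex$tree, ex$tab, presence_params())
  tips <- pcgkit:::clade_tips(ex$tree)
  labels_of <- function(nd) sort(ex$tree$tip.label[tips[[nd]]])
  core_sets <- lapply(cn, labels_of)
  expect_true(list(c("A", "B")) %in% core_sets)
  # no leaf is core
  expect_true(all(cn > ape::Ntip(ex$tree)))
  # root pools everything, always core when every sample has reads
  expect_true((ape::Ntip(ex$tree) + 1L) %in% cn)
})

test_that("find_pcgs returns the minimal core clades of the worked example", {
  ex <- worked_example()
  pcgs <- find_pcgs(ex$tree, ex$tab)
  expect_identical(pcg_member_sets(pcgs),
                   list(c("A", "B"), c("C", "D")))
  expect_identical(pcg_member_sets(pcgs), oracle_find_pcgs(ex$tree, ex$tab,
                                                           presence_params()))
  expect_equal(vapply(pcgs$pcgs, `[[`, numeric(1), "depth"), c(1, 1))
  expect_equal(vapply(pcgs$pcgs, `[[`, numeric(1), "prevalence"), c(1, 1))
  # summary: dominants and full coverage
  summ <- pcg_summary(pcgs, ex$tab, ex$tree)
  expect_identical(unname(summ$dominants["pcg_1", ]), c("A", "B", "A"))
  expect_equal(summ$mean_coverage, 1.0)
})

test_that("a single ubiquitous taxon yields a depth-zero leaf PCG", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tab <- matrix(c(3L, 2L, 9L, rep(0L, 6)), 3, 3,
                dimnames = list(paste0("s", 1:3), c("A", "B", "C")))
  pcgs <- find_pcgs(tree, tab)
  expect_identical(pcg_member_sets(pcgs), list("A"))
  expect_equal(pcgs$pcgs[[1]]$depth, 0)
})

test_that("one sample below threshold empties the PCG set at prevalence 1", {
  ex <- worked_example()
  tab <- ex$tab
  tab["s2", ] <- c(0L, 1L, 0L, 0L)  # total 1 read
  expect_length(find_pcgs(ex$tree, tab,
                          presence_params(min_count = 2L))$pcgs, 0L)
})

test_that("empty samples error unless explicitly dropped", {
  ex <- worked_example()
  tab <- ex$tab
  tab["s2", ] <- 0L
  expect_error(find_pcgs(ex$tree, tab), "zero total")
  pcgs <- suppressMessages(
    find_pcgs(ex$tree, tab, allow_empty_samples = TRUE))
  expect_equal(pcgs$n_samples, 2L)
})

test_that("detection matches the brute-force clade oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    got <- pcg_member_sets(find_pcgs(inst$tree, inst$tab, inst$params))
    want <- oracle_find_pcgs(inst$tree, inst$tab, inst$params)
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("coreness is monotone rootward and PCGs are minimal and disjoint", {
  for (seed in 101:140) {
    inst <- random_instance(seed)
    cn <- core_nodes(inst$tree, inst$tab, inst$params)
    core <- logical(ape::Ntip(inst$tree) + inst$tree$Nnode)
    core[cn] <- TRUE
    ch <- pcgkit:::node_children(inst$tree)
    for (k in seq_along(ch)) for (c in ch[[k]])
      if (core[c]) expect_true(core[k], label = paste("parent core, seed", seed))
    pcgs <- find_pcgs(inst$tree, inst$tab, inst$params)
    sets <- pcg_member_sets(pcgs)
    all_members <- unlist(sets)
    expect_equal(anyDuplicated(all_members), 0L)
    # minimality: no PCG strictly contains another core clade
    tips <- pcgkit:::clade_tips(inst$tree)
    core_sets <- lapply(cn, function(nd)
      sort(inst$tree$tip.label[tips[[nd]]], method = "radix"))
    for (s in sets)
      expect_false(any(vapply(core_sets, function(o)
        length(o) < length(s) && all(o %in% s), logical(1))))
  }
})

test_that("a fully observed community always yields at least one PCG", {
  for (seed in 201:230) {
    inst <- random_instance(seed, force_defaults = TRUE)
    # defaults: min_count 1, prevalence 1, and every sample has >= 1 read
    expect_gt(length(find_pcgs(inst$tree, inst$tab)$pcgs), 0L)
  }
})

test_that("stricter thresholds never add core nodes and only coarsen PCGs", {
  # raising min_count / min_relabund (or demanding higher prevalence) can
  # only remove core nodes; minimal core nodes therefore move rootward, so
  # every PCG under the stricter setting contains at least one PCG from the
  # looser setting (when it has any PCGs at all)
  check_pair <- function(tree, tab, loose_p, strict_p, seed) {
    loose_cn <- core_nodes(tree, tab, loose_p)
    strict_cn <- core_nodes(tree, tab, strict_p)
    expect_true(all(strict_cn %in% loose_cn), info = paste("seed", seed))
    loose <- pcg_member_sets(find_pcgs(tree, tab, loose_p))
    strict <- pcg_member_sets(find_pcgs(tree, tab, strict_p))
    for (s in strict)
      expect_true(any(vapply(loose, function(w) all(w %in% s), logical(1))),
                  info = paste("seed", seed))
  }
  for (seed in 301:330) {
    inst <- random_instance(seed, force_defaults = TRUE)
    check_pair(inst$tree, inst$tab, presence_params(),
               presence_params(min_count = 3L), seed)
    check_pair(inst$tree, inst$tab, presence_params(),
               presence_params(min_relabund = 0.05), seed)
    check_pair(inst$tree, inst$tab, presence_params(prevalence = 0.5),
               presence_params(), seed)
  }
})
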