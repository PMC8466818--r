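test_that("three-taxon NJ solves the closed-form branch system", {
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), (0.3 + 0.4 + 0.5) / 2)
  cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cp, D, tolerance = 1e-12)
})

test_that("NJ recovers the generating 5-taxon tree found by exhaustive LS search", {
  set.seed(431)
  for (i in 1:5) {
    ra <- random_additive(5)
    best <- best_ls_topology(ra$D)
    expect_lt(best$rss, 1e-18)
    tr <- nj_tree(ra$D)
    expect_equal(ape::dist.topo(tr, best$tree), setNames(0L, "PH85"),
                 ignore_attr = TRUE)
    cp <- ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)]
    expect_lt(max(abs(cp - ra$D)), 1e-9)
  }
})

test_that("equidistant taxa resolve reproducibly under the tie rule", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  expect_equal(write_newick(nj_tree(D)), write_newick(nj_tree(D)))
})

test_that("pairwise deletion excludes ambiguous sites and p-distance matches counting", {
  set.seed(432)
  s <- random_dna(600)
  s2 <- mutate_at(s, sample(600, 30), sample(BASES4, 30, replace = TRUE))
  s3 <- mutate_at(s, sample(1:590, 10), rep("N", 10))
  recs <- as_seq_records(c(a = s, b = s2, c = s3))
  dm <- pairwise_distance(recs, "p-distance")
  expect_equal(dm$sites_used["a", "c"], 590)
  expect_equal(dm$d["a", "c"], 0)
  mism <- sum(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(dm$d["a", "b"], mism / 600)
  expect_equal(dm$d, t(dm$d))
})

test_that("TN93 collapses to the JC69 closed form under balanced composition", {
  m <- 50; k <- 3
  s1 <- c(); s2 <- c()
  for (b in BASES4) { s1 <- c(s1, rep(b, m)); s2 <- c(s2, rep(b, m)) }
  for (x in BASES4) for (y in BASES4) if (x != y) {
    s1 <- c(s1, rep(x, k)); s2 <- c(s2, rep(y, k))
  }
  recs <- as_seq_records(c(a = paste(s1, collapse = ""),
                           b = paste(s2, collapse = ""),
                           c = paste(s1, collapse = "")))
  p <- sum(s1 != s2) / length(s1)
  jc_closed <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(pairwise_distance(recs, "TN93")$d["a", "b"], jc_closed,
               tolerance = 1e-9)
  expect_equal(pairwise_distance(recs, "JC69")$d["a", "b"], jc_closed,
               tolerance = 1e-9)
  expect_equal(pairwise_distance(recs, "TN93")$d["a", "c"], 0)
})

test_that("identical sequences give zero distance under every model", {
  recs <- as_seq_records(c(a = strrep("ACGT", 50), b = strrep("ACGT", 50),
                           c = strrep("ACGT", 50)))
  for (model in c("p-distance", "JC69", "TN93"))
    expect_true(all(pairwise_distance(recs, model)$d == 0))
})

test_that("bootstrap gives near-certain support to a deeply split clade and is seeded", {
  sim <- simulate_gene_family(family_config(
    clades = list(clade_spec("A", 3, data.frame(pos_nt = seq(12, 400, by = 4),
                                                allele = "A"),
                             private_snps_range = c(1, 2)),
                  clade_spec("B", 3, data.frame(pos_nt = seq(12, 400, by = 4) + 1,
                                                allele = "T"),
                             private_snps_range = c(1, 2))),
    seed = 48))
  recs <- sim$records[!grepl("_ref$", sim$truth$id)]
  tr <- bootstrap_support(recs, "JC69", n_reps = 200, collapse_below = 0,
                          seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the A/B split is the strongest bipartition present
  expect_gte(max(sup, na.rm = TRUE), 99)
  tr2 <- bootstrap_support(recs, "JC69", n_reps = 200, collapse_below = 0,
                           seed = 5)
  expect_identical(write_newick(tr), write_newick(tr2))
})

test_that("collapsing is monotone and produces polytomies below threshold", {
  sim <- simulate_gene_family(family_config(clades = cansynth:::default_clades(4),
                                            seed = 49))
  recs <- sim$records[!grepl("_ref$", sim$truth$id)]
  t0 <- bootstrap_support(recs, "JC69", n_reps = 100, collapse_below = 0, seed = 6)
  t50 <- bootstrap_support(recs, "JC69", n_reps = 100, collapse_below = 50, seed = 6)
  t90 <- bootstrap_support(recs, "JC69", n_reps = 100, collapse_below = 90, seed = 6)
  expect_gte(t0$Nnode, t50$Nnode)
  expect_gte(t50$Nnode, t90$Nnode)
  sup50 <- suppressWarnings(as.numeric(t50$node.label))
  expect_true(all(sup50[-1][!is.na(sup50[-1])] >= 50))
})

test_that("alignment of identical sequences collapses to a star tree", {
  recs <- as_seq_records(setNames(rep(strrep("ACGT", 100), 5), paste0("t", 1:5)))
  tr <- suppressWarnings(bootstrap_support(recs, "p-distance", n_reps = 20,
                                           collapse_below = 50, seed = 7))
  expect_equal(tr$Nnode, 1)  # full polytomy
})

test_that("Newick output round-trips topology, lengths and supports", {
  sim <- simulate_gene_family(family_config(clades = cansynth:::default_clades(3),
                                            seed = 50))
  recs <- sim$records[!grepl("_ref$", sim$truth$id)]
  tr <- bootstrap_support(recs, "JC69", n_reps = 50, collapse_below = 50, seed = 8)
  s <- write_newick(tr)
  back <- read_newick(s)
  expect_equal(ape::dist.topo(tr, back), setNames(0L, "PH85"), ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sum(back$edge.length), sum(tr$edge.length), tolerance = 1e-4)
  expect_identical(write_newick(back), s)

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_identical(write_newick(read_newick(path)), s)
})

test_that("negative NJ branch estimates are clamped with a warning", {
  D <- matrix(c(0.000, 0.339, 0.435, 0.917,
                0.339, 0.000, 0.616, 0.282,
                0.435, 0.616, 0.000, 0.909,
                0.917, 0.282, 0.909, 0.000), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  # this matrix is strongly non-additive; NJ yields a negative edge estimate
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})
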