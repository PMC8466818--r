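test_that("standard-curve fitting reproduces slope, R2 and the efficiency formula", {
  lq <- -(0:4) * log10(4)
  # exact line of slope -3.3219 through intercept 30
  cv <- fit_standard_curve(lq, 30 + (-3.3219) * lq)
  expect_equal(cv$slope, -3.3219, tolerance = 1e-9)
  expect_equal(cv$intercept, 30, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$efficiency, 1, tolerance = 1e-3)

  expect_equal(efficiency_from_slope(-3.4531), 0.948, tolerance = 1e-3)
  # efficiency decreases as the slope steepens
  sl <- seq(-3.1, -3.9, by = -0.1)
  expect_true(all(diff(efficiency_from_slope(sl)) < 0))

  expect_error(fit_standard_curve(rep(1, 5), rnorm(5)), "equal")
  expect_error(fit_standard_curve(1:2, 1:2), "at least 3")
})

test_that("quantity interpolation inverts the curve exactly", {
  cv <- fit_standard_curve(-(0:4) * log10(4), 25 + (-3.3219) * -(0:4) * log10(4))
  expect_equal(interpolate_quantity(cv$intercept, cv), 1)
  expect_equal(interpolate_quantity(cv$intercept - 3.3219, cv), 10,
               tolerance = 1e-9)
  # round-trip on the fitting points
  for (q in 10^(-(0:4) * log10(4)))
    expect_equal(interpolate_quantity(cv$intercept + cv$slope * log10(q), cv),
                 q, tolerance = 1e-9)
  expect_true(is.na(interpolate_quantity(NA_real_, cv)))
})

test_that("noiseless simulated standards recover the configured efficiency", {
  design <- data.frame(genotype = "g1", gene = "target", expression = 1)
  sp <- simulate_qpcr_plate(design, efficiencies = c(target = 0.93),
                            noise_sd = 0, seed = 3)
  cv <- curves_from_plate(sp$plate)$target
  expect_equal(cv$efficiency, 0.93, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
})

test_that("stability ranking prefers the low-noise gene and recovers the noise order", {
  set.seed(471)
  # constant gene ranks first even on a small panel
  p0 <- stability_plate(8, c(0, 0.5, 0.5))
  r0 <- rank_reference_stability(p0, c("gA", "gB", "gC"))
  expect_equal(r0$gene[1], "gA")

  # full-order recovery on a panel large enough to resolve the 0.05 vs 0.2
  # contrast through the shared 0.8-SD partner
  hits <- 0L
  for (i in 1:50) {
    r <- rank_reference_stability(stability_plate(250, c(0.05, 0.2, 0.8)),
                                  c("gA", "gB", "gC"))
    if (identical(r$gene, c("gA", "gB", "gC"))) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("stability ranking breaks ties deterministically and excludes sparse genes", {
  cqs <- c(20.1, 20.4, 19.8, 20.0)
  p <- do.call(rbind, lapply(1:4, function(s) rbind(
    plate_rows(paste0("s", s), "geneA", cqs[s]),
    plate_rows(paste0("s", s), "geneB", cqs[s]),
    plate_rows(paste0("s", s), "geneC", cqs[s] + rnorm(1, 0, 1)))))
  r <- rank_reference_stability(p, c("geneB", "geneA", "geneC"))
  expect_equal(r$gene[1:2], c("geneA", "geneB"))  # tied, name breaks the tie

  p2 <- p
  p2$cq[p2$gene == "geneC"] <- NA
  expect_warning(r2 <- rank_reference_stability(p2, c("geneA", "geneB", "geneC")),
                 "excluding")
  expect_false("geneC" %in% r2$gene)
})

test_that("RQ is the target quantity over the geometric reference mean", {
  # construct exact wells: target 10, refs 5 and 20 -> geomean 10 -> RQ 1
  cv <- list(
    t = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "t"),
    r1 = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "r1"),
    r2 = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "r2"))
  cq_for <- function(cv1, q) cv1$intercept + cv1$slope * log10(q)
  p <- rbind(plate_rows("g1", "t", cq_for(cv$t, 10)),
             plate_rows("g1", "r1", cq_for(cv$r1, 5)),
             plate_rows("g1", "r2", cq_for(cv$r2, 20)))
  rq <- compute_rq(p, "t", c("r1", "r2"), cv)
  expect_equal(rq$rq, 1, tolerance = 1e-9)

  # global rescaling of all quantities in the sample leaves RQ unchanged
  for (c_scale in c(0.1, 7, 300)) {
    p2 <- rbind(plate_rows("g1", "t", cq_for(cv$t, 10 * c_scale)),
                plate_rows("g1", "r1", cq_for(cv$r1, 5 * c_scale)),
                plate_rows("g1", "r2", cq_for(cv$r2, 20 * c_scale)))
    expect_equal(compute_rq(p2, "t", c("r1", "r2"), cv)$rq, 1, tolerance = 1e-9)
  }
  # exchanging the reference genes leaves RQ unchanged
  expect_equal(compute_rq(p, "t", c("r2", "r1"), cv)$rq, rq$rq)
})

test_that("undetected targets report n.d. and undetected references drop replicates", {
  cv <- list(t = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "t"),
             r1 = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "r1"))
  p <- rbind(plate_rows("g1", "t", NA_real_, bio = 1L),
             plate_rows("g1", "t", NA_real_, bio = 2L),
             plate_rows("g1", "r1", 20, bio = 1L),
             plate_rows("g1", "r1", 20, bio = 2L))
  rq <- compute_rq(p, "t", "r1", cv)
  expect_false(rq$detected)
  expect_equal(format_rq(rq)$rq, "n.d.")

  p2 <- rbind(plate_rows("g2", "t", 18, bio = 1L),
              plate_rows("g2", "r1", 20, bio = 1L),
              plate_rows("g2", "t", 18, bio = 2L),
              plate_rows("g2", "r1", NA_real_, bio = 2L))
  expect_warning(rq2 <- compute_rq(p2, "t", "r1", cv), "dropped")
  expect_equal(rq2$n, 1)
})

test_that("baseline comparison matches the pooled t-test and stars thresholds", {
  # build per-replicate RQs via exact wells: log-RQs {0,0,0} vs {1,1.1,0.9}
  cv <- list(t = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "t"),
             r = fit_standard_curve(-(0:4), 20 - 3 * -(0:4), gene = "r"))
  cq_for <- function(cv1, q) cv1$intercept + cv1$slope * log10(q)
  base_rq <- exp(c(0, 0, 0)); alt_rq <- exp(c(1, 1.1, 0.9))
  rows <- list()
  for (b in 1:3) {
    rows[[length(rows) + 1]] <- plate_rows("base", "t", cq_for(cv$t, base_rq[b]), bio = b)
    rows[[length(rows) + 1]] <- plate_rows("base", "r", cq_for(cv$r, 1), bio = b)
    rows[[length(rows) + 1]] <- plate_rows("alt", "t", cq_for(cv$t, alt_rq[b]), bio = b)
    rows[[length(rows) + 1]] <- plate_rows("alt", "r", cq_for(cv$r, 1), bio = b)
  }
  p <- do.call(rbind, rows)
  rq <- compute_rq(p, "t", "r", cv)
  out <- compare_to_baseline(rq, "base")
  want <- t.test(c(1, 1.1, 0.9), c(0, 0, 0), var.equal = TRUE)$p.value
  expect_equal(out$p_vs_baseline[out$genotype == "alt"], want, tolerance = 1e-9)
  expect_equal(out$p_vs_baseline[out$genotype == "base"], 1)
  expect_equal(out$stars[out$genotype == "base"], "ns")

  expect_equal(cansynth:::stars_for_p(0.009), "**")
  expect_equal(cansynth:::stars_for_p(0.04), "*")
  expect_equal(cansynth:::stars_for_p(0.0009), "***")
  expect_equal(cansynth:::stars_for_p(0.2), "ns")

  expect_error(compare_to_baseline(rq, "missing"), "absent")
})

test_that("a known expression ratio is recovered from a simulated plate", {
  set.seed(472)
  ratios <- vapply(1:10, function(i) recover_ratio(15, 0.15, seed = 1000 + i),
                   numeric(1))
  expect_lt(abs(mean(ratios) / 15 - 1), 0.15)
})

test_that("plate reader validates columns and standards", {
  p <- std_rows("t")
  path <- withr::local_tempfile(fileext = ".csv")
  write_qpcr_plate(p, path)
  back <- read_qpcr_plate(path)
  expect_equal(back$cq, p$cq)
  expect_error(validate_plate(p[, -3]), "missing column")
  p_bad <- p; p_bad$log10_quantity <- NA
  expect_error(validate_plate(p_bad), "log10_quantity")
})
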