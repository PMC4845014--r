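small_cfg <- function(...) {
  sim_config(seed = 7, n_chroms = 1L, chrom_length = 300000L,
             subfamily_catalogue = data.frame(
               subfamily = c("IAPEY", "RLTRETN"),
               class_family = "LTR/ERVK",
               element_length = 700L, n_elements = c(100L, 100L)),
             planted_effects = data.frame(subfamily = "IAPEY", fraction = 0.2,
                                          delta_pp = 25, direction = "hypo"),
             tss_count = 10L, icr_count = 2L, ...)
}

test_that("toy genome satisfies its structural constraints", {
  cfg <- small_cfg()
  g <- build_genome(cfg)
  expect_equal(unname(g$chrom_sizes), 300000L)
  # elements non-overlapping and inside the chromosome
  r <- g$repeats[order(g$repeats$start), ]
  expect_true(all(r$end[-nrow(r)] <= r$start[-1]))
  expect_true(all(r$start >= 0) && all(r$end <= 300000))
  expect_equal(nrow(r), 200)
  # CpG positions strictly increasing with roughly the configured spacing
  expect_true(all(diff(g$cpgs$pos) >= 2))
  expect_equal(mean(diff(g$cpgs$pos)), cfg$cpg_spacing_mean, tolerance = 0.1)
  # determinism
  g2 <- build_genome(cfg)
  expect_identical(g, g2)
})

test_that("genome building fails when elements cannot be packed", {
  cfg <- sim_config(seed = 1, n_chroms = 1L, chrom_length = 1000000L,
                    subfamily_catalogue = data.frame(
                      subfamily = "IAPEY", class_family = "LTR/ERVK",
                      element_length = 2000L, n_elements = 1000L),
                    planted_effects = NULL)
  expect_error(build_genome(cfg), "too short")
})

test_that("planted effects shift only the chosen elements by the stated delta", {
  cfg <- small_cfg()
  g <- build_genome(cfg)
  sim <- simulate_methylomes(g, cfg)
  truth <- sim$truth
  expect_equal(sum(truth$planted), 20)
  expect_true(all(truth$subfamily[truth$planted] == "IAPEY"))
  d <- truth$true_meth_mut - truth$true_meth_wt
  expect_equal(d[!truth$planted], rep(0, sum(!truth$planted)))
  # planted delta is -25 pp unless floored at zero
  floored <- truth$true_meth_wt < 25
  expect_equal(d[truth$planted & !floored],
               rep(-25, sum(truth$planted & !floored)))
  expect_true(all(truth$true_meth_mut[truth$planted & floored] == 0))

  # no-effect configuration plants nothing
  cfg0 <- small_cfg()
  cfg0$planted_effects <- NULL
  sim0 <- simulate_methylomes(build_genome(cfg0), cfg0)
  expect_false(any(sim0$truth$planted))
  expect_equal(sim0$truth$true_meth_mut, sim0$truth$true_meth_wt)
})

test_that("background methylation matches the configured Beta mean", {
  cfg <- sim_config(seed = 11, n_chroms = 1L, chrom_length = 1000000L,
                    subfamily_catalogue = data.frame(
                      subfamily = "IAPEY", class_family = "LTR/ERVK",
                      element_length = 700L, n_elements = 10L),
                    planted_effects = NULL, icr_count = 1L)
  g <- build_genome(cfg)
  sim <- simulate_methylomes(g, cfg)
  j <- merge(as.data.frame(unclass(sim$wt)), g$cpgs, by = c("chrom", "pos"))
  in_element <- !is.na(repmeth:::overlap_index(g$cpgs, g$repeats))
  in_icr <- !is.na(repmeth:::overlap_index(g$cpgs, g$icrs))
  bg <- sim$wt[!in_element & !in_icr, ]
  bg <- bg[bg$meth + bg$unmeth > 0, ]
  expect_gt(nrow(bg), 10000)
  mean_pct <- mean(100 * bg$meth / (bg$meth + bg$unmeth))
  expect_lt(abs(mean_pct - 90), 1)
})

test_that("coverage follows the configured negative binomial", {
  cfg <- small_cfg()
  sim <- simulate_methylomes(build_genome(cfg), cfg)
  cov <- sim$wt$meth + sim$wt$unmeth
  expect_lt(abs(mean(cov) - 30), 0.5)
  # overdispersed: variance well above the Poisson value
  expect_gt(stats::var(cov), 1.5 * mean(cov))
})

test_that("cohort simulation is multinomial, consistent and seeded", {
  recs <- simulate_cohort(c(Y = 1, M = 0, psi = 0), 10, seed = 2)
  expect_equal(nrow(recs), 10)
  expect_true(all(pool_categories(recs$category5) == "Y"))

  big <- simulate_cohort(c(Y = 0.29, M = 0.56, psi = 0.15), 10000, seed = 3)
  fy <- mean(pool_categories(big$category5) == "Y")
  expect_lt(abs(fy - 0.29), 3 * sqrt(0.29 * 0.71 / 10000))
  # category5 is always consistent with its pool
  expect_true(all(as.character(pool_categories(big$category5)) %in%
                    c("Y", "M", "psi")))
  expect_identical(big, simulate_cohort(c(Y = 0.29, M = 0.56, psi = 0.15),
                                        10000, seed = 3))
  expect_error(simulate_cohort(c(Y = 0.5, M = 0.4, psi = 0.2), 10, seed = 1),
               "sum to 1")
})

test_that("cohort probability helper keeps the control M:psi ratio", {
  p <- cohort_probs(0.47)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["M"] / p["psi"]), 56 / 15)
  expect_equal(unname(cohort_probs(0.29)["M"]), 0.56)
})

test_that("clone simulation honours extreme probabilities and the QC path", {
  ms <- simulate_clones(2, 3, 5, p_meth = c(wt = 1, mut = 1), seed = 4)
  expect_equal(length(ms), 4)
  expect_true(all(vapply(ms, function(m) all(m$calls == 1), TRUE)))

  low <- simulate_clones(3, 10, 20, conversion_eff = 0.95, seed = 5)
  rates <- vapply(low, function(m) conversion_rate(m)$pass, TRUE)
  expect_true(mean(!rates) > 0.5)  # 95 percent efficiency mostly fails QC at 97
})

test_that("fixture writing produces a complete, reproducible, re-readable bundle", {
  cfg <- small_cfg()
  g <- build_genome(cfg)
  sim <- simulate_methylomes(g, cfg)
  d1 <- withr::local_tempdir()
  man1 <- write_fixture(d1, g, sim,
                        cohort = simulate_cohort(cohort_probs(), 50, seed = 1),
                        clones = simulate_clones(2, 3, 5, seed = 1))
  expect_gte(nrow(man1), 7)
  expect_true(all(man1$bytes > 0))
  d2 <- withr::local_tempdir()
  man2 <- write_fixture(d2, g, sim,
                        cohort = simulate_cohort(cohort_probs(), 50, seed = 1),
                        clones = simulate_clones(2, 3, 5, seed = 1))
  expect_identical(man1$md5, man2$md5)

  # re-reading the emitted files reproduces the in-memory objects
  wt2 <- merge_strands(read_cytosine_report(
    file.path(d1, "wt.cytosine_report.tsv")), "wt")
  expect_identical(wt2$meth, sim$wt$meth)
  expect_identical(wt2$pos, sim$wt$pos)
  ann <- read_repeat_annotation(file.path(d1, "repeats.bed"))
  expect_equal(ann$start, g$repeats$start)
  expect_equal(ann$subfamily, g$repeats$subfamily)
  cs <- read_chrom_sizes(file.path(d1, "chrom.sizes"))
  expect_identical(cs, g$chrom_sizes)
})
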