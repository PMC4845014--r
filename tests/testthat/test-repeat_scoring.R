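test_that("CpG qualification enforces the coverage and balance rules", {
  pos <- c(11L, 21L, 31L, 41L, 51L)
  # covs wt: 8, 10, 20, 20, 7 / mut: 8, 5, 12, 11, 30
  wt <- make_methylome(pos, meth = c(4L, 5L, 10L, 10L, 4L),
                       unmeth = c(4L, 5L, 10L, 10L, 3L))
  mut <- make_methylome(pos, meth = c(4L, 2L, 6L, 6L, 15L),
                        unmeth = c(4L, 3L, 6L, 5L, 15L))
  q <- qualify_cpgs(wt, mut)
  # (8, 8) kept at the coverage boundary; (10, 5) dropped (5 < 0.6 * 10);
  # (20, 12) kept exactly at the bias boundary; (20, 11) dropped;
  # (7, 30) dropped by min_cov
  expect_setequal(q$pos, c(11L, 31L))

  # at min_cov = 1 the bias rule alone decides: (10, 6) kept, (10, 5) dropped
  wt6 <- make_methylome(c(11L, 21L), meth = c(5L, 5L), unmeth = c(5L, 5L))
  mut6 <- make_methylome(c(11L, 21L), meth = c(3L, 2L), unmeth = c(3L, 3L))
  expect_equal(qualify_cpgs(wt6, mut6, min_cov = 1)$pos, 11L)

  expect_error(qualify_cpgs(wt, mut, min_cov = 0), "min_cov")
  expect_error(qualify_cpgs(wt, mut, bias_fraction = 0), "bias_fraction")
  expect_error(qualify_cpgs(wt, mut, bias_fraction = 1.5), "bias_fraction")

  # the alternative deviation reading admits (10, 5): (10-5)/10 <= 0.6
  q2 <- qualify_cpgs(wt6, mut6, min_cov = 1, bias_rule = "deviation")
  expect_setequal(q2$pos, c(11L, 21L))
})

test_that("qualification is symmetric in the two samples", {
  withr::with_seed(21, {
    pos <- seq(11, by = 10, length.out = 200)
    wt <- make_methylome(pos, rpois(200, 15), rpois(200, 3), id = "wt")
    mut <- make_methylome(pos, rpois(200, 15), rpois(200, 3), id = "mut")
  })
  q1 <- qualify_cpgs(wt, mut)
  q2 <- qualify_cpgs(mut, wt)
  expect_identical(q1$pos, q2$pos)
})

test_that("region membership uses half-open containment of the plus-strand C", {
  # region [100, 200): 1-based C positions 101..200 are inside
  pos <- c(100L, 101L, 200L, 201L)
  wt <- make_methylome(pos, 10L, 2L)
  mut <- make_methylome(pos, 10L, 2L)
  q <- qualify_cpgs(wt, mut, region = list(chrom = "chr1", start = 100, end = 200))
  expect_setequal(q$pos, c(101L, 200L))
})

test_that("weighted score matches hand arithmetic and the brute-force loop", {
  expect_equal(weighted_region_score(c(100, 0), c(10, 10)), 50)
  expect_equal(weighted_region_score(c(80, 60, 100), c(20, 10, 10)), 80)
  expect_equal(weighted_region_score(rep(73.2, 5), c(1, 9, 30, 2, 8)), 73.2)
  expect_error(weighted_region_score(numeric(), numeric()), "empty")
  expect_error(weighted_region_score(c(50, 50), c(10, 0)), "positive")

  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(1:40, 1)
      m <- runif(n, 0, 100); cov <- sample(1:80, n, replace = TRUE)
      expect_equal(weighted_region_score(m, cov), oracle_weighted_score(m, cov),
                   tolerance = 1e-12)
    }
  })
})

test_that("weighted score is invariant to CpG order and coverage scaling", {
  withr::with_seed(32, {
    m <- runif(30, 0, 100); cov <- sample(1:50, 30, replace = TRUE)
  })
  ref <- weighted_region_score(m, cov)
  p <- sample(30)
  expect_equal(weighted_region_score(m[p], cov[p]), ref)
  expect_equal(weighted_region_score(m, cov * 7L), ref)
})

test_that("element scoring enforces the minimum-CpG rule at the boundary", {
  # 8 CpGs in the first element, 7 in the second, 0 in the third
  pos <- c(seq(111, by = 10, length.out = 8), seq(1011, by = 10, length.out = 7))
  wt <- make_methylome(pos, 27L, 3L, id = "wt")
  mut <- make_methylome(pos, 15L, 15L, id = "mut")
  reps <- data.frame(chrom = "chr1", start = c(100L, 1000L, 5000L),
                     end = c(400L, 1400L, 5400L),
                     subfamily = c("IAPEY", "IAPEY", "RLTRETN"),
                     class_family = "LTR/ERVK", strand = ".")
  sc <- score_repeats(wt, mut, reps)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$n_cpgs, 8L)
  expect_equal(sc$meth_wt, 90)
  expect_equal(sc$meth_mut, 50)
  expect_equal(sc$delta, -40)
  expect_equal(attr(sc, "n_excluded"), 2L)

  expect_equal(nrow(score_repeats(wt, mut, reps[0, ])), 0)
})

test_that("recomputing a region score from raw inputs reproduces it exactly", {
  withr::with_seed(33, {
    pos <- sort(sample(seq(11, 99991, by = 10), 600))
    wt <- make_methylome(pos, rpois(600, 27), rpois(600, 3), id = "wt")
    mut <- make_methylome(pos, rpois(600, 20), rpois(600, 10), id = "mut")
  })
  reps <- data.frame(chrom = "chr1", start = seq(0, 90000, by = 10000),
                     end = seq(0, 90000, by = 10000) + 5000,
                     subfamily = "IAPEY", class_family = "LTR/ERVK")
  sc <- score_repeats(wt, mut, reps)
  q <- qualify_cpgs(wt, mut)
  for (i in seq_len(nrow(sc))) {
    inside <- q$pos - 1 >= sc$start[i] & q$pos - 1 < sc$end[i]
    expect_equal(sum(inside), sc$n_cpgs[i])
    expect_equal(weighted_region_score(q$meth_pct_wt[inside], q$cov_wt[inside]),
                 sc$meth_wt[i])
    expect_equal(weighted_region_score(q$meth_pct_mut[inside], q$cov_mut[inside]),
                 sc$meth_mut[i])
  }
})

test_that("window tiling covers each chromosome from zero with a short tail", {
  pos <- seq(11, 24001, by = 100)
  wt <- make_methylome(pos, 9L, 1L, id = "wt")
  mut <- make_methylome(pos, 9L, 1L, id = "mut")
  ws <- window_scores(wt, mut, c(chr1 = 25000L), window_size = 10000)
  expect_equal(ws$windows$start, c(0L, 10000L, 20000L))
  expect_equal(ws$windows$end, c(10000L, 20000L, 25000L))
  # constant methylome: every window and both medians at 90
  expect_equal(ws$windows$meth_wt, rep(90, 3))
  expect_equal(ws$median_wt, 90)
  expect_equal(ws$median_mut, 90)
  expect_error(window_scores(wt, mut, integer()), "empty genome")
})

test_that("windows without covered CpGs are absent from the output", {
  pos <- seq(11, 9901, by = 100)  # all CpGs in the first 10 kb
  wt <- make_methylome(pos, 9L, 1L, id = "wt")
  mut <- make_methylome(pos, 9L, 1L, id = "mut")
  ws <- window_scores(wt, mut, c(chr1 = 30000L), window_size = 10000)
  expect_equal(nrow(ws$windows), 1)
  expect_equal(ws$windows$start, 0L)
})

test_that("ICR summary scores and flags sperm purity", {
  pos <- seq(101, by = 10, length.out = 10)
  icrs <- data.frame(chrom = "chr1", start = 0L, end = 10000L,
                     name = "icr_1_maternal")
  # all unmethylated: score 0, purity TRUE
  wt <- make_methylome(pos, 0L, 10L, id = "wt")
  mut <- make_methylome(pos, 0L, 10L, id = "mut")
  s <- icr_summary(wt, mut, icrs)
  expect_equal(s$meth_wt, 0)
  expect_true(s$pure_wt)
  # fully methylated maternal ICR: purity FALSE
  wt2 <- make_methylome(pos, 10L, 0L, id = "wt")
  s2 <- icr_summary(wt2, mut, icrs)
  expect_equal(s2$meth_wt, 100)
  expect_false(s2$pure_wt)
  # mixed 1/1 at each CpG: 50 percent; paternal ICRs carry no flag
  wt3 <- make_methylome(pos, 1L, 1L, id = "wt")
  icrs$name <- "icr_1_paternal"
  s3 <- icr_summary(wt3, mut, icrs)
  expect_equal(s3$meth_wt, 50)
  expect_true(is.na(s3$pure_wt))
})
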