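fake_scores <- function(deltas, meth_wt = 60, subfamily = "IAPEY") {
  data.frame(chrom = "chr1",
             start = seq(0, by = 1000, length.out = length(deltas)),
             end = seq(700, by = 1000, length.out = length(deltas)),
             subfamily = rep_len(subfamily, length(deltas)),
             class_family = "LTR/ERVK", n_cpgs = 10L,
             meth_wt = rep_len(meth_wt, length(deltas)),
             meth_mut = rep_len(meth_wt, length(deltas)) + deltas,
             delta = deltas, stringsAsFactors = FALSE)
}

test_that("differential calling uses a strict threshold and mutant-relative direction", {
  sc <- fake_scores(c(-33, 10, -10.0001, 15, 0), meth_wt = 59)
  calls <- call_differential(sc, 10)
  expect_equal(nrow(calls), 3)
  expect_equal(as.character(calls$direction), c("hypo", "hypo", "hyper"))
  # the 59 -> 26 element is a hypo call
  expect_equal(calls$meth_mut[1], 26)
  # delta exactly +10 is not called
  expect_false(10 %in% calls$delta)
  expect_equal(attr(calls, "n_hypo"), 2L)
  expect_equal(attr(calls, "n_hyper"), 1L)
  expect_error(call_differential(sc, -1), "threshold")
})

test_that("calling partitions the DM set with no element counted twice", {
  withr::with_seed(41, deltas <- runif(300, -40, 40))
  sc <- fake_scores(deltas)
  calls <- call_differential(sc, 10)
  expect_equal(nrow(calls), sum(abs(deltas) > 10))
  expect_equal(attr(calls, "n_hypo") + attr(calls, "n_hyper"), nrow(calls))
  expect_false(any(duplicated(calls$start)))
})

test_that("subfamily counts sort, tie-break and truncate", {
  sc <- fake_scores(c(-15, -20, -30, 12, -18), subfamily = c("IAPEY", "IAPEY", "IAPEY", "IAPEY", "RLTRETN"))
  tab <- subfamily_counts(call_differential(sc))
  expect_equal(tab$subfamily, c("IAPEY", "RLTRETN"))
  expect_equal(tab$n_hypo, c(3L, 1L))
  expect_equal(tab$n_hyper, c(1L, 0L))

  expect_equal(nrow(subfamily_counts(call_differential(fake_scores(0)))), 0)

  # 25 subfamilies with distinct totals, top 20 kept; ties alphabetical
  deltas <- rep(-20, sum(1:25))
  subs <- rep(sprintf("sf%02d", 1:25), times = 1:25)
  tab <- subfamily_counts(call_differential(fake_scores(deltas, subfamily = subs)), top_n = 20)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$subfamily[1], "sf25")
  expect_false(any(sprintf("sf%02d", 1:5) %in% tab$subfamily))
  tie <- fake_scores(rep(-20, 4), subfamily = c("b", "a", "b", "a"))
  expect_equal(subfamily_counts(call_differential(tie))$subfamily, c("a", "b"))
})

test_that("shift test matches exhaustive enumeration on small samples", {
  sc <- data.frame(chrom = "chr1", start = 0:5 * 1000,
                   end = 0:5 * 1000 + 700, subfamily = "IAPEY",
                   class_family = "LTR/ERVK", n_cpgs = 10L,
                   meth_wt = c(4, 5, 6, 4, 5, 6),
                   meth_mut = c(1, 2, 3, 1, 2, 3), delta = -3)
  sc3 <- sc[1:3, ]
  res <- shift_test(sc3, scope = "all")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  oracle <- oracle_mw_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, oracle$U)
  expect_equal(res$p_value, oracle$p_value)

  # identical vectors: two-sided p ~ 1
  eq <- fake_scores(rep(0, 10), meth_wt = 50)
  expect_gt(shift_test(eq, scope = "all")$p_value, 0.99)
  expect_error(shift_test(eq[1, , drop = FALSE], scope = "all"), "fewer than 2")
})

test_that("shift test agrees with enumeration on random small inputs", {
  withr::with_seed(42, {
    for (i in 1:10) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      vals <- sample(1:100, n1 + n2)  # distinct -> no ties
      x <- vals[1:n1]; y <- vals[-(1:n1)]
      sc <- data.frame(chrom = "chr1", start = 0, end = 1, subfamily = "s",
                       class_family = "c", n_cpgs = 1L,
                       meth_wt = NA, meth_mut = NA, delta = 0)
      # exercise the internal test through equal-length vectors
      res <- repmeth:::mw_u_test(x, y)
      oracle <- oracle_mw_exact(x, y)
      expect_equal(res$U, oracle$U)
      expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12)
    }
  })
})

test_that("shift test is antisymmetric under swapping the samples", {
  withr::with_seed(43, {
    x <- runif(15, 0, 100); y <- runif(12, 0, 100)
  })
  a <- repmeth:::mw_u_test(x, y)
  b <- repmeth:::mw_u_test(y, x)
  expect_equal(a$U, length(x) * length(y) - b$U)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("TSS proximity counts by minimal element distance", {
  calls <- call_differential(fake_scores(-20))  # element [0, 700)
  tss <- data.frame(chrom = "chr1", pos = 5699L)  # 5000 bp beyond the end
  expect_equal(tss_proximity(calls, tss)$count, 1)
  tss <- data.frame(chrom = "chr1", pos = 10700L)  # 10001 bp away
  expect_equal(tss_proximity(calls, tss)$count, 0)
  tss <- data.frame(chrom = "chr1", pos = 350L)  # inside
  res <- tss_proximity(calls, tss)
  expect_equal(res$count, 1)
  expect_equal(res$calls$tss_distance, 0)
  expect_error(tss_proximity(calls, tss[0, ]), "empty")
})

test_that("TSS proximity is monotone in the distance cutoff", {
  withr::with_seed(44, {
    calls <- call_differential(fake_scores(runif(50, -40, -11)))
    tss <- data.frame(chrom = "chr1", pos = sample(0:60000, 20))
  })
  counts <- vapply(c(100, 1000, 5000, 10000, 50000),
                   function(d) tss_proximity(calls, tss, d)$count, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("random regions are seeded, length-proportional and validated", {
  cs <- c(chr1 = 1000000L, chr2 = 3000000L)
  r1 <- random_regions(cs, 1000, seed = 9)
  expect_identical(r1, random_regions(cs, 1000, seed = 9))
  expect_true(all(r1$end - r1$start == 1000))
  expect_true(all(r1$start >= 0))
  expect_true(all(r1$end <= cs[r1$chrom]))
  frac2 <- mean(random_regions(cs, 10000, seed = 10)$chrom == "chr2")
  expect_lt(abs(frac2 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  expect_error(random_regions(cs, 0, seed = 1), "n must be")
  expect_error(random_regions(c(chr1 = 500L), 5, length = 1000, seed = 1),
               "shorter")
})

test_that("control-class analysis on the target set reproduces the main analysis", {
  withr::with_seed(45, {
    pos <- sort(sample(seq(11, 99991, by = 10), 2000))
    wt <- make_methylome(pos, rpois(2000, 27), rpois(2000, 3), id = "wt")
    mut <- make_methylome(pos, rpois(2000, 20), rpois(2000, 10), id = "mut")
  })
  reps <- data.frame(chrom = "chr1", start = seq(0, 95000, by = 5000),
                     end = seq(0, 95000, by = 5000) + 3000,
                     subfamily = "IAPEY", class_family = "LTR/ERVK")
  main <- score_repeats(wt, mut, reps)
  ctrl <- control_class_analysis(wt, mut, reps, "self")
  expect_equal(ctrl$scores$meth_wt, main$meth_wt)
  expect_equal(ctrl$scores$delta, main$delta)
  expect_equal(ctrl$label, "self")
  expect_error(control_class_analysis(wt, mut, reps[0, ], "x"), "empty")
})
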