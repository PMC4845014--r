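# Independent reference implementations used to cross-check the package.
# These are deliberately naive (explicit loops, enumeration, closed forms)
# and share no code with the implementation under test.

# brute-force coverage-weighted score: explicit loop
oracle_weighted_score <- function(meth_pct, cov) {
  num <- 0; den <- 0
  for (i in seq_along(meth_pct)) {
    num <- num + meth_pct[i] * cov[i]
    den <- den + cov[i]
  }
  num / den
}

# Mann-Whitney U and exact two-sided p by exhaustive enumeration of all
# choose(n1 + n2, n1) rank assignments (no ties assumed)
oracle_mw_exact <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  n1 <- length(x); n2 <- length(y)
  combined <- c(x, y)
  idx_sets <- utils::combn(n1 + n2, n1)
  us <- apply(idx_sets, 2, function(ix)
    u_stat(combined[ix], combined[-ix]))
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p_value = p)
}

# Pearson chi-squared on a 2 x k table, textbook closed form
oracle_pearson_2xk <- function(a, b) {
  tab <- rbind(a, b)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Welch two-sample t, closed form
oracle_welch_t <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# build a small methylome from vectors without going through files
make_methylome <- function(pos, meth, unmeth, chrom = "chr1", id = "s") {
  methylome(rep(chrom, length(pos)), pos, rep_len(meth, length(pos)),
            rep_len(unmeth, length(pos)), id)
}

# a small deterministic two-sample fixture: CpGs every 10 bp
make_pair <- function(n = 20, cov_wt = 30, cov_mut = 30, pct_wt = 90,
                      pct_mut = 90, chrom = "chr1", start_pos = 11) {
  pos <- seq(start_pos, by = 10, length.out = n)
  wt <- make_methylome(pos, round(cov_wt * pct_wt / 100),
                       cov_wt - round(cov_wt * pct_wt / 100), chrom, "wt")
  mut <- make_methylome(pos, round(cov_mut * pct_mut / 100),
                        cov_mut - round(cov_mut * pct_mut / 100), chrom, "mut")
  list(wt = wt, mut = mut, pos = pos)
}
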