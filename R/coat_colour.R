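#' Five-category coat-colour classification
#'
#' Maps the percentage of yellow coat on an agouti viable yellow (Avy)
#' carrier to the five-category score used for metastable-epiallele
#' expressivity: yellow (100% yellow), yellow-mottled (>95%), mottled
#' (more than 25% and at most 95% yellow), pseudoagouti-mottled
#' (5-25% yellow, i.e. 75-95% agouti) and pseudoagouti (<5% yellow,
#' i.e. >95% agouti). Boundaries are half-open by convention; in
#' practice the assignment is made by a trained observer and the
#' formula fixes the edge cases deterministically.
#'
#' @param percent_yellow Numeric in \[0, 100\].
#' @return Factor with levels `yellow`, `yellow_mottled`, `mottled`,
#'   `pseudoagouti_mottled`, `pseudoagouti`.
#' @export
categorize_coat <- function(percent_yellow) {
  if (any(percent_yellow < 0 | percent_yellow > 100))
    stop_argument("categorize_coat: percent_yellow outside [0, 100]")
  lv <- c("yellow", "yellow_mottled", "mottled",
          "pseudoagouti_mottled", "pseudoagouti")
  out <- ifelse(percent_yellow == 100, "yellow",
         ifelse(percent_yellow > 95, "yellow_mottled",
         ifelse(percent_yellow > 25, "mottled",
         ifelse(percent_yellow >= 5, "pseudoagouti_mottled",
                "pseudoagouti"))))
  factor(out, levels = lv)
}

#' Pool five coat categories into three penetrance groups
#'
#' Y = yellow and yellow-mottled, M = mottled, psi = pseudoagouti-mottled
#' and pseudoagouti.
#'
#' @param category5 Factor or character vector of five-category scores.
#' @return Factor with levels `Y`, `M`, `psi`.
#' @export
pool_categories <- function(category5) {
  map <- c(yellow = "Y", yellow_mottled = "Y", mottled = "M",
           pseudoagouti_mottled = "psi", pseudoagouti = "psi")
  v <- as.character(category5)
  if (any(!v %in% names(map)))
    stop_argument("pool_categories: unknown category '%s'",
                  v[!v %in% names(map)][1])
  factor(unname(map[v]), levels = c("Y", "M", "psi"))
}

#' Pearson chi-squared test on a 2x3 penetrance table
#'
#' Compares two groups' pooled Y/M/psi counts with a plain Pearson
#' chi-squared test (no continuity correction, no exact test). Columns
#' that are empty in both groups are collapsed out, reducing the
#' degrees of freedom, and the reduction is reported. A warning flag is
#' set when any expected count is below 5.
#'
#' @param a,b Numeric vectors of category counts (same length, usually
#'   3, ordered Y, M, psi).
#' @return A list: `chi2`, `df`, `p_value`, `expected_lt5` (logical),
#'   `table` (the 2 x k matrix tested).
#' @export
chi_squared_2x3 <- function(a, b) {
  if (length(a) != length(b))
    stop_argument("chi_squared_2x3: category vectors differ in length")
  if (any(a < 0) || any(b < 0))
    stop_argument("chi_squared_2x3: negative counts")
  if (sum(a) == 0 || sum(b) == 0)
    stop_argument("chi_squared_2x3: a group has total count 0")
  tab <- rbind(a = as.numeric(a), b = as.numeric(b))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2)
    stop_argument("chi_squared_2x3: fewer than 2 non-empty categories")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected_lt5 = any(ht$expected < 5),
       table = tab)
}

#' Goodness-of-fit test against Mendelian ratios
#'
#' Chi-squared goodness-of-fit of observed genotype counts against
#' expected Mendelian proportions (e.g. 1:1 for a het x wt cross).
#'
#' @param genotype_counts Named numeric vector of observed counts.
#' @param expected_ratio Named numeric vector of positive weights; names
#'   must cover the observed genotypes.
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
mendelian_test <- function(genotype_counts, expected_ratio) {
  if (sum(genotype_counts) == 0)
    stop_argument("mendelian_test: no observations")
  if (any(expected_ratio <= 0))
    stop_argument("mendelian_test: non-positive expected weight")
  if (!all(names(genotype_counts) %in% names(expected_ratio)))
    stop_argument("mendelian_test: missing genotype key in expected_ratio")
  w <- expected_ratio[names(genotype_counts)]
  ht <- suppressWarnings(chisq.test(as.numeric(genotype_counts),
                                    p = as.numeric(w) / sum(w)))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Penetrance report for coat-colour cohorts
#'
#' Tabulates pooled Y/M/psi counts and proportions per group and runs
#' all pairwise chi-squared comparisons. Records must already be
#' restricted to Avy carriers (non-carriers show no yellow and are
#' excluded from penetrance by convention).
#'
#' @param records Data.frame with a `category5` column (values as in
#'   [categorize_coat()]) and a grouping column.
#' @param group_var Name of the grouping column (default `"cross_id"`).
#' @return A list: `counts` (group x Y/M/psi matrix), `proportions`,
#'   `comparisons` (data.frame of pairwise chi-squared results).
#' @export
penetrance_report <- function(records, group_var = "cross_id") {
  if (!group_var %in% names(records))
    stop_argument("penetrance_report: no column '%s'", group_var)
  if (nrow(records) == 0) stop_argument("penetrance_report: no records")
  pooled <- pool_categories(records$category5)
  groups <- as.character(records[[group_var]])
  counts <- table(group = groups, pooled = pooled)
  if (any(rowSums(counts) == 0)) stop_argument("penetrance_report: empty group")
  props <- counts / rowSums(counts)
  gs <- rownames(counts)
  comparisons <- NULL
  if (length(gs) >= 2) {
    pairs <- utils::combn(gs, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      ht <- chi_squared_2x3(counts[g1, ], counts[g2, ])
      data.frame(group_a = g1, group_b = g2, chi2 = ht$chi2, df = ht$df,
                 p_value = ht$p_value, expected_lt5 = ht$expected_lt5,
                 stringsAsFactors = FALSE)
    }))
  }
  list(counts = unclass(counts), proportions = unclass(props),
       comparisons = comparisons)
}

#' Read a coat-colour cohort table
#'
#' One row per animal: animal_id, cross_id, sire_genotype, dam_genotype,
#' offspring_genotype, avy_parent, category5.
#'
#' @param path Path to the cohort TSV.
#' @return Data.frame of cohort records.
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop_parse("cohort file not found: %s", path)
  as.data.frame(fread(path, sep = "\t", header = TRUE,
                      colClasses = "character"))
}
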