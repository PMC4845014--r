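#' Call differentially methylated elements
#'
#' Flags region scores whose wild-type/mutant difference exceeds the
#' threshold, strictly: `|delta| > threshold_pp`. Direction is defined
#' relative to the mutant: `hypo` means the mutant is lower
#' (`delta < 0`), `hyper` that it is higher.
#'
#' @param scores Data.frame from [score_repeats()].
#' @param threshold_pp Threshold in percentage points (default 10).
#' @return The called rows with a `direction` factor column. Attributes
#'   `n_hypo` and `n_hyper` carry the direction counts.
#' @export
call_differential <- function(scores, threshold_pp = 10) {
  if (!is.numeric(threshold_pp) || threshold_pp < 0)
    stop_argument("call_differential: threshold_pp must be >= 0")
  called <- scores[abs(scores$delta) > threshold_pp, , drop = FALSE]
  called$direction <- factor(ifelse(called$delta < 0, "hypo", "hyper"),
                             levels = c("hypo", "hyper"))
  rownames(called) <- NULL
  attr(called, "n_hypo") <- sum(called$direction == "hypo")
  attr(called, "n_hyper") <- sum(called$direction == "hyper")
  attr(called, "threshold_pp") <- threshold_pp
  called
}

#' Subfamily composition of differential calls
#'
#' Counts calls per repeat subfamily, split by direction, sorted by
#' total count descending (ties broken alphabetically) and truncated to
#' the `top_n` most frequent subfamilies.
#'
#' @param calls Output of [call_differential()]; rows must carry a
#'   `subfamily` column.
#' @param top_n Number of subfamilies to keep (default 20).
#' @return Data.frame with columns `subfamily`, `n_hypo`, `n_hyper`,
#'   `total`.
#' @export
subfamily_counts <- function(calls, top_n = 20) {
  empty <- data.frame(subfamily = character(), n_hypo = integer(),
                      n_hyper = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  dt <- data.table(subfamily = calls$subfamily, direction = calls$direction)
  tab <- dt[, .(n_hypo = sum(direction == "hypo"),
                n_hyper = sum(direction == "hyper")), by = subfamily]
  tab[, total := n_hypo + n_hyper]
  setorder(tab, -total, subfamily)
  as.data.frame(head(tab, top_n))
}

#' Mann-Whitney test for a methylation distribution shift
#'
#' Compares the vector of mutant element scores against the vector of
#' wild-type element scores with a two-sample Mann-Whitney (Wilcoxon
#' rank-sum) test. Ties are handled by midranks; for small samples
#' (both groups at most 20, no ties) the exact distribution is used,
#' otherwise the normal approximation with tie correction. The reported
#' U statistic counts mutant-over-wild-type pairs.
#'
#' @param scores Data.frame from [score_repeats()].
#' @param scope `"dm_subset"` (elements with `|delta|` above
#'   `threshold_pp`, the default) or `"all"`.
#' @param alternative Passed to the test: `"two.sided"` (default),
#'   `"less"` or `"greater"`, for the mutant relative to the wild type.
#' @param threshold_pp Threshold defining the DM subset (default 10).
#' @return A list with `U`, `p_value`, `n` (elements in scope), `scope`,
#'   `alternative`.
#' @export
shift_test <- function(scores, scope = c("dm_subset", "all"),
                       alternative = c("two.sided", "less", "greater"),
                       threshold_pp = 10) {
  scope <- match.arg(scope)
  alternative <- match.arg(alternative)
  sub <- if (scope == "dm_subset")
    scores[abs(scores$delta) > threshold_pp, , drop = FALSE] else scores
  if (nrow(sub) < 2)
    stop_argument("shift_test: fewer than 2 elements in scope '%s'", scope)
  mw_u_test(sub$meth_mut, sub$meth_wt, alternative = alternative,
            scope = scope)
}

# Mann-Whitney on two raw vectors; x is the mutant-side vector
mw_u_test <- function(x, y, alternative = "two.sided", scope = NULL) {
  if (length(unique(c(x, y))) == 1) {
    # every observation tied: no evidence of a shift by convention
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                n = length(x), scope = scope, alternative = alternative))
  }
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = FALSE))
  list(U = unname(ht$statistic), p_value = ht$p.value,
       n = length(x), scope = scope, alternative = alternative)
}

#' Count differential calls near transcription start sites
#'
#' A call is proximal when the minimal distance between its element
#' interval and any TSS point is at most `max_distance` bp; a TSS inside
#' the element has distance 0.
#'
#' @param calls Output of [call_differential()].
#' @param tss Data.frame of TSS points with columns `chrom` and `pos`
#'   (0-based position, e.g. the `start` of a BED4 row).
#' @param max_distance Distance cutoff in bp (default 10000).
#' @return A list: `count` of proximal calls, and `calls` with added
#'   `tss_distance` (NA when no TSS shares the chromosome) and
#'   `tss_proximal` columns.
#' @export
tss_proximity <- function(calls, tss, max_distance = 10000) {
  if (nrow(tss) == 0) stop_argument("tss_proximity: TSS list is empty")
  dist_one <- function(chrom, s, e) {
    p <- tss$pos[tss$chrom == chrom]
    if (length(p) == 0) return(NA_real_)
    # 0-based half-open element [s, e); inside -> 0
    d <- ifelse(p >= s & p < e, 0, ifelse(p < s, s - p, p - (e - 1)))
    min(d)
  }
  d <- if (nrow(calls)) mapply(dist_one, calls$chrom, calls$start, calls$end)
       else numeric()
  calls$tss_distance <- as.numeric(d)
  calls$tss_proximal <- !is.na(d) & d <= max_distance
  list(count = sum(calls$tss_proximal), calls = calls)
}

#' Draw random fixed-length genomic regions
#'
#' Chromosomes are chosen with probability proportional to their
#' length; start positions are uniform over the valid starts. Draws are
#' seeded and reproducible.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n Number of regions.
#' @param length Region length in bp (default 1000).
#' @param seed Integer seed (required).
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
random_regions <- function(chrom_sizes, n, length = 1000, seed) {
  if (!is.numeric(n) || n <= 0) stop_argument("random_regions: n must be > 0")
  if (missing(seed)) stop_argument("random_regions: seed is required")
  if (any(chrom_sizes < length))
    stop_argument("random_regions: a chromosome is shorter than the region length")
  with_seed(seed, {
    idx <- sample.int(length(chrom_sizes), n, replace = TRUE,
                      prob = as.numeric(chrom_sizes))
    starts <- floor(runif(n) * (as.numeric(chrom_sizes[idx]) - length + 1))
  })
  data.frame(chrom = names(chrom_sizes)[idx], start = as.integer(starts),
             end = as.integer(starts + length), stringsAsFactors = FALSE)
}

#' Control-class analysis
#'
#' Runs the full element-level analysis (scoring with identical filters,
#' differential calling, shift test) on a control annotation such as
#' LINE1 or B1 elements or random regions, and tags the result bundle
#' with a label.
#'
#' @inheritParams score_repeats
#' @param annotation Data.frame of control intervals (`chrom`, `start`,
#'   `end`, optional labels).
#' @param label Character tag for the bundle.
#' @param threshold_pp DM threshold in percentage points (default 10).
#' @param scope Scope for the shift test (default `"all"`; the DM subset
#'   of a control class is often empty).
#' @return A list: `label`, `scores`, `calls`, `shift`,
#'   `fraction_dm` (fraction of scored elements with `|delta|` above the
#'   threshold).
#' @export
control_class_analysis <- function(wt, mut, annotation, label,
                                   min_cpgs = 8, min_cov = 8,
                                   bias_fraction = 0.6, threshold_pp = 10,
                                   scope = "all") {
  if (nrow(annotation) == 0)
    stop_argument("control_class_analysis: empty annotation")
  scores <- score_repeats(wt, mut, annotation, min_cpgs = min_cpgs,
                          min_cov = min_cov, bias_fraction = bias_fraction)
  calls <- call_differential(scores, threshold_pp)
  shift <- shift_test(scores, scope = scope, threshold_pp = threshold_pp)
  list(label = label, scores = scores, calls = calls, shift = shift,
       fraction_dm = if (nrow(scores)) nrow(calls) / nrow(scores) else NA_real_)
}

#' Write differential calls as BED6+4
#'
#' Columns: chrom, start, end, subfamily, delta, strand, direction,
#' n_cpgs, meth_wt, meth_mut.
#'
#' @param calls Output of [call_differential()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_bed <- function(calls, path) {
  strand <- if ("strand" %in% names(calls)) calls$strand else rep(".", nrow(calls))
  dt <- data.table(calls$chrom, calls$start, calls$end, calls$subfamily,
                   round(calls$delta, 4), strand, as.character(calls$direction),
                   calls$n_cpgs, round(calls$meth_wt, 4),
                   round(calls$meth_mut, 4))
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
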