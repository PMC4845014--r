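#' Join two methylomes and apply the CpG qualification rules
#'
#' A CpG qualifies for repeat-level scoring when it is covered in both
#' samples with at least `min_cov` reads each, and the coverages are not
#' badly imbalanced: under the default (literal) rule the sample with
#' the lower coverage must reach at least `bias_fraction` of the
#' coverage in the other sample. The alternative `"deviation"` reading
#' (relative coverage difference at most `bias_fraction`) is available
#' as a switch.
#'
#' @param wt,mut [methylome()] objects (strand-merged).
#' @param region Optional single interval `list(chrom=, start=, end=)`
#'   (0-based half-open) restricting the CpGs considered; `NULL` keeps
#'   the whole genome.
#' @param min_cov Minimum coverage per sample (default 8).
#' @param bias_fraction Coverage-balance fraction in (0, 1] (default 0.6).
#' @param bias_rule `"ratio"` (literal: `min >= bias_fraction * max`) or
#'   `"deviation"` (`(max - min) / max <= bias_fraction`).
#' @return Data.frame of qualified CpGs: `chrom`, `pos`, `cov_wt`,
#'   `cov_mut`, `meth_pct_wt`, `meth_pct_mut`.
#' @export
qualify_cpgs <- function(wt, mut, region = NULL, min_cov = 8,
                         bias_fraction = 0.6,
                         bias_rule = c("ratio", "deviation")) {
  bias_rule <- match.arg(bias_rule)
  if (!is.numeric(min_cov) || min_cov < 1)
    stop_argument("qualify_cpgs: min_cov must be >= 1")
  if (!is.numeric(bias_fraction) || bias_fraction <= 0 || bias_fraction > 1)
    stop_argument("qualify_cpgs: bias_fraction must be in (0, 1]")
  j <- join_samples(wt, mut)
  if (!is.null(region)) {
    # 0-based half-open containment of the 1-based plus-strand C: the C at
    # 1-based pos p occupies 0-based coordinate p - 1
    j <- j[j$chrom == region$chrom & j$pos - 1L >= region$start &
             j$pos - 1L < region$end, ]
  }
  keep <- j$cov_wt >= min_cov & j$cov_mut >= min_cov
  lo <- pmin(j$cov_wt, j$cov_mut); hi <- pmax(j$cov_wt, j$cov_mut)
  # small tolerance so integer boundary cases (e.g. 6 vs 0.6 * 10) are not
  # decided by floating-point representation
  eps <- 1e-9
  keep <- keep & if (bias_rule == "ratio") lo >= bias_fraction * hi - eps
                 else (hi - lo) <= bias_fraction * hi + eps
  out <- j[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

join_samples <- function(wt, mut) {
  a <- as.data.table(as.data.frame(unclass(wt)))
  b <- as.data.table(as.data.frame(unclass(mut)))
  setnames_safe(a, c("meth", "unmeth"), c("meth_wt", "unmeth_wt"))
  setnames_safe(b, c("meth", "unmeth"), c("meth_mut", "unmeth_mut"))
  j <- merge(a, b, by = c("chrom", "pos"))
  j[, cov_wt := meth_wt + unmeth_wt]
  j[, cov_mut := meth_mut + unmeth_mut]
  j <- j[cov_wt > 0 & cov_mut > 0]
  j[, meth_pct_wt := 100 * meth_wt / cov_wt]
  j[, meth_pct_mut := 100 * meth_mut / cov_mut]
  as.data.frame(j[, .(chrom, pos, cov_wt, cov_mut, meth_pct_wt, meth_pct_mut)])
}

setnames_safe <- function(dt, old, new) data.table::setnames(dt, old, new)

#' Coverage-weighted mean methylation of a region
#'
#' Each CpG's methylation percentage is weighted by its own read count:
#' the score is `sum(meth_pct * cov) / sum(cov)`.
#'
#' @param meth_pct Numeric vector of per-CpG methylation percentages.
#' @param cov Positive read counts, one per CpG.
#' @return The weighted score (percent).
#' @export
weighted_region_score <- function(meth_pct, cov) {
  if (length(meth_pct) == 0)
    stop_argument("weighted_region_score: empty CpG sequence, score undefined")
  if (length(meth_pct) != length(cov))
    stop_argument("weighted_region_score: length mismatch")
  if (any(cov <= 0))
    stop_argument("weighted_region_score: coverages must be positive")
  sum(meth_pct * cov) / sum(cov)
}

#' Score repeat elements in two samples
#'
#' Applies the CpG qualification rules ([qualify_cpgs()]), then computes
#' a coverage-weighted methylation score per element and per sample,
#' each sample weighted by its own per-CpG coverages. Elements with
#' fewer than `min_cpgs` qualifying CpGs are excluded (never imputed)
#' and counted in the `n_excluded` attribute. Overlapping or duplicate
#' elements are scored independently.
#'
#' @inheritParams qualify_cpgs
#' @param repeats Data.frame of elements with columns `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `subfamily`,
#'   `class_family`, `strand` ([read_repeat_annotation()] layout).
#' @param min_cpgs Minimum number of qualifying CpGs per element
#'   (default 8).
#' @return Data.frame of region scores: element coordinates and labels,
#'   `n_cpgs`, `meth_wt`, `meth_mut`, `delta` (`meth_mut - meth_wt`, in
#'   percentage points). Attribute `n_excluded` counts elements dropped
#'   by the `min_cpgs` rule.
#' @export
score_repeats <- function(wt, mut, repeats, min_cpgs = 8, min_cov = 8,
                          bias_fraction = 0.6,
                          bias_rule = c("ratio", "deviation")) {
  bias_rule <- match.arg(bias_rule)
  if (!is.numeric(min_cpgs) || min_cpgs < 1)
    stop_argument("score_repeats: min_cpgs must be >= 1")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      subfamily = character(), class_family = character(),
                      n_cpgs = integer(), meth_wt = numeric(),
                      meth_mut = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(repeats) == 0) {
    attr(empty, "n_excluded") <- 0L
    return(empty)
  }
  validate_intervals(repeats$start, repeats$end,
                     if ("strand" %in% names(repeats)) repeats$strand
                     else rep(".", nrow(repeats)), "repeats")
  q <- qualify_cpgs(wt, mut, region = NULL, min_cov = min_cov,
                    bias_fraction = bias_fraction, bias_rule = bias_rule)
  scores <- score_regions_weighted(q, repeats, min_cpgs)
  if (!"subfamily" %in% names(repeats)) repeats$subfamily <- NA_character_
  if (!"class_family" %in% names(repeats)) repeats$class_family <- NA_character_
  out <- cbind(repeats[scores$region_idx,
                       c("chrom", "start", "end", "subfamily", "class_family"),
                       drop = FALSE],
               scores[c("n_cpgs", "meth_wt", "meth_mut", "delta")])
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nrow(repeats) - nrow(out)
  attr(out, "region_idx") <- scores$region_idx
  out
}

# shared region-scoring core: overlap qualified CpGs with 0-based
# half-open intervals and compute per-region weighted scores per sample
score_regions_weighted <- function(q, regions, min_cpgs) {
  if (nrow(q) == 0 || nrow(regions) == 0) {
    return(data.frame(region_idx = integer(), n_cpgs = integer(),
                      meth_wt = numeric(), meth_mut = numeric(),
                      delta = numeric()))
  }
  cpg_gr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$pos, q$pos))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(cpg_gr, reg_gr, type = "within")
  if (length(hits) == 0) {
    return(data.frame(region_idx = integer(), n_cpgs = integer(),
                      meth_wt = numeric(), meth_mut = numeric(),
                      delta = numeric()))
  }
  dt <- data.table(region_idx = S4Vectors::subjectHits(hits),
                   mw = q$meth_pct_wt[S4Vectors::queryHits(hits)],
                   cw = q$cov_wt[S4Vectors::queryHits(hits)],
                   mm = q$meth_pct_mut[S4Vectors::queryHits(hits)],
                   cm = q$cov_mut[S4Vectors::queryHits(hits)])
  agg <- dt[, .(n_cpgs = .N,
                meth_wt = sum(mw * cw) / sum(cw),
                meth_mut = sum(mm * cm) / sum(cm)), by = region_idx]
  agg <- agg[n_cpgs >= min_cpgs]
  agg[, delta := meth_mut - meth_wt]
  setorder(agg, region_idx)
  as.data.frame(agg)
}

# single-sample weighted region scores over the sample's own covered CpGs
score_regions_single <- function(sample, regions, min_cov = 1) {
  s <- as.data.frame(unclass(sample))
  s$cov <- s$meth + s$unmeth
  s <- s[s$cov >= min_cov, , drop = FALSE]
  if (nrow(s) == 0 || nrow(regions) == 0) {
    return(data.frame(region_idx = integer(), n_cpgs = integer(),
                      score = numeric()))
  }
  cpg_gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(cpg_gr, reg_gr, type = "within")
  if (length(hits) == 0) {
    return(data.frame(region_idx = integer(), n_cpgs = integer(),
                      score = numeric()))
  }
  dt <- data.table(region_idx = S4Vectors::subjectHits(hits),
                   m = 100 * s$meth[S4Vectors::queryHits(hits)] /
                       s$cov[S4Vectors::queryHits(hits)],
                   cov = s$cov[S4Vectors::queryHits(hits)])
  agg <- dt[, .(n_cpgs = .N, score = sum(m * cov) / sum(cov)),
            by = region_idx]
  setorder(agg, region_idx)
  as.data.frame(agg)
}

#' Average methylation in fixed-width genome windows
#'
#' Tiles every chromosome with non-overlapping windows starting at
#' coordinate 0 (the final window of a chromosome may be shorter) and
#' computes the coverage-weighted methylation of each window per sample.
#' This global view precedes the repeat-level filtering, so the
#' two-sample filters are relaxed: every covered CpG counts
#' (`min_cov = 1`, no coverage-bias rule), and windows with fewer than
#' `min_cpgs` covered CpGs in either sample are dropped.
#'
#' @inheritParams qualify_cpgs
#' @param chrom_sizes Named vector of chromosome lengths
#'   ([read_chrom_sizes()]).
#' @param window_size Window width in bp (default 10000).
#' @param min_cpgs Minimum covered CpGs per window per sample (default 1).
#' @param min_cov Minimum per-sample coverage for a CpG to count
#'   (default 1).
#' @return A list: `windows` (data.frame `chrom`, `start`, `end`,
#'   `n_cpgs`, `meth_wt`, `meth_mut`), `median_wt`, `median_mut`
#'   (medians of the per-window scores over included windows).
#' @export
window_scores <- function(wt, mut, chrom_sizes, window_size = 10000L,
                          min_cpgs = 1L, min_cov = 1L) {
  if (length(chrom_sizes) == 0) stop_argument("window_scores: empty genome table")
  if (window_size <= 0) stop_argument("window_scores: window_size must be > 0")
  tiles <- do.call(rbind, lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = cn, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, len)),
               stringsAsFactors = FALSE)
  }))
  sw <- score_regions_single(wt, tiles, min_cov)
  sm <- score_regions_single(mut, tiles, min_cov)
  j <- merge(sw, sm, by = "region_idx", suffixes = c("_wt", "_mut"))
  j <- j[j$n_cpgs_wt >= min_cpgs & j$n_cpgs_mut >= min_cpgs, , drop = FALSE]
  windows <- cbind(tiles[j$region_idx, , drop = FALSE],
                   data.frame(n_cpgs_wt = j$n_cpgs_wt,
                              n_cpgs_mut = j$n_cpgs_mut,
                              meth_wt = j$score_wt, meth_mut = j$score_mut))
  rownames(windows) <- NULL
  list(windows = windows,
       median_wt = median(windows$meth_wt),
       median_mut = median(windows$meth_mut),
       n_windows = nrow(windows))
}

#' Per-ICR methylation summary and sperm purity check
#'
#' Scores each imprinting control region with the coverage-weighted mean
#' over all covered CpGs (no two-sample coverage filters) and flags
#' purity: in sperm, maternally methylated ICRs are expected to be
#' hypomethylated, so a maternal ICR scoring below `purity_threshold`
#' percent in a sample passes the purity check.
#'
#' @inheritParams qualify_cpgs
#' @param icrs Data.frame with `chrom`, `start`, `end`, `name`, where
#'   `name` contains "maternal" or "paternal" ([read_bed4()] layout).
#' @param purity_threshold Percent threshold for the maternal-ICR purity
#'   flag (default 15).
#' @return Data.frame: ICR coordinates and label, `n_cpgs`, `meth_wt`,
#'   `meth_mut`, and logical `pure_wt`, `pure_mut` (TRUE for maternal
#'   ICRs below the threshold; NA for paternal ICRs).
#' @export
icr_summary <- function(wt, mut, icrs, purity_threshold = 15) {
  validate_intervals(icrs$start, icrs$end, rep(".", nrow(icrs)), "ICRs")
  sw <- score_regions_single(wt, icrs, min_cov = 1)
  sm <- score_regions_single(mut, icrs, min_cov = 1)
  j <- merge(sw, sm, by = "region_idx", suffixes = c("_wt", "_mut"))
  out <- cbind(icrs[j$region_idx, , drop = FALSE],
               data.frame(n_cpgs_wt = j$n_cpgs_wt, n_cpgs_mut = j$n_cpgs_mut,
                          meth_wt = j$score_wt, meth_mut = j$score_mut))
  rownames(out) <- NULL
  maternal <- grepl("maternal", out$name, ignore.case = TRUE)
  out$pure_wt <- ifelse(maternal, out$meth_wt < purity_threshold, NA)
  out$pure_mut <- ifelse(maternal, out$meth_mut < purity_threshold, NA)
  out
}
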