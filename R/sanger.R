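#' Construct a clone matrix
#'
#' Holds the clone-by-CpG methylation calls from Sanger sequencing of
#' bisulphite-converted DNA for one amplicon in one individual, together
#' with the non-CpG cytosine conversion counts used for QC.
#'
#' @param calls Matrix (clones x CpG positions) with entries 1
#'   (methylated), 0 (unmethylated) or NA (missing call).
#' @param amplicon_id,individual_id Identifiers.
#' @param genotype `"wt"` or `"mut"`.
#' @param non_cpg_c_total,non_cpg_c_converted Non-CpG cytosines observed
#'   and converted, for the conversion-rate QC.
#' @return An object of class `clone_matrix`.
#' @export
clone_matrix <- function(calls, amplicon_id, individual_id,
                         genotype = c("wt", "mut"),
                         non_cpg_c_total = 0L, non_cpg_c_converted = 0L) {
  genotype <- match.arg(genotype)
  calls <- as.matrix(calls)
  if (length(calls) == 0) stop_validation("clone_matrix: empty call matrix")
  if (!all(calls %in% c(0, 1, NA)))
    stop_validation("clone_matrix: calls must be 0, 1 or NA")
  if (non_cpg_c_converted > non_cpg_c_total)
    stop_validation("clone_matrix: converted count exceeds total")
  structure(list(calls = calls, amplicon_id = amplicon_id,
                 individual_id = individual_id, genotype = genotype,
                 non_cpg_c_total = as.integer(non_cpg_c_total),
                 non_cpg_c_converted = as.integer(non_cpg_c_converted)),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("<clone_matrix> %s / %s (%s): %d clones x %d CpGs\n",
              x$amplicon_id, x$individual_id, x$genotype,
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Bisulphite conversion rate of a clone matrix
#'
#' The fraction of non-CpG cytosines that were converted, as a
#' percentage. Runs below 97% conversion are conventionally rejected.
#'
#' @param m A [clone_matrix()].
#' @param threshold QC threshold in percent (default 97); rates at or
#'   above the threshold pass.
#' @return A list: `rate` (percent) and logical `pass`.
#' @export
conversion_rate <- function(m, threshold = 97) {
  if (m$non_cpg_c_total == 0)
    stop_argument("conversion_rate: no non-CpG cytosines observed, rate undefined")
  rate <- 100 * m$non_cpg_c_converted / m$non_cpg_c_total
  list(rate = rate, pass = rate >= threshold)
}

#' Per-individual methylation percentage
#'
#' Pools all clones of the individual: 100 x methylated calls /
#' non-missing calls. Missing calls enter neither numerator nor
#' denominator.
#'
#' @param m A [clone_matrix()].
#' @return Percentage of methylated CpG calls.
#' @export
individual_percent <- function(m) {
  n_called <- sum(!is.na(m$calls))
  if (n_called == 0)
    stop_argument("individual_percent: all calls missing, percent undefined")
  100 * sum(m$calls, na.rm = TRUE) / n_called
}

#' Between-genotype t-test on individual methylation percentages
#'
#' Two-sided t-test comparing per-individual methylation percentages
#' between genotypes; Welch (unequal variance) by default, with a
#' pooled-variance option. When both groups have zero variance and
#' equal means, p = 1 by convention.
#'
#' @param wt_percents,mut_percents Numeric vectors of per-individual
#'   percentages, at least 2 per group.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list: `t`, `p_value`, `df`, `mean_wt`, `mean_mut`.
#' @export
genotype_ttest <- function(wt_percents, mut_percents, var_equal = FALSE) {
  if (length(wt_percents) < 2 || length(mut_percents) < 2)
    stop_argument("genotype_ttest: at least 2 individuals per group required")
  if (stats::var(wt_percents) == 0 && stats::var(mut_percents) == 0) {
    if (mean(wt_percents) == mean(mut_percents)) {
      return(list(t = 0, p_value = 1, df = NA_real_,
                  mean_wt = mean(wt_percents), mean_mut = mean(mut_percents)))
    }
    return(list(t = Inf * sign(mean(mut_percents) - mean(wt_percents)),
                p_value = 0, df = NA_real_,
                mean_wt = mean(wt_percents), mean_mut = mean(mut_percents)))
  }
  ht <- t.test(mut_percents, wt_percents, var.equal = var_equal)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_wt = mean(wt_percents), mean_mut = mean(mut_percents))
}

#' Read / write clone matrices as TSV
#'
#' Layout: columns amplicon, individual, genotype, clone, then one
#' column per CpG with values 1/0/NA. Conversion counts live in a
#' side-car TSV (`<path>.conversion.tsv`) with columns amplicon,
#' individual, non_cpg_c_total, non_cpg_c_converted.
#'
#' @param matrices List of [clone_matrix()] objects.
#' @param path Output path for the call table.
#' @return `path`, invisibly.
#' @export
write_clone_tsv <- function(matrices, path) {
  n_cpg <- unique(vapply(matrices, function(m) ncol(m$calls), 1L))
  if (length(n_cpg) != 1)
    stop_argument("write_clone_tsv: matrices have differing CpG counts")
  rows <- rbindlist(lapply(matrices, function(m) {
    cbind(data.table(amplicon = m$amplicon_id, individual = m$individual_id,
                     genotype = m$genotype, clone = seq_len(nrow(m$calls))),
          as.data.table(m$calls))
  }))
  fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
  side <- rbindlist(lapply(matrices, function(m) {
    data.table(amplicon = m$amplicon_id, individual = m$individual_id,
               non_cpg_c_total = m$non_cpg_c_total,
               non_cpg_c_converted = m$non_cpg_c_converted)
  }))
  fwrite(side, paste0(path, ".conversion.tsv"), sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_clone_tsv
#' @export
read_clone_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  side_path <- paste0(path, ".conversion.tsv")
  side <- if (file.exists(side_path)) fread(side_path, sep = "\t") else NULL
  keys <- unique(dt[, .(amplicon, individual, genotype)])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i]
    block <- dt[amplicon == k$amplicon & individual == k$individual]
    calls <- as.matrix(block[, -(1:4)])
    conv <- if (!is.null(side))
      side[amplicon == k$amplicon & individual == k$individual] else NULL
    clone_matrix(calls, k$amplicon, k$individual, k$genotype,
                 non_cpg_c_total = if (nrow(conv %||% data.table())) conv$non_cpg_c_total else 0L,
                 non_cpg_c_converted = if (nrow(conv %||% data.table())) conv$non_cpg_c_converted else 0L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lollipop-style strings for a clone matrix
#'
#' One string per clone: a closed symbol for a methylated CpG, an open
#' symbol for an unmethylated one, and `.` for a missing call —
#' the conventional text rendering of bisulphite clone diagrams.
#'
#' @param m A [clone_matrix()].
#' @param closed,open Symbols for methylated / unmethylated calls.
#' @return Character vector, one element per clone.
#' @export
lollipop_strings <- function(m, closed = "*", open = "o") {
  apply(m$calls, 1, function(r) {
    paste(ifelse(is.na(r), ".", ifelse(r == 1, closed, open)), collapse = "")
  })
}
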