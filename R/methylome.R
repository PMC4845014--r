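#' Construct a methylome sample
#'
#' A methylome sample holds strand-merged methylated/unmethylated read
#' counts for CpG dinucleotides, keyed by the 1-based position of the
#' plus-strand cytosine. It is stored as a data.frame with columns
#' `chrom`, `pos`, `meth`, `unmeth` and carries the sample identifier as
#' an attribute.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector, 1-based plus-strand C positions.
#' @param meth,unmeth Non-negative integer read counts.
#' @param sample_id Sample identifier.
#' @return An object of class `methylome`.
#' @export
methylome <- function(chrom, pos, meth, unmeth, sample_id = "sample") {
  n <- length(chrom)
  if (length(pos) != n || length(meth) != n || length(unmeth) != n)
    stop_validation("methylome: column lengths differ")
  if (n > 0) {
    if (any(meth < 0) || any(unmeth < 0))
      stop_validation("methylome: negative counts")
    if (any(pos < 1))
      stop_validation("methylome: positions must be >= 1")
  }
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   meth = as.integer(meth), unmeth = as.integer(unmeth))
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stop_validation("methylome: duplicate (chrom, pos) keys")
  setorder(dt, chrom, pos)
  out <- as.data.frame(dt)
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("methylome", "data.frame")
  out
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> sample '%s': %d CpG sites, total coverage %s\n",
              sample_id(x), nrow(x),
              format(sum(as.numeric(x$meth + x$unmeth)), big.mark = ",")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(unclass(x)), 6))
  invisible(x)
}

#' Sample identifier of a methylome
#' @param x A `methylome`.
#' @return The sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Total read count of a methylome
#' @param x A `methylome`.
#' @return Sum of methylated plus unmethylated counts over all sites.
#' @export
total_counts <- function(x) sum(as.numeric(x$meth) + as.numeric(x$unmeth))

#' Per-site methylation percentages
#' @param x A `methylome`.
#' @return Numeric vector, `100 * meth / (meth + unmeth)`; `NaN` where
#'   coverage is zero.
#' @export
methylation_percent <- function(x) 100 * x$meth / (x$meth + x$unmeth)
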