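#' Read a per-cytosine bisulphite report
#'
#' Reads the six-column tab-separated cytosine report dialect:
#' chromosome, 1-based position of the cytosine, strand (`+`/`-`),
#' methylated count, unmethylated count, context (`CpG`, `CHG`, `CHH`).
#' Non-CpG rows are retained (they carry the conversion-rate QC signal)
#' but can be recognised through the `context` column.
#'
#' @param path Path to the report (optionally gzip-compressed).
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, `context`. An empty file yields a zero-row data.frame.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop_parse("cytosine report not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), context = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop_parse("cytosine report %s: line %d has %d columns, expected 6",
               path, which(nf != 6L)[1], nf[nf != 6L][1])
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 4]))
  unmeth <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop_parse("cytosine report %s: non-integer field at line %d", path, bad[1])
  bad_strand <- which(!m[, 3] %in% c("+", "-"))
  if (length(bad_strand))
    stop_parse("cytosine report %s: invalid strand '%s' at line %d",
               path, m[bad_strand[1], 3], bad_strand[1])
  if (any(meth < 0) || any(unmeth < 0))
    stop_parse("cytosine report %s: negative count", path)
  data.frame(chrom = m[, 1], pos = pos, strand = m[, 3],
             meth = meth, unmeth = unmeth, context = m[, 6],
             stringsAsFactors = FALSE)
}

#' Merge strand-level CpG calls into per-dinucleotide counts
#'
#' A CpG dinucleotide is covered by a cytosine on each strand: the
#' plus-strand C at position p and the minus-strand C at p + 1. Counts
#' from the two strands are summed and reported at the plus-strand
#' position, giving a single methylation value per CpG dinucleotide.
#' Sites covered on only one strand pass through unchanged (after
#' position adjustment for minus-strand records).
#'
#' @param records Data.frame as returned by [read_cytosine_report()].
#'   Rows with `context != "CpG"` are dropped.
#' @param sample_id Sample identifier for the resulting methylome.
#' @return A [methylome()].
#' @export
merge_strands <- function(records, sample_id = "sample") {
  stopifnot(all(c("chrom", "pos", "strand", "meth", "unmeth") %in% names(records)))
  if ("context" %in% names(records)) records <- records[records$context == "CpG", ]
  if (nrow(records) == 0) {
    return(methylome(character(), integer(), integer(), integer(), sample_id))
  }
  dt <- as.data.table(records[c("chrom", "pos", "strand", "meth", "unmeth")])
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop_validation("merge_strands: duplicate record for the same (chrom, pos, strand)")
  dt[, pos := ifelse(strand == "-", pos - 1L, pos)]
  merged <- dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
  methylome(merged$chrom, merged$pos, merged$meth, merged$unmeth, sample_id)
}

#' Binomially thin the read counts of a methylome
#'
#' Each methylated and unmethylated count is replaced by a binomial draw
#' with retention probability `ratio`, emulating random subsampling of
#' reads at the count level. The expected per-site methylation fraction
#' is unchanged; results are reproducible for a fixed seed.
#'
#' @param sample A [methylome()].
#' @param ratio Retention fraction in (0, 1].
#' @param seed Integer seed (required; no silent clock seeding).
#' @return A thinned [methylome()].
#' @export
thin_counts <- function(sample, ratio, seed) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio > 1)
    stop_argument("thin_counts: ratio must be in (0, 1]")
  if (missing(seed)) stop_argument("thin_counts: seed is required")
  if (ratio == 1) return(sample)
  with_seed(seed, {
    meth <- rbinom(nrow(sample), sample$meth, ratio)
    unmeth <- rbinom(nrow(sample), sample$unmeth, ratio)
  })
  methylome(sample$chrom, sample$pos, meth, unmeth, sample_id(sample))
}

#' Equalize the library sizes of two methylomes
#'
#' The sample with the larger total read count is binomially thinned by
#' the ratio of the two totals; the smaller sample passes through
#' unchanged. This mirrors read-level subsampling of the larger library,
#' applied at the count level.
#'
#' @param a,b [methylome()] objects.
#' @param seed Integer seed for the thinning draw.
#' @return A list with elements `a` and `b` (same order as the inputs)
#'   and attribute `ratio`, the thinning fraction applied.
#' @export
equalize_libraries <- function(a, b, seed) {
  ta <- total_counts(a); tb <- total_counts(b)
  if (ta == 0 || tb == 0)
    stop_validation("equalize_libraries: a sample has total count 0")
  ratio <- min(ta, tb) / max(ta, tb)
  if (ta > tb) {
    a <- thin_counts(a, ratio, seed)
  } else if (tb > ta) {
    b <- thin_counts(b, ratio, seed)
  }
  out <- list(a = a, b = b)
  attr(out, "ratio") <- ratio
  out
}

#' Write / read the coverage-file dialect
#'
#' The coverage file is a six-column TSV: chrom, start, end (both the
#' 1-based CpG position, start = end), methylation percentage,
#' methylated count, unmethylated count. Counts round-trip exactly; the
#' percentage column is derived.
#'
#' @param sample A [methylome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(sample, path) {
  pct <- ifelse(sample$meth + sample$unmeth > 0,
                100 * sample$meth / (sample$meth + sample$unmeth), 0)
  dt <- data.table(sample$chrom, sample$pos, sample$pos,
                   formatC(pct, format = "g", digits = 15),
                   sample$meth, sample$unmeth)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coverage_file
#' @param sample_id Sample identifier for the methylome read back.
#' @export
read_coverage_file <- function(path, sample_id = "sample") {
  if (!file.exists(path)) stop_parse("coverage file not found: %s", path)
  dt <- fread(path, sep = "\t", header = FALSE,
              colClasses = list(character = 1, integer = c(2, 3, 5, 6)))
  if (nrow(dt) == 0)
    return(methylome(character(), integer(), integer(), integer(), sample_id))
  if (ncol(dt) != 6) stop_parse("coverage file %s: expected 6 columns", path)
  if (any(dt[[2]] != dt[[3]]))
    stop_parse("coverage file %s: start != end (per-site dialect required)", path)
  methylome(dt[[1]], dt[[2]], dt[[5]], dt[[6]], sample_id)
}

#' Write a methylome as a per-strand cytosine report
#'
#' Each CpG dinucleotide's counts are split across the two strands: a
#' plus-strand record at the C position and a minus-strand record at
#' position + 1. With `split = "binomial"` reads are assigned to strands
#' by a fair seeded coin (emulating strand-symmetric sequencing); with
#' `split = "plus"` all counts stay on the plus strand. Reading the
#' report back with [read_cytosine_report()] and [merge_strands()]
#' reproduces the input counts exactly in either mode.
#'
#' @param sample A [methylome()].
#' @param path Output path.
#' @param split `"binomial"` or `"plus"`.
#' @param seed Seed for the binomial split.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sample, path, split = c("binomial", "plus"),
                                  seed = 0L) {
  split <- match.arg(split)
  n <- nrow(sample)
  if (split == "binomial" && n > 0) {
    with_seed(seed, {
      mp <- rbinom(n, sample$meth, 0.5)
      up <- rbinom(n, sample$unmeth, 0.5)
    })
  } else {
    mp <- sample$meth; up <- sample$unmeth
  }
  plus <- data.table(chrom = sample$chrom, pos = sample$pos, strand = "+",
                     meth = mp, unmeth = up, context = "CpG")
  minus <- data.table(chrom = sample$chrom, pos = sample$pos + 1L, strand = "-",
                      meth = sample$meth - mp, unmeth = sample$unmeth - up,
                      context = "CpG")
  dt <- rbindlist(list(plus, minus))
  setorder(dt, chrom, pos, strand)
  dt <- dt[meth + unmeth > 0 | strand == "+"]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a repeat annotation (BED6+2)
#'
#' Expects tab-separated columns chrom, start (0-based), end (half-open),
#' subfamily name, score, strand, class/family (e.g. `LTR/ERVK`,
#' `LINE/L1`, `SINE/B1`), the layout of a RepeatMasker track export.
#'
#' @param path Path to the annotation file.
#' @param class_family Optional filter: keep only elements whose
#'   class/family equals this string.
#' @return A data.frame with columns `chrom`, `start`, `end`,
#'   `subfamily`, `score`, `strand`, `class_family`.
#' @export
read_repeat_annotation <- function(path, class_family = NULL) {
  if (!file.exists(path)) stop_parse("annotation not found: %s", path)
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "subfamily",
                            "score", "strand", "class_family"),
              colClasses = list(character = c(1, 4, 6, 7),
                                integer = c(2, 3), numeric = 5))
  validate_intervals(dt$start, dt$end, dt$strand, path)
  if (any(!nzchar(dt$subfamily)) || any(!nzchar(dt$class_family)))
    stop_validation("%s: empty subfamily or class_family label", path)
  out <- as.data.frame(dt)
  if (!is.null(class_family)) {
    out <- out[out$class_family == class_family, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a BED4 file of labelled intervals or points
#'
#' Used for TSS lists (single-base intervals; the point is the 0-based
#' `start`) and for ICR intervals whose name column carries the
#' maternal/paternal label.
#'
#' @param path Path to a 4-column BED file.
#' @return Data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed4 <- function(path) {
  if (!file.exists(path)) stop_parse("BED file not found: %s", path)
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "name"),
              colClasses = list(character = c(1, 4), integer = c(2, 3)))
  validate_intervals(dt$start, dt$end, rep(".", nrow(dt)), path)
  as.data.frame(dt)
}

#' Read a chromosome-size table
#'
#' Two-column TSV (chromosome name, length in bp), the standard
#' "chrom.sizes" layout.
#'
#' @param path Path to the table.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_parse("chrom.sizes not found: %s", path)
  dt <- fread(path, sep = "\t", header = FALSE,
              colClasses = list(character = 1, integer = 2))
  if (any(dt[[2]] <= 0)) stop_validation("%s: non-positive chromosome length", path)
  setNames(as.integer(dt[[2]]), dt[[1]])
}

validate_intervals <- function(start, end, strand, what = "intervals") {
  if (any(start < 0)) stop_validation("%s: negative start coordinate", what)
  if (any(start >= end)) stop_validation("%s: start >= end", what)
  if (any(!strand %in% c("+", "-", "."))) stop_validation("%s: unknown strand symbol", what)
  invisible(TRUE)
}
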