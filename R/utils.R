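#' @importFrom data.table data.table setDT setkey := .N .SD setorder as.data.table rbindlist fread fwrite
#' @importFrom stats rbinom rnbinom rbeta rgeom rmultinom runif median wilcox.test t.test chisq.test pchisq pbinom binom.test setNames
#' @importFrom utils head read.table write.table
NULL

# data.table NSE variables
utils::globalVariables(c(
  ".", "chrom", "pos", "meth", "unmeth", "cov", "cov_wt", "cov_mut",
  "meth_wt", "meth_mut", "unmeth_wt", "unmeth_mut",
  "meth_pct_wt", "meth_pct_mut", "delta",
  "n_cpgs", "subfamily", "class_family", "direction", "n_hypo", "n_hyper",
  "total", "element_id", "planted", "start", "end", "region_idx",
  "mw", "cw", "mm", "cm", "m", "score", "n_cpgs_wt", "n_cpgs_mut",
  "amplicon", "individual", "genotype", "clone", "strand"
))

#' Derive a named sub-stream seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Independent
#' stages (genome layout, methylome counts, cohorts, clone matrices,
#' thinning) draw from sub-streams derived deterministically from the root
#' seed and a stream name, so a stage can be regenerated without replaying
#' the stages before it.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # small string hash; keeps everything in 32-bit integer range
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 7919L) %% 2147483647L
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_validation <- function(...) {
  stop(structure(class = c("repmeth_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_argument <- function(...) {
  stop(structure(class = c("repmeth_argument_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("repmeth_parse_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
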