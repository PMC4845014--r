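#' Default pipeline parameters
#'
#' The filter and threshold parameters of the whole-genome analysis:
#' minimum per-sample CpG coverage (8 reads), coverage-balance fraction
#' (0.6), minimum qualifying CpGs per element (8), differential
#' threshold (10 percentage points), window size (10 kb) and TSS
#' proximity distance (10 kb).
#'
#' @param min_cov,bias_fraction,min_cpgs,dm_threshold_pp,window_size,tss_distance
#'   See the individual stage functions.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(min_cov = 8, bias_fraction = 0.6, min_cpgs = 8,
                            dm_threshold_pp = 10, window_size = 10000,
                            tss_distance = 10000) {
  list(min_cov = min_cov, bias_fraction = bias_fraction, min_cpgs = min_cpgs,
       dm_threshold_pp = dm_threshold_pp, window_size = window_size,
       tss_distance = tss_distance)
}

#' Run the full two-sample repeat-methylation analysis
#'
#' Composes the pipeline stages: library-size equalization, genome-wide
#' window scoring, ICR purity summary, repeat-element scoring under the
#' coverage/bias/CpG-count filters, differential calling at the
#' percentage-point threshold, subfamily composition, the Mann-Whitney
#' shift test, TSS proximity of hypomethylated calls, and optional
#' control-class analyses run with identical filters.
#'
#' @param wt,mut [methylome()] objects (strand-merged).
#' @param repeats Repeat annotation data.frame (the target class, e.g.
#'   ERVK elements).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param tss Data.frame of TSS points (`chrom`, `pos`); optional.
#' @param icrs Data.frame of labelled ICR intervals; optional.
#' @param params List from [pipeline_params()].
#' @param seed Integer seed for the equalization thinning.
#' @param controls Optional named list of control annotations
#'   (data.frames), each analysed with [control_class_analysis()].
#' @param shift_scope Scope of the main shift test (default
#'   `"dm_subset"`).
#' @param out_dir Optional output directory for TSV/BED/JSON artefacts.
#' @return A list with the stage outputs (`windows`, `icr`, `scores`,
#'   `calls`, `subfamilies`, `shift`, `tss`, `controls`) and `summary`,
#'   a flat list of the headline numbers and all parameters used.
#' @export
run_wgbs_analysis <- function(wt, mut, repeats, chrom_sizes, tss = NULL,
                              icrs = NULL, params = pipeline_params(),
                              seed = 1L, controls = NULL,
                              shift_scope = "dm_subset", out_dir = NULL) {
  shared <- intersect(unique(wt$chrom), unique(mut$chrom))
  if (length(shared) == 0)
    stop_validation("run_wgbs_analysis: samples share no chromosome names")
  if (nrow(repeats) > 0 && !any(repeats$chrom %in% shared))
    stop_validation("run_wgbs_analysis: annotation chromosomes do not match samples")
  eq <- equalize_libraries(wt, mut, seed = derive_seed(seed, "equalize"))
  wt <- eq$a; mut <- eq$b
  win <- window_scores(wt, mut, chrom_sizes,
                       window_size = params$window_size)
  icr <- if (!is.null(icrs) && nrow(icrs)) icr_summary(wt, mut, icrs) else NULL
  scores <- score_repeats(wt, mut, repeats, min_cpgs = params$min_cpgs,
                          min_cov = params$min_cov,
                          bias_fraction = params$bias_fraction)
  calls <- call_differential(scores, params$dm_threshold_pp)
  subfam <- subfamily_counts(calls)
  shift <- if (nrow(scores) >= 2 &&
               (shift_scope == "all" || nrow(calls) >= 2))
    shift_test(scores, scope = shift_scope,
               threshold_pp = params$dm_threshold_pp) else NULL
  tss_res <- if (!is.null(tss) && nrow(tss) && nrow(calls)) {
    hypo <- calls[calls$direction == "hypo", , drop = FALSE]
    if (nrow(hypo)) tss_proximity(hypo, tss, params$tss_distance) else NULL
  } else NULL
  ctrl <- if (!is.null(controls)) {
    lapply(names(controls), function(lab)
      control_class_analysis(wt, mut, controls[[lab]], lab,
                             min_cpgs = params$min_cpgs,
                             min_cov = params$min_cov,
                             bias_fraction = params$bias_fraction,
                             threshold_pp = params$dm_threshold_pp))
  } else NULL
  if (!is.null(ctrl)) names(ctrl) <- names(controls)
  summary <- list(
    n_scored = nrow(scores),
    n_excluded = attr(scores, "n_excluded"),
    n_dm = nrow(calls),
    n_hypo = attr(calls, "n_hypo"),
    n_hyper = attr(calls, "n_hyper"),
    median_window_wt = win$median_wt,
    median_window_mut = win$median_mut,
    n_windows = win$n_windows,
    U = if (!is.null(shift)) shift$U else NA_real_,
    p_shift = if (!is.null(shift)) shift$p_value else NA_real_,
    n_tss_proximal_hypo = if (!is.null(tss_res)) tss_res$count else NA_integer_,
    equalize_ratio = attr(eq, "ratio"),
    params = params, seed = seed)
  res <- list(windows = win, icr = icr, scores = scores, calls = calls,
              subfamilies = subfam, shift = shift, tss = tss_res,
              controls = ctrl, summary = summary)
  if (!is.null(out_dir)) write_analysis_outputs(res, out_dir)
  res
}

write_analysis_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(as.data.table(res$scores), file.path(out_dir, "region_scores.tsv"),
         sep = "\t", quote = FALSE)
  if (nrow(res$calls))
    write_differential_bed(res$calls, file.path(out_dir, "differential.bed"))
  fwrite(as.data.table(res$subfamilies),
         file.path(out_dir, "subfamily_counts.tsv"), sep = "\t", quote = FALSE)
  fwrite(as.data.table(res$windows$windows),
         file.path(out_dir, "window_scores.tsv"), sep = "\t", quote = FALSE)
  if (!is.null(res$icr))
    fwrite(as.data.table(res$icr), file.path(out_dir, "icr_summary.tsv"),
           sep = "\t", quote = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate-analyse-evaluate benchmark
#'
#' For each replicate, simulates a fresh study from the configuration
#' (with a replicate-specific sub-seed), runs the element-level analysis
#' with the given parameters, and scores recovery against the truth
#' table: sensitivity (fraction of planted elements called in the
#' planted direction), false-positive rate (fraction of unplanted
#' elements called at all), the hypo/hyper direction split, and the
#' shift-test p-value over all scored elements.
#'
#' @param cfg A [sim_config()]; its seed is the benchmark root seed.
#' @param replicates Number of replicates (>= 1).
#' @param params List from [pipeline_params()].
#' @param target_class Class/family analysed (default `"LTR/ERVK"`).
#' @return Data.frame with one row per replicate: `replicate`, `seed`,
#'   `n_scored`, `n_dm`, `n_hypo`, `n_hyper`, `n_planted`,
#'   `sensitivity` (NA when nothing was planted), `fpr`, `p_shift`.
#' @export
run_benchmark <- function(cfg, replicates, params = pipeline_params(),
                          target_class = "LTR/ERVK") {
  if (replicates < 1) stop_argument("run_benchmark: replicates must be >= 1")
  rows <- lapply(seq_len(replicates), function(r) {
    rcfg <- cfg
    rcfg$seed <- derive_seed(cfg$seed, paste0("replicate_", r))
    genome <- build_genome(rcfg)
    sim <- simulate_methylomes(genome, rcfg)
    ervk <- genome$repeats[genome$repeats$class_family == target_class, ,
                           drop = FALSE]
    truth <- sim$truth[sim$truth$class_family == target_class, , drop = FALSE]
    ev <- evaluate_recovery(sim$wt, sim$mut, ervk, truth, params)
    cbind(data.frame(replicate = r, seed = rcfg$seed), ev)
  })
  do.call(rbind, rows)
}

#' Score differential-calling recovery against a truth table
#'
#' @param wt,mut [methylome()] objects.
#' @param repeats Annotation of the analysed elements (must carry
#'   `element_id` matching the truth table).
#' @param truth Truth table from [simulate_methylomes()].
#' @param params List from [pipeline_params()].
#' @return One-row data.frame with recovery metrics.
#' @export
evaluate_recovery <- function(wt, mut, repeats, truth,
                              params = pipeline_params()) {
  scores <- score_repeats(wt, mut, repeats, min_cpgs = params$min_cpgs,
                          min_cov = params$min_cov,
                          bias_fraction = params$bias_fraction)
  scores$element_id <- repeats$element_id[attr(scores, "region_idx")]
  calls <- call_differential(scores, params$dm_threshold_pp)
  called_ids <- scores$element_id[abs(scores$delta) > params$dm_threshold_pp]
  # recovery requires the called direction to match the planted direction
  true_delta <- setNames(truth$true_meth_mut - truth$true_meth_wt,
                         truth$element_id)
  call_dir <- sign(scores$delta[match(called_ids, scores$element_id)])
  dir_ok_ids <- called_ids[call_dir ==
                             sign(true_delta[as.character(called_ids)])]
  planted_ids <- truth$element_id[truth$planted]
  null_ids <- truth$element_id[!truth$planted]
  sens <- if (length(planted_ids))
    mean(planted_ids %in% dir_ok_ids) else NA_real_
  fpr <- if (length(null_ids)) mean(null_ids %in% called_ids) else NA_real_
  p_shift <- if (nrow(scores) >= 2)
    shift_test(scores, scope = "all")$p_value else NA_real_
  data.frame(n_scored = nrow(scores), n_dm = nrow(calls),
             n_hypo = attr(calls, "n_hypo"), n_hyper = attr(calls, "n_hyper"),
             n_planted = length(planted_ids), sensitivity = sens, fpr = fpr,
             p_shift = p_shift)
}
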