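#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: a toy genome carrying
#' labelled repeat subfamilies, two-sample beta-binomial CpG count data
#' at roughly 30-fold coverage with regional methylation centred near
#' 90%, a planted hypomethylation effect in a chosen fraction of
#' ERVK-like elements, plus TSS and imprinting-control-region
#' annotations. All randomness flows from `seed` through named
#' sub-streams (genome, methylome, cohort, clones), so each stage can be
#' regenerated independently.
#'
#' Defaults emulate sperm WGBS of the kind the pipeline targets: mean
#' CpG methylation ~90% (Beta(18, 2)), negative-binomial per-CpG
#' coverage with mean 30 and size 15, CpG-dense elements (mean spacing
#' 35 bp, as in IAP long terminal repeats), 2,000 ERVK-like elements
#' across four subfamilies with 5% planted hypomethylation at -25
#' percentage points, and LINE1/B1-like control classes with no effect.
#'
#' @param seed Integer root seed.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param cpg_spacing_mean Mean CpG spacing in bp (geometric, minimum 2).
#' @param subfamily_catalogue Data.frame with columns `subfamily`,
#'   `class_family`, `element_length`, `n_elements`.
#' @param baseline_meth Length-2 numeric, shape parameters of the Beta
#'   distribution of true regional methylation (default c(18, 2), mean
#'   0.9).
#' @param icr_low_meth Beta shapes for maternally methylated ICRs in
#'   sperm (default c(1.5, 28.5), mean 0.05).
#' @param coverage_mean,coverage_size Negative-binomial coverage model
#'   per CpG per sample.
#' @param coverage_imbalance Multiplier on the mutant coverage mean
#'   (default 1; set away from 1 to exercise the coverage-bias filter).
#' @param planted_effects Data.frame with columns `subfamily`,
#'   `fraction`, `delta_pp`, `direction` ("hypo"/"hyper"); `NULL` for a
#'   no-effect simulation.
#' @param tss_count,icr_count Number of TSS points / ICR intervals.
#' @param icr_length ICR interval length in bp.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2000000L,
                       cpg_spacing_mean = 35,
                       subfamily_catalogue = default_subfamily_catalogue(),
                       baseline_meth = c(18, 2),
                       icr_low_meth = c(1.5, 28.5),
                       coverage_mean = 30,
                       coverage_size = 15,
                       coverage_imbalance = 1,
                       planted_effects = default_planted_effects(),
                       tss_count = 50L,
                       icr_count = 8L,
                       icr_length = 2000L) {
  stopifnot(n_chroms > 0, chrom_length > 0, cpg_spacing_mean > 2,
            coverage_mean > 0, coverage_size > 0, coverage_imbalance > 0,
            tss_count > 0, icr_count > 0)
  if (!is.null(planted_effects) && nrow(planted_effects)) {
    stopifnot(all(planted_effects$fraction > 0),
              all(planted_effects$fraction <= 1),
              all(abs(planted_effects$delta_pp) <= 100),
              all(planted_effects$direction %in% c("hypo", "hyper")))
  }
  stopifnot(all(subfamily_catalogue$n_elements > 0),
            all(subfamily_catalogue$element_length > 0))
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 cpg_spacing_mean = cpg_spacing_mean,
                 subfamily_catalogue = subfamily_catalogue,
                 baseline_meth = baseline_meth, icr_low_meth = icr_low_meth,
                 coverage_mean = coverage_mean, coverage_size = coverage_size,
                 coverage_imbalance = coverage_imbalance,
                 planted_effects = planted_effects,
                 tss_count = as.integer(tss_count),
                 icr_count = as.integer(icr_count),
                 icr_length = as.integer(icr_length)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_subfamily_catalogue <- function() {
  data.frame(
    subfamily = c("IAPEY", "RLTRETN", "IAPLTR3", "RNERVK23-int",
                  "L1Md_A", "B1_Mus1"),
    class_family = c("LTR/ERVK", "LTR/ERVK", "LTR/ERVK", "LTR/ERVK",
                     "LINE/L1", "SINE/B1"),
    element_length = c(700L, 700L, 700L, 700L, 1200L, 400L),
    n_elements = c(600L, 600L, 400L, 400L, 200L, 200L),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted_effects <- function() {
  data.frame(subfamily = c("IAPEY", "RLTRETN"),
             fraction = c(1 / 12, 1 / 12),
             delta_pp = c(25, 25),
             direction = c("hypo", "hypo"),
             stringsAsFactors = FALSE)
}

#' Build a toy genome with repeat, TSS and ICR annotations
#'
#' Chromosome sizes, strictly increasing CpG positions with geometric
#' spacing, non-overlapping repeat elements per chromosome (elements are
#' distributed round-robin over chromosomes and packed with random
#' gaps), random TSS points and alternating maternal/paternal ICR
#' intervals.
#'
#' @param cfg A [sim_config()].
#' @return A list: `chrom_sizes` (named vector), `cpgs` (data.frame
#'   `chrom`, `pos`, 1-based), `repeats` (BED6+2 layout data.frame with
#'   an `element_id` column), `tss` (`chrom`, `start`, `end`, `name`,
#'   `pos`), `icrs` (`chrom`, `start`, `end`, `name`).
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gseed <- derive_seed(cfg$seed, "genome")
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  cat <- cfg$subfamily_catalogue
  elements <- data.frame(
    subfamily = rep(cat$subfamily, cat$n_elements),
    class_family = rep(cat$class_family, cat$n_elements),
    len = rep(cat$element_length, cat$n_elements),
    stringsAsFactors = FALSE)
  with_seed(gseed, {
    elements <- elements[sample.int(nrow(elements)), , drop = FALSE]
    elements$chrom <- chroms[(seq_len(nrow(elements)) - 1L) %% cfg$n_chroms + 1L]
    placed <- do.call(rbind, lapply(chroms, function(cn) {
      e <- elements[elements$chrom == cn, , drop = FALSE]
      slack <- cfg$chrom_length - sum(e$len)
      if (slack < 0)
        stop_argument("build_genome: chromosome %s too short for %d elements (need %d bp)",
                      cn, nrow(e), sum(e$len))
      # random gaps: split the slack by a Dirichlet-like draw
      g <- stats::rexp(nrow(e) + 1L)
      gaps <- floor(slack * g / sum(g))
      starts <- cumsum(gaps[seq_len(nrow(e))] ) + c(0, cumsum(e$len))[seq_len(nrow(e))]
      e$start <- as.integer(starts)
      e$end <- as.integer(starts + e$len)
      e
    }))
    cpgs <- do.call(rbind, lapply(chroms, function(cn) {
      n_guess <- ceiling(cfg$chrom_length / cfg$cpg_spacing_mean * 1.5) + 100L
      sp <- 2L + rgeom(n_guess, 1 / (cfg$cpg_spacing_mean - 2 + 1))
      pos <- cumsum(sp)
      pos <- pos[pos <= cfg$chrom_length - 1L]
      data.frame(chrom = cn, pos = as.integer(pos), stringsAsFactors = FALSE)
    }))
    tss_chrom <- sample(chroms, cfg$tss_count, replace = TRUE)
    tss_pos <- floor(runif(cfg$tss_count) * (cfg$chrom_length - 1))
    icr_chrom <- sample(chroms, cfg$icr_count, replace = TRUE)
    icr_start <- floor(runif(cfg$icr_count) * (cfg$chrom_length - cfg$icr_length))
  })
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  placed$element_id <- seq_len(nrow(placed))
  repeats <- data.frame(chrom = placed$chrom, start = placed$start,
                        end = placed$end, subfamily = placed$subfamily,
                        score = 0, strand = ".",
                        class_family = placed$class_family,
                        element_id = placed$element_id,
                        stringsAsFactors = FALSE)
  tss <- data.frame(chrom = tss_chrom, start = as.integer(tss_pos),
                    end = as.integer(tss_pos + 1),
                    name = paste0("tss_", seq_len(cfg$tss_count)),
                    pos = as.integer(tss_pos), stringsAsFactors = FALSE)
  icr_lab <- rep(c("maternal", "paternal"), length.out = cfg$icr_count)
  icrs <- data.frame(chrom = icr_chrom, start = as.integer(icr_start),
                     end = as.integer(icr_start + cfg$icr_length),
                     name = paste0("icr_", seq_len(cfg$icr_count), "_", icr_lab),
                     stringsAsFactors = FALSE)
  list(chrom_sizes = chrom_sizes, cpgs = cpgs, repeats = repeats,
       tss = tss, icrs = icrs, config = cfg)
}

#' Simulate two beta-binomial methylomes with planted effects
#'
#' Draws a true methylation level per repeat element from the baseline
#' Beta distribution (shared between the samples), shifts the mutant
#' level of planted elements by the configured percentage points
#' (floored at 0, capped at 100), assigns background CpGs an independent
#' Beta level each and ICR CpGs their imprint-appropriate level
#' (maternal ICRs hypomethylated in sperm), then draws per-CpG coverage
#' from a negative binomial and methylated counts from a binomial at the
#' true level, independently per sample.
#'
#' @param genome Output of [build_genome()].
#' @param cfg The same [sim_config()].
#' @return A list: `wt`, `mut` ([methylome()] objects), `truth`
#'   (data.frame: `element_id`, `subfamily`, `class_family`, `chrom`,
#'   `start`, `end`, `true_meth_wt`, `true_meth_mut` in percent,
#'   `planted`).
#' @export
simulate_methylomes <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mseed <- derive_seed(cfg$seed, "methylome")
  cpgs <- genome$cpgs
  reps <- genome$repeats
  n_cpg <- nrow(cpgs)
  with_seed(mseed, {
    ab <- cfg$baseline_meth
    lvl_wt_elem <- rbeta(nrow(reps), ab[1], ab[2])
    lvl_mut_elem <- lvl_wt_elem
    planted <- rep(FALSE, nrow(reps))
    pe <- cfg$planted_effects
    if (!is.null(pe) && nrow(pe)) {
      for (i in seq_len(nrow(pe))) {
        idx <- which(reps$subfamily == pe$subfamily[i])
        n_pick <- round(pe$fraction[i] * length(idx))
        pick <- sample(idx, n_pick)
        planted[pick] <- TRUE
        shift <- pe$delta_pp[i] / 100
        lvl_mut_elem[pick] <- if (pe$direction[i] == "hypo")
          pmax(0, lvl_wt_elem[pick] - shift)
        else pmin(1, lvl_wt_elem[pick] + shift)
      }
    }
    # per-CpG true levels: background by default, element / ICR override
    lvl_wt <- rbeta(n_cpg, ab[1], ab[2])
    lvl_mut <- lvl_wt
    hit_e <- overlap_index(cpgs, reps)
    in_e <- !is.na(hit_e)
    lvl_wt[in_e] <- lvl_wt_elem[hit_e[in_e]]
    lvl_mut[in_e] <- lvl_mut_elem[hit_e[in_e]]
    hit_i <- overlap_index(cpgs, genome$icrs)
    in_i <- !is.na(hit_i)
    if (any(in_i)) {
      maternal <- grepl("maternal", genome$icrs$name[hit_i[in_i]])
      lo <- cfg$icr_low_meth
      icr_lvl <- ifelse(maternal, rbeta(sum(in_i), lo[1], lo[2]),
                        rbeta(sum(in_i), ab[1], ab[2]))
      lvl_wt[in_i] <- icr_lvl
      lvl_mut[in_i] <- icr_lvl
    }
    cov_wt <- rnbinom(n_cpg, mu = cfg$coverage_mean, size = cfg$coverage_size)
    cov_mut <- rnbinom(n_cpg, mu = cfg$coverage_mean * cfg$coverage_imbalance,
                       size = cfg$coverage_size)
    meth_wt <- rbinom(n_cpg, cov_wt, lvl_wt)
    meth_mut <- rbinom(n_cpg, cov_mut, lvl_mut)
  })
  wt <- methylome(cpgs$chrom, cpgs$pos, meth_wt, cov_wt - meth_wt, "wt")
  mut <- methylome(cpgs$chrom, cpgs$pos, meth_mut, cov_mut - meth_mut, "mut")
  truth <- data.frame(element_id = reps$element_id,
                      subfamily = reps$subfamily,
                      class_family = reps$class_family,
                      chrom = reps$chrom, start = reps$start, end = reps$end,
                      true_meth_wt = 100 * lvl_wt_elem,
                      true_meth_mut = 100 * lvl_mut_elem,
                      planted = planted, stringsAsFactors = FALSE)
  list(wt = wt, mut = mut, truth = truth)
}

# index of the (first) interval containing each 1-based CpG position
overlap_index <- function(cpgs, intervals) {
  if (nrow(intervals) == 0) return(rep(NA_integer_, nrow(cpgs)))
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos, cpgs$pos))
  int_gr <- GenomicRanges::GRanges(intervals$chrom,
                                   IRanges::IRanges(intervals$start + 1L,
                                                    intervals$end))
  hits <- GenomicRanges::findOverlaps(cpg_gr, int_gr, select = "first")
  as.integer(hits)
}

#' Simulate a coat-colour cohort
#'
#' Draws pooled Y/M/psi categories from a multinomial at the given
#' probabilities and expands each to a five-category score consistent
#' with its pool (Y splits evenly between yellow and yellow-mottled,
#' psi between pseudoagouti-mottled and pseudoagouti).
#'
#' @param probabilities Named numeric `c(Y=, M=, psi=)`, summing to 1.
#' @param n Number of offspring.
#' @param seed Integer seed.
#' @param cross_id Group label stored on every record.
#' @param sire_genotype,dam_genotype,offspring_genotype,avy_parent
#'   Labels copied onto every record.
#' @return Data.frame of coat-colour records.
#' @export
simulate_cohort <- function(probabilities, n, seed, cross_id = "cross",
                            sire_genotype = "wt", dam_genotype = "wt",
                            offspring_genotype = "wt", avy_parent = "dam") {
  if (abs(sum(probabilities) - 1) > 1e-9)
    stop_argument("simulate_cohort: probabilities must sum to 1")
  if (n <= 0) stop_argument("simulate_cohort: n must be > 0")
  stopifnot(all(c("Y", "M", "psi") %in% names(probabilities)))
  fine <- list(Y = c("yellow", "yellow_mottled"),
               M = "mottled",
               psi = c("pseudoagouti_mottled", "pseudoagouti"))
  with_seed(seed, {
    pooled <- sample(c("Y", "M", "psi"), n, replace = TRUE,
                     prob = probabilities[c("Y", "M", "psi")])
    category5 <- vapply(pooled, function(g) sample(fine[[g]], 1), "")
  })
  data.frame(animal_id = sprintf("%s_%04d", cross_id, seq_len(n)),
             cross_id = cross_id, sire_genotype = sire_genotype,
             dam_genotype = dam_genotype,
             offspring_genotype = offspring_genotype,
             avy_parent = avy_parent, category5 = category5,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Penetrance probabilities at a given yellow fraction
#'
#' The control cross (Avy from the dam, wild-type sire) shows 29% yellow
#' (Y), 56% mottled (M) and 15% pseudoagouti (psi) offspring. Cohorts
#' with a different yellow fraction are modelled by moving probability
#' into or out of Y while keeping the M:psi ratio of the control cross,
#' since only the yellow fractions of the comparison groups are
#' reported.
#'
#' @param p_yellow Probability of the pooled Y category.
#' @return Named numeric `c(Y=, M=, psi=)` summing to 1.
#' @export
cohort_probs <- function(p_yellow = 0.29) {
  stopifnot(p_yellow >= 0, p_yellow <= 1)
  rest <- 1 - p_yellow
  c(Y = p_yellow, M = rest * 0.56 / 0.71, psi = rest * 0.15 / 0.71)
}

#' Simulate Sanger bisulphite clone matrices
#'
#' For each individual in each genotype group, draws a clones-by-CpG
#' matrix of Bernoulli methylation calls at the genotype's methylation
#' probability, and non-CpG conversion counts at the given conversion
#' efficiency (about 50 non-CpG cytosines per clone) to exercise the QC
#' path.
#'
#' @param n_individuals_per_group Individuals per genotype.
#' @param n_clones,n_cpgs Clone matrix dimensions.
#' @param p_meth Named numeric `c(wt=, mut=)` methylation probabilities.
#' @param conversion_eff Per-cytosine conversion probability.
#' @param seed Integer seed.
#' @param amplicon_id Amplicon label.
#' @return List of [clone_matrix()] objects.
#' @export
simulate_clones <- function(n_individuals_per_group, n_clones, n_cpgs,
                            p_meth = c(wt = 0.59, mut = 0.26),
                            conversion_eff = 0.99, seed = 1L,
                            amplicon_id = "amplicon1") {
  stopifnot(all(p_meth >= 0), all(p_meth <= 1),
            conversion_eff >= 0, conversion_eff <= 1,
            all(c("wt", "mut") %in% names(p_meth)))
  cseed <- derive_seed(seed, "clones")
  out <- list()
  with_seed(cseed, {
    for (g in c("wt", "mut")) {
      for (i in seq_len(n_individuals_per_group)) {
        calls <- matrix(rbinom(n_clones * n_cpgs, 1, p_meth[[g]]),
                        nrow = n_clones)
        total <- 50L * n_clones
        converted <- rbinom(1, total, conversion_eff)
        out[[length(out) + 1]] <- clone_matrix(
          calls, amplicon_id, sprintf("%s_%d", g, i), g,
          non_cpg_c_total = total, non_cpg_c_converted = converted)
      }
    }
  })
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits per-sample cytosine reports, the repeat annotation (BED6+2),
#' chrom.sizes, TSS and ICR BED4 files, the truth table, and optional
#' cohort and clone tables, plus a JSON manifest with md5 checksums.
#'
#' @param dir Output directory (created if needed).
#' @param genome Output of [build_genome()].
#' @param sim Output of [simulate_methylomes()].
#' @param cohort Optional cohort data.frame.
#' @param clones Optional list of [clone_matrix()] objects.
#' @param seed Seed for the strand split of the cytosine reports.
#' @return Data.frame manifest (`file`, `sha256`, `bytes`), invisibly
#'   also written to `manifest.json`.
#' @export
write_fixture <- function(dir, genome, sim, cohort = NULL, clones = NULL,
                          seed = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "wt.cytosine_report.tsv")
  write_cytosine_report(sim$wt, p, seed = derive_seed(seed, "split_wt"))
  paths <- c(paths, p)
  p <- file.path(dir, "mut.cytosine_report.tsv")
  write_cytosine_report(sim$mut, p, seed = derive_seed(seed, "split_mut"))
  paths <- c(paths, p)
  p <- file.path(dir, "repeats.bed")
  fwrite(as.data.table(genome$repeats[c("chrom", "start", "end", "subfamily",
                                        "score", "strand", "class_family")]),
         p, sep = "\t", col.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "chrom.sizes")
  fwrite(data.table(names(genome$chrom_sizes), genome$chrom_sizes), p,
         sep = "\t", col.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "tss.bed")
  fwrite(as.data.table(genome$tss[c("chrom", "start", "end", "name")]), p,
         sep = "\t", col.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "icr.bed")
  fwrite(as.data.table(genome$icrs[c("chrom", "start", "end", "name")]), p,
         sep = "\t", col.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.tsv")
  fwrite(as.data.table(sim$truth), p, sep = "\t", quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(cohort)) {
    p <- file.path(dir, "cohort.tsv")
    fwrite(as.data.table(cohort), p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(clones)) {
    p <- file.path(dir, "clones.tsv")
    write_clone_tsv(clones, p)
    paths <- c(paths, p, paste0(p, ".conversion.tsv"))
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = vapply(paths, function(f)
                           as.character(tools::md5sum(f)), ""),
                         bytes = file.size(paths),
                         row.names = NULL, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}
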