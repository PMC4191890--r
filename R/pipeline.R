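# End-to-end orchestration: default synthetic study design, dataset
# simulation presets, YAML run configuration, and the scan -> refine ->
# pA-select -> metagene -> motifs pipeline with a machine-readable manifest.

#' Default synthetic study design
#'
#' A 12-chromosome genome (100 kb each) carrying 32 transcription units:
#' 12 mRNAs, 10 snoRNAs, 8 CUTs and 2 antisense CUTs (20 non-pA
#' terminators in total), spaced so that no two same-strand loci come
#' within 2 kb. Gene-body rate is 5 events/base.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length (nt).
#' @param body_rate Gene-body occupancy rate (events/base).
#' @return List with `loci` (locus data frame) and `chrom_lengths`.
#' @export
default_loci <- function(n_chrom = 12L, chrom_len = 1e5, body_rate = 5) {
  chroms <- paste0("chr", utils::as.roman(seq_len(n_chrom)))
  chrom_lengths <- stats::setNames(rep(chrom_len, n_chrom), chroms)
  spans <- c(mRNA = 1500L, snoRNA = 400L, CUT = 600L, antisenseCUT = 600L)
  slot_pos <- list(three = c(15000L, 50000L, 82000L),
                   two = c(25000L, 70000L))
  slot_strand <- list(three = c("+", "-", "+"), two = c("+", "-"))
  cls3 <- rep(c("mRNA", "snoRNA", "CUT"), 8L)          # chrom 1..8
  cls2 <- c("mRNA", "snoRNA", "mRNA", "snoRNA",        # chrom 9..12
            "mRNA", "antisenseCUT", "mRNA", "antisenseCUT")
  rows <- list()
  j3 <- 0L; j2 <- 0L
  for (i in seq_len(n_chrom)) {
    layout <- if (i <= 8L) "three" else "two"
    for (s in seq_along(slot_pos[[layout]])) {
      cls <- if (layout == "three") {
        j3 <- j3 + 1L; cls3[j3]
      } else {
        j2 <- j2 + 1L; cls2[j2]
      }
      term <- slot_pos[[layout]][s]
      strand <- slot_strand[[layout]][s]
      tss <- if (strand == "+") term - spans[[cls]] else term + spans[[cls]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%d", cls, chroms[i], s),
        chrom = chroms[i], strand = strand, tss = tss, term_point = term,
        locus_class = cls, body_rate = body_rate, stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, rows)
  validate_loci(loci, chrom_lengths)
  list(loci = loci, chrom_lengths = chrom_lengths)
}

#' Available simulation presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() c("nrd1-demo", "sen1-demo", "ysh1-demo")

preset_factor <- function(preset) {
  switch(preset,
    "nrd1-demo" = "Nrd1",
    "sen1-demo" = "Sen1",
    "ysh1-demo" = "Ysh1",
    stop("unknown preset '", preset, "'; see list_presets()", call. = FALSE))
}

#' Simulate a complete ready-to-analyze dataset
#'
#' Wraps the synthetic-data generators to produce a genome, annotation,
#' control and depleted occupancy tracks, a pA-site table and ground-truth
#' tables for one factor-depletion scenario. If `out_dir` is given, all
#' components are also written to disk (FASTA, BED6, per-strand bedGraph,
#' TSV).
#'
#' @param preset One of [list_presets()].
#' @param seed Integer seed; sub-stages derive fixed offsets from it.
#' @param out_dir Optional output directory.
#' @param design Study design from [default_loci()] (or a compatible
#'   list).
#' @return List with `genome`, `annotation`, `loci`, `chrom_lengths`,
#'   `model`, `factor_class`, `control`, `depleted`, `pa_table`, `truth`,
#'   `inserts`, and `files` (paths, when written).
#' @export
simulate_dataset <- function(preset = "nrd1-demo", seed = 1L,
                             out_dir = NULL, design = default_loci()) {
  factor_class <- preset_factor(preset)
  model <- preset_model(factor_class)
  loci <- design$loci
  chrom_lengths <- design$chrom_lengths
  gen <- simulate_genome(sequence_spec(), loci, chrom_lengths,
                         seed = seed + 11L)
  control <- simulate_occupancy(loci, model, "control", factor_class,
                                chrom_lengths, seed = seed + 23L)
  depleted <- simulate_occupancy(loci, model, "depleted", factor_class,
                                 chrom_lengths, seed = seed + 37L)
  pa_table <- simulate_pa_table(loci, chrom_lengths, seed = seed + 51L,
                                noise_sites = 20L)
  truth <- loci[, c("id", "chrom", "strand", "tss", "term_point",
                    "locus_class")]
  res <- list(genome = gen$genome, annotation = gen$annotation, loci = loci,
              chrom_lengths = chrom_lengths, model = model,
              factor_class = factor_class, control = control,
              depleted = depleted, pa_table = pa_table, truth = truth,
              inserts = gen$inserts, files = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    Biostrings::writeXStringSet(res$genome, p("genome.fa"))
    rtracklayer::export(res$annotation, p("annotation.bed"), format = "BED")
    write_track(control, p("control_plus.bedgraph"),
                p("control_minus.bedgraph"))
    write_track(depleted, p("depleted_plus.bedgraph"),
                p("depleted_minus.bedgraph"))
    write_tsv(pa_table, p("pa_sites.tsv"))
    write_tsv(truth, p("truth_loci.tsv"))
    res$files <- list(
      genome = p("genome.fa"), annotation = p("annotation.bed"),
      control = c(p("control_plus.bedgraph"), p("control_minus.bedgraph")),
      depleted = c(p("depleted_plus.bedgraph"), p("depleted_minus.bedgraph")),
      pa_table = p("pa_sites.tsv"), truth = p("truth_loci.tsv"))
  }
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Build a run configuration
#'
#' All stage parameters with their standard defaults (window 500,
#' min_index 0.10, min_reads 1000, smoothing window 25, metagene flank
#' 1000 and bin 10, pA selection 200/200/0.4/500, upstream window 150).
#' The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param out_dir Output directory for pipeline tables.
#' @param seed Global seed; stages derive fixed offsets from it.
#' @param preset Simulation preset used when no input paths are given.
#' @param ... Overrides for nested entries, e.g.
#'   `scan = list(min_index = 0.2)`.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("termscan_run_"), seed = 1L,
                       preset = "nrd1-demo", ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(preset = preset, n_chrom = 12L, chrom_len = 1e5),
    inputs = list(),  # optional on-disk inputs override simulation
    scan = list(window = 500L, min_index = 0.10, min_reads = 1000,
                require_treated_gt_control = TRUE, min_separation = 1000L),
    refine = list(halfwidth = 1000L, smooth_window = 25L, amp_flank = 100L,
                  min_separation = 1000L),
    pa = list(min_reads = 200, cluster_dist = 200L, dominance_ratio = 0.4,
              top_n = 500L),
    metagene = list(flank = 1000L, bin = 10L),
    motifs = list(upstream = 150L, patterns = c("GUA[AG]", "UCUUG"),
                  n_shuffles = 200L, u_run_min_len = 3L,
                  u_run_halfwidth = 50L)
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(lines, con, quiet = FALSE) {
  if (!quiet) message(paste(lines, collapse = "\n"))
  writeLines(lines, con)
}

#' Run the full termination-mapping pipeline
#'
#' Executes simulate (or load) -> scan -> refine -> pA-select -> metagene
#' -> motifs, writing every stage's table plus a machine-readable manifest
#' (`manifest.json`: package version, seed, parameters, stage row counts)
#' and a run log with each filter's pass tallies to `out_dir`. Outputs are
#' deterministic: the same configuration and seed reproduce every file
#' byte for byte.
#'
#' When `config$inputs` names on-disk files (`control_plus`,
#' `control_minus`, `depleted_plus`, `depleted_minus`, `genome`,
#' `pa_table`, `chrom_lengths` needed with tracks), those are used instead
#' of simulation; missing named inputs abort with the input named.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) pipeline_log(sprintf(...), log_con, quiet)
  outp <- function(...) file.path(config$out_dir, ...)

  # ---- inputs -------------------------------------------------------------
  inputs <- config$inputs
  use_files <- length(inputs) > 0
  if (use_files) {
    need <- c("control_plus", "control_minus", "depleted_plus",
              "depleted_minus", "genome", "chrom_lengths")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in)) {
      stop("stage 'inputs' failed: missing input(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
    }
    for (nm in setdiff(names(inputs), "chrom_lengths")) {
      if (!file.exists(inputs[[nm]])) {
        stop("stage 'inputs' failed: input '", nm, "' not found: ",
             inputs[[nm]], call. = FALSE)
      }
    }
    chrom_lengths <- unlist(inputs$chrom_lengths)
    control <- read_track(inputs$control_plus, inputs$control_minus,
                          chrom_lengths)
    depleted <- read_track(inputs$depleted_plus, inputs$depleted_minus,
                           chrom_lengths)
    genome <- Biostrings::readDNAStringSet(inputs$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    pa_table <- if (!is.null(inputs$pa_table)) {
      utils::read.table(inputs$pa_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    truth <- NULL
    logf("stage inputs: loaded tracks (%d chromosomes), genome, %s",
         length(chrom_lengths),
         if (is.null(pa_table)) "no pA table" else
           sprintf("pA table (%d sites)", nrow(pa_table)))
  } else {
    ds <- simulate_dataset(config$simulate$preset, seed = config$seed,
                           design = default_loci(
                             n_chrom = config$simulate$n_chrom,
                             chrom_len = config$simulate$chrom_len))
    control <- ds$control
    depleted <- ds$depleted
    genome <- ds$genome
    pa_table <- ds$pa_table
    truth <- ds$truth
    chrom_lengths <- ds$chrom_lengths
    logf("stage simulate: preset %s, %d loci on %d chromosomes",
         config$simulate$preset, nrow(ds$loci), length(chrom_lengths))
  }

  # ---- scan ---------------------------------------------------------------
  thr <- scan_thresholds(
    window = config$scan$window, min_index = config$scan$min_index,
    min_reads = config$scan$min_reads,
    require_treated_gt_control = config$scan$require_treated_gt_control,
    min_separation = config$scan$min_separation)
  points <- global_scan(control, depleted, thr)
  candidates <- select_candidates(points, thr$min_separation)
  write_tsv(candidates, outp("candidates.tsv"))
  write_bed6(candidates$chrom, candidates$pos, candidates$pos + 1L,
             sprintf("cand_%d", seq_len(nrow(candidates))),
             pmin(1000L, as.integer(round(1000 * candidates$index))),
             candidates$strand, outp("candidates.bed"))
  logf("stage scan: %d passing points, %d non-overlapping candidates",
       nrow(points), nrow(candidates))

  # ---- refine -------------------------------------------------------------
  sites <- refine_all(candidates, control, depleted,
                      halfwidth = config$refine$halfwidth,
                      smooth_window = config$refine$smooth_window,
                      amp_flank = config$refine$amp_flank,
                      min_separation = config$refine$min_separation)
  write_tsv(sites, outp("termination_sites.tsv"))
  write_bed6(sites$chrom, sites$pos, sites$pos + 1L,
             sprintf("term_%d", seq_len(nrow(sites))),
             pmin(1000L, as.integer(round(10 * sites$crossing_amplitude))),
             sites$strand, outp("termination_sites.bed"))
  dropped <- attr(sites, "dropped")
  logf("stage refine: %d termination sites, %d candidates dropped",
       nrow(sites), nrow(dropped))

  # ---- pA selection -------------------------------------------------------
  pa_anchors <- NULL
  if (!is.null(pa_table)) {
    pa_anchors <- select_top_pa(pa_table, pa_selector_params(
      min_reads = config$pa$min_reads,
      cluster_dist = config$pa$cluster_dist,
      dominance_ratio = config$pa$dominance_ratio,
      top_n = config$pa$top_n))
    write_tsv(pa_anchors, outp("pa_anchors.tsv"))
    write_bed6(pa_anchors$chrom, pa_anchors$pos, pa_anchors$pos + 1L,
               sprintf("pa_%d", seq_len(nrow(pa_anchors))),
               pmin(1000L, pa_anchors$raw_reads), pa_anchors$strand,
               outp("pa_anchors.bed"))
    logf("stage pa_select: %d of %d sites kept", nrow(pa_anchors),
         nrow(pa_table))
  } else {
    logf("stage pa_select: skipped (no pA table)")
  }

  # ---- metagene -----------------------------------------------------------
  metagene_rows <- 0L
  ranking <- NULL
  if (nrow(sites)) {
    mg_c <- anchor_matrix(control, sites, flank = config$metagene$flank,
                          bin = config$metagene$bin)
    mg_t <- anchor_matrix(depleted, sites, flank = config$metagene$flank,
                          bin = config$metagene$bin)
    prof <- data.frame(offset = mg_c$bin_offsets,
                       control_mean = mean_profile(mg_c)$mean,
                       depleted_mean = mean_profile(mg_t)$mean)
    write_tsv(prof, outp("metagene_terminators.tsv"))
    metagene_rows <- nrow(prof)
    ranking <- percent_readthrough_ranking(sites, control, depleted,
                                           window = config$scan$window)
    write_tsv(ranking, outp("readthrough_ranking.tsv"))
  }
  if (!is.null(pa_anchors) && nrow(pa_anchors)) {
    pg_c <- anchor_matrix(control, pa_anchors,
                          flank = config$metagene$flank,
                          bin = config$metagene$bin)
    pg_t <- anchor_matrix(depleted, pa_anchors,
                          flank = config$metagene$flank,
                          bin = config$metagene$bin)
    prof_pa <- data.frame(offset = pg_c$bin_offsets,
                          control_mean = mean_profile(pg_c)$mean,
                          depleted_mean = mean_profile(pg_t)$mean)
    write_tsv(prof_pa, outp("metagene_pa.tsv"))
  }
  logf("stage metagene: %d bins, ranking over %d terminators",
       metagene_rows, if (is.null(ranking)) 0L else nrow(ranking))

  # ---- motifs -------------------------------------------------------------
  enrichment <- NULL
  u_runs <- NULL
  if (nrow(sites)) {
    sites$id <- sprintf("term_%d", seq_len(nrow(sites)))
    ups <- extract_upstream(genome, sites, length = config$motifs$upstream)
    fa <- outp("upstream_windows.fasta")
    writeLines(paste0(">", names(ups), "\n", unname(ups)), fa)
    enrich_rows <- lapply(seq_along(config$motifs$patterns), function(pi) {
      pat <- config$motifs$patterns[pi]
      e <- motif_enrichment(ups, pat,
                            n_shuffles = config$motifs$n_shuffles,
                            seed = config$seed + 500L + pi)
      data.frame(pattern = pat, observed = e$observed,
                 null_mean = e$null_mean,
                 fold_enrichment = e$fold_enrichment, p_value = e$p_value)
    })
    enrichment <- do.call(rbind, enrich_rows)
    write_tsv(enrichment, outp("motif_enrichment.tsv"))
    win <- terminator_window_seq(genome, sites,
                                 upstream = config$motifs$u_run_halfwidth,
                                 downstream = config$motifs$u_run_halfwidth)
    u_runs <- do.call(rbind, lapply(names(win), function(id) {
      st <- u_run_stats(win[[id]], min_len = config$motifs$u_run_min_len)
      if (!st$count) return(NULL)
      data.frame(id = id, start = st$starts, length = st$lengths)
    }))
    if (is.null(u_runs)) {
      u_runs <- data.frame(id = character(0), start = integer(0),
                           length = integer(0))
    }
    write_tsv(u_runs, outp("u_runs.tsv"))
    logf("stage motifs: %d upstream windows, %d U-runs", length(ups),
         nrow(u_runs))
  } else {
    logf("stage motifs: skipped (no termination sites)")
  }

  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package = "termscan",
    version = as.character(utils::packageVersion("termscan")),
    seed = config$seed,
    parameters = unclass(config)[c("scan", "refine", "pa", "metagene",
                                   "motifs")],
    counts = list(
      scan_points = nrow(points),
      candidates = nrow(candidates),
      termination_sites = nrow(sites),
      pa_anchors = if (is.null(pa_anchors)) 0L else nrow(pa_anchors),
      ranking = if (is.null(ranking)) 0L else nrow(ranking),
      u_runs = if (is.null(u_runs)) 0L else nrow(u_runs)))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  logf("pipeline complete: %d output files", length(list.files(config$out_dir)))

  invisible(list(points = points, candidates = candidates, sites = sites,
                 pa_anchors = pa_anchors, ranking = ranking,
                 enrichment = enrichment, u_runs = u_runs, truth = truth,
                 manifest = manifest, out_dir = config$out_dir))
}

# Minimal BED6 writer (scores clipped to [0, 1000] by callers).
write_bed6 <- function(chrom, start, end, name, score, strand, path) {
  if (length(chrom) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  writeLines(paste(chrom, fmt_int(start), fmt_int(end), name,
                   fmt_int(pmax(0L, score)), strand, sep = "\t"), path)
  invisible(path)
}
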