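#' Pipeline thresholds
#'
#' All screening and validation thresholds in one place, defaulting to the
#' published analysis settings: threefold change, 50 TP2M abundance floor,
#' >90% strand bias, inclusive target-score cutoff 4.0, exact position-10
#' cleavage window.
#'
#' @param fold fold-change threshold (screen and locus candidates).
#' @param floor abundance floor, TP2M.
#' @param pseudocount TP2M pseudocount for fold changes.
#' @param min_bias strand-bias threshold (exclusive).
#' @param hairpin_threshold stem-loop score threshold.
#' @param lambda,min_span,fold_pad,min_loop folding parameters.
#' @param flank,merge_gap clustering parameters (nt).
#' @param cutoff target-score cutoff (inclusive).
#' @param window PARE cleavage acceptance window (nt).
#' @param rank_max maximum PARE site rank for support.
#' @param abundance_floor locus abundant-sRNA floor (at `scale` units).
#' @param scale locus/PARE per-N normalization unit.
#' @param precision_threshold precise-excision threshold.
#' @return list of thresholds.
#' @export
pipeline_thresholds <- function(fold = 3, floor = 50, pseudocount = 1,
                                min_bias = 0.9, hairpin_threshold = 0.6,
                                lambda = 1.25, min_span = 50L,
                                fold_pad = 30L, min_loop = 3L,
                                flank = 250L, merge_gap = 100L,
                                cutoff = 4.0, window = 0L, rank_max = 5L,
                                abundance_floor = 1000, scale = 1e7,
                                precision_threshold = 0.75) {
  as.list(environment())
}

#' Run the full senescence small RNA + PARE pipeline
#'
#' Simulates (or accepts) the reference and libraries, processes every
#' small RNA library (trim, collapse, exact-map, structural filter, TP2M),
#' screens known miRNAs per tissue, discovers new hairpin loci, predicts
#' targets of the discovered abundant sRNAs, and validates predicted
#' cleavage against the PARE libraries. Identical config and seed give
#' identical outputs.
#'
#' @param config a [simulation_config()], or a pre-built `sim_reference`.
#' @param thresholds a [pipeline_thresholds()] list.
#' @param pare process PARE libraries (skipped when FALSE or when the
#'   design has none).
#' @param outdir optional directory; when given, all result tables are
#'   written as TSV/BED and a run log records per-stage read accounting.
#' @return object of class `senescmir_run`: list with `stats`, `mat`
#'   (distinct-sequence TP2M), `mirna_matrix`, `screens`, `correlations`,
#'   `discovery`, `targets`, `pare_profiles`, `evidence`, `tracking`,
#'   `ref`, `thresholds`, `config_hash`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         thresholds = pipeline_thresholds(),
                         pare = TRUE, outdir = NULL) {
  ref <- if (inherits(config, "sim_reference")) config else
    build_reference(config)
  cfg <- ref$config
  srna <- lapply(seq_len(nrow(cfg$srna_libraries)), function(i) {
    li <- cfg$srna_libraries[i, ]
    sim <- simulate_srna_library(ref, li$tissue, li$stage)
    list(reads = sim$reads, library_id = li$library_id,
         tissue = li$tissue, stage = li$stage)
  })
  pare_in <- NULL
  if (pare && nrow(cfg$pare_libraries)) {
    pare_in <- lapply(seq_len(nrow(cfg$pare_libraries)), function(i) {
      li <- cfg$pare_libraries[i, ]
      sim <- simulate_pare_library(ref, li$stage, li$replicate)
      list(reads = sim$reads, library_id = li$library_id, stage = li$stage)
    })
  }
  catalog <- ledger_catalog(ref)
  res <- run_core(genome = ref$genome, annotations = ref$annotations,
                  transcriptome = ref$transcriptome, catalog = catalog,
                  srna = srna, pare = pare_in, adapter3 = cfg$adapter3,
                  thresholds = thresholds)
  res$ref <- ref
  res$config_hash <- hash_object(list(cfg[setdiff(names(cfg), "planted_loci")],
                                      names(cfg$planted_loci), thresholds))
  res$seed <- cfg$seed
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

# miRNA catalog implied by a reference's known planted matures
ledger_catalog <- function(ref) {
  known <- ref$ledger$matures[ref$ledger$matures$known, , drop = FALSE]
  mirna_catalog(known$mature_id, known$sequence)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

run_core <- function(genome, annotations, transcriptome, catalog, srna,
                     pare = NULL, adapter3, thresholds = pipeline_thresholds()) {
  th <- thresholds
  index <- genome_index(genome)
  # trim + collapse all libraries, then map the union of sequences once
  trimmed <- lapply(srna, function(s) {
    tr <- trim_adapter(s$reads, adapter3)
    rs <- collapse_reads(tr$insert[tr$kept], s$library_id, s$tissue, s$stage)
    list(rs = rs, raw = length(s$reads), kept = sum(tr$kept))
  })
  all_seqs <- unique(unlist(lapply(trimmed, function(t) t$rs$records$sequence)))
  hits <- map_exact(all_seqs, index = index)
  stats_rows <- list()
  retained <- list()
  accounting <- list()
  for (t in trimmed) {
    gm <- filter_genome_matched(t$rs, hits)
    fs <- filter_structural(gm$retained, hits, annotations)
    retained[[t$rs$library_id]] <- fs$retained
    stats_rows[[t$rs$library_id]] <- library_stats(
      t$kept, total_count(gm$retained), fs$structural_count, fs$retained)
    accounting[[t$rs$library_id]] <- c(
      raw = t$raw, trimmed_kept = t$kept, trimmed_rejected = t$raw - t$kept,
      genome_matched = total_count(gm$retained),
      unmatched = gm$unmatched_count, structural = fs$structural_count,
      retained = total_count(fs$retained))
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  mat <- abundance_matrix(retained)
  info <- attr(mat, "library_info")
  hits_retained <- hits[hits$sequence %in% rownames(mat), , drop = FALSE]
  mirna_mat <- quantify_mirnas(mat, catalog)
  tissues <- unique(info$tissue)
  screens <- lapply(stats::setNames(tissues, tissues), function(ti)
    screen_differential(mirna_mat, ti, th$floor, th$fold, th$pseudocount))
  correlations <- do.call(rbind, lapply(tissues, function(ti) {
    mcol <- stage_column(info, ti, "mature")
    do.call(rbind, lapply(setdiff(senescence_stages(), "mature"),
      function(st) {
        r2 <- tryCatch(correlate_libraries(
          mirna_mat, mcol, stage_column(info, ti, st), th$floor),
          error = function(e) NA_real_)
        data.frame(tissue = ti, stage = st, r_squared = as.numeric(r2),
                   n = attr(r2, "n") %||% NA_integer_,
                   stringsAsFactors = FALSE)
      }))
  }))
  discovery <- discover_loci(
    mat, catalog, hits_retained, genome, tissue = "leaf",
    fold = th$fold, floor = th$floor, pseudocount = th$pseudocount,
    flank = th$flank, merge_gap = th$merge_gap, min_bias = th$min_bias,
    fold_pad = th$fold_pad, min_loop = th$min_loop,
    hairpin_threshold = th$hairpin_threshold, lambda = th$lambda,
    min_span = th$min_span, abundance_floor = th$abundance_floor,
    scale = th$scale, precision_threshold = th$precision_threshold)
  # target scan: abundant sRNAs of discovered loci, plus known miRNAs the
  # screen flagged as senescence-induced in any tissue
  scan_seqs <- unique(unlist(lapply(discovery$reports, function(rep)
    rep$srnas$sequence)))
  up_ids <- unique(unlist(lapply(screens, function(s)
    s$mirna[s$candidate_up])))
  scan_seqs <- unique(c(scan_seqs,
                        catalog$sequence[catalog$id %in% up_ids]))
  targets <- do.call(rbind, lapply(scan_seqs, function(s)
    predict_targets(s, transcriptome, th$cutoff)))
  if (is.null(targets))
    targets <- data.frame(srna = character(), transcript_id = character(),
                          site_start = integer(), site_end = integer(),
                          score = numeric(), cleavage_pos = integer(),
                          pairing = character())
  profiles <- NULL; evidence <- NULL; tracking <- NULL
  if (!is.null(pare) && length(pare)) {
    profiles <- lapply(pare, function(p)
      build_pare_profiles(p$reads, transcriptome, p$library_id, p$stage,
                          scale = th$scale))
    names(profiles) <- vapply(pare, `[[`, character(1), "library_id")
    if (nrow(targets)) {
      evidence <- do.call(rbind, lapply(names(profiles), function(lib) {
        do.call(rbind, lapply(seq_len(nrow(targets)), function(a) {
          ev <- validate_cleavage(targets[a, ], profiles[[lib]],
                                  th$window, th$rank_max)
          data.frame(library_id = lib, stage = profiles[[lib]]$stage,
                     srna = targets$srna[a],
                     transcript_id = ev$transcript_id,
                     expected_pos = ev$expected_pos, observed = ev$observed,
                     site_rank = ev$site_rank, fraction = ev$fraction,
                     supported = ev$supported, stringsAsFactors = FALSE)
        }))
      }))
      tracking <- tryCatch(
        track_site_across_stages(targets, profiles, window = th$window),
        error = function(e) NULL)
    }
  }
  structure(list(stats = stats, accounting = accounting, mat = mat,
                 mirna_matrix = mirna_mat, screens = screens,
                 correlations = correlations, discovery = discovery,
                 targets = targets, pare_profiles = profiles,
                 evidence = evidence, tracking = tracking,
                 catalog = catalog, thresholds = th),
            class = "senescmir_run")
}

#' @export
print.senescmir_run <- function(x, ...) {
  cat("senescmir_run\n")
  cat("  libraries:", nrow(x$stats), "sRNA,",
      length(x$pare_profiles %||% list()), "PARE\n")
  up <- sum(vapply(x$screens, function(s) sum(s$candidate_up), numeric(1)))
  dn <- sum(vapply(x$screens, function(s) sum(s$candidate_down), numeric(1)))
  cat("  screen: ", up, " candidate-up, ", dn, " candidate-down miRNA calls\n",
      sep = "")
  cat("  discovered loci:", nrow(x$discovery$loci), "\n")
  cat("  predicted targets (score <= ", x$thresholds$cutoff, "): ",
      nrow(x$targets), "\n", sep = "")
  if (!is.null(x$evidence))
    cat("  PARE-supported evidence rows:", sum(x$evidence$supported), "of",
        nrow(x$evidence), "\n")
  invisible(x)
}

#' Run the pipeline from files on disk
#'
#' Same computation as [run_pipeline()] but reading genome FASTA, GFF3
#' annotations, catalog FASTA, transcriptome FASTA and per-library FASTQ.
#'
#' @param genome_fa,gff3,catalog_fa,transcriptome_fa reference file paths.
#' @param srna_design data.frame: `library_id`, `tissue`, `stage`, `path`.
#' @param pare_design optional data.frame: `library_id`, `stage`, `path`.
#' @param adapter3 3' adapter of the sRNA libraries.
#' @param thresholds a [pipeline_thresholds()] list.
#' @param outdir optional output directory.
#' @return a `senescmir_run` object.
#' @export
run_pipeline_files <- function(genome_fa, gff3, catalog_fa, transcriptome_fa,
                               srna_design, pare_design = NULL,
                               adapter3, thresholds = pipeline_thresholds(),
                               outdir = NULL) {
  srna <- lapply(seq_len(nrow(srna_design)), function(i)
    list(reads = read_fastq(srna_design$path[i]),
         library_id = srna_design$library_id[i],
         tissue = srna_design$tissue[i], stage = srna_design$stage[i]))
  pare <- NULL
  if (!is.null(pare_design) && nrow(pare_design))
    pare <- lapply(seq_len(nrow(pare_design)), function(i)
      list(reads = read_fastq(pare_design$path[i]),
           library_id = pare_design$library_id[i],
           stage = pare_design$stage[i]))
  res <- run_core(genome = read_fasta(genome_fa),
                  annotations = read_gff3(gff3),
                  transcriptome = read_fasta(transcriptome_fa),
                  catalog = read_mirna_catalog(catalog_fa),
                  srna = srna, pare = pare, adapter3 = adapter3,
                  thresholds = thresholds)
  res$config_hash <- hash_object(list(srna_design, pare_design, thresholds))
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' Read a run configuration from YAML
#'
#' Thresholds and simulation settings for a scripted run; unknown keys are
#' rejected. Threshold keys default to the published settings.
#'
#' @param path YAML file.
#' @return list with `config` (simulation_config) and `thresholds`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_keys <- intersect(names(y$simulation %||% list()),
                        names(formals(simulation_config)))
  extra <- setdiff(names(y$simulation %||% list()), sim_keys)
  if (length(extra)) stop("unknown simulation keys: ",
                          paste(extra, collapse = ", "))
  th_keys <- intersect(names(y$thresholds %||% list()),
                       names(formals(pipeline_thresholds)))
  extra <- setdiff(names(y$thresholds %||% list()), th_keys)
  if (length(extra)) stop("unknown threshold keys: ",
                          paste(extra, collapse = ", "))
  list(config = do.call(simulation_config, y$simulation[sim_keys] %||% list()),
       thresholds = do.call(pipeline_thresholds, y$thresholds[th_keys] %||% list()))
}

write_run <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$stats, file.path(outdir, "library_stats.tsv"))
  mirna <- data.frame(mirna = rownames(res$mirna_matrix), res$mirna_matrix,
                      check.names = FALSE)
  write_tsv(mirna, file.path(outdir, "mirna_abundance.tsv"))
  for (ti in names(res$screens))
    write_tsv(res$screens[[ti]], file.path(outdir, paste0("screen_", ti, ".tsv")))
  write_tsv(res$correlations, file.path(outdir, "library_correlations.tsv"))
  write_tsv(res$discovery$loci, file.path(outdir, "loci.tsv"))
  if (nrow(res$discovery$loci))
    write_loci_bed(res$discovery$loci, file.path(outdir, "loci.bed"))
  for (i in seq_along(res$discovery$reports)) {
    rep <- res$discovery$reports[[i]]
    write_tsv(rep$srnas, file.path(outdir, sprintf("locus%02d_srnas.tsv", i)))
    write_tsv(rep$track, file.path(outdir, sprintf("locus%02d_track.bedgraph.tsv", i)))
  }
  write_tsv(res$targets, file.path(outdir, "targets.tsv"))
  if (!is.null(res$pare_profiles)) {
    pstats <- do.call(rbind, lapply(res$pare_profiles, `[[`, "stats"))
    rownames(pstats) <- NULL
    write_tsv(pstats, file.path(outdir, "pare_stats.tsv"))
  }
  if (!is.null(res$evidence))
    write_tsv(res$evidence, file.path(outdir, "cleavage_evidence.tsv"))
  if (!is.null(res$tracking)) {
    write_tsv(res$tracking$table, file.path(outdir, "site_tracking.tsv"))
    write_tsv(res$tracking$trends, file.path(outdir, "site_trends.tsv"))
  }
  log <- c(sprintf("senescmir run  config_hash=%s", res$config_hash %||% ""),
           "per-library read accounting:",
           vapply(names(res$accounting), function(id)
             paste0("  ", id, ": ",
                    paste(names(res$accounting[[id]]),
                          res$accounting[[id]], sep = "=", collapse = " ")),
             character(1)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
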