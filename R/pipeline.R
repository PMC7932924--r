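# Pipeline orchestration: stage runner, run directory artifacts, manifest.

#' Pipeline run configuration
#'
#' Bundles everything a pipeline run needs. A single `seed` feeds derived
#' per-stage/per-case generators, so stages are individually re-runnable
#' with stable results.
#'
#' @param seed Integer master seed.
#' @param reference_fasta Optional path to a germline reference FASTA; if
#'   `NULL`, a toy reference is built from the seed.
#' @param segments_per_type Toy reference size (used when
#'   `reference_fasta` is `NULL`).
#' @param sim [simulation_params()].
#' @param annotation [annotation_params()].
#' @param thresholds [marker_thresholds()].
#' @param match_mode `"exact_key"` or `"allow_damaged_partial"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, reference_fasta = NULL,
                       segments_per_type = 3,
                       sim = simulation_params(),
                       annotation = annotation_params(),
                       thresholds = marker_thresholds(),
                       match_mode = c("exact_key", "allow_damaged_partial")) {
  structure(list(seed = as.integer(seed), reference_fasta = reference_fasta,
                 segments_per_type = as.integer(segments_per_type),
                 sim = sim, annotation = annotation,
                 thresholds = thresholds,
                 match_mode = match.arg(match_mode)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()], [simulation_params()], [annotation_params()] and
#' [marker_thresholds()] (under `sim`, `annotation`, `thresholds`). Unknown
#' keys are a validation error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("seed", "reference_fasta", "segments_per_type", "sim",
                 "annotation", "thresholds", "match_mode")
  bad <- setdiff(names(y), known_top)
  if (length(bad) > 0) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  check_args <- function(given, fn, where) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0) {
      abort(paste0("unknown config field(s) under ", where, ": ",
                   paste(bad, collapse = ", ")))
    }
    given
  }
  sim <- do.call(simulation_params,
                 check_args(y$sim %||% list(), simulation_params, "sim"))
  ann <- do.call(annotation_params,
                 check_args(y$annotation %||% list(), annotation_params,
                            "annotation"))
  thr <- do.call(marker_thresholds,
                 check_args(y$thresholds %||% list(), marker_thresholds,
                            "thresholds"))
  run_config(seed = y$seed %||% 1, reference_fasta = y$reference_fasta,
             segments_per_type = y$segments_per_type %||% 3,
             sim = sim, annotation = ann, thresholds = thr,
             match_mode = y$match_mode %||% "exact_key")
}

config_fingerprint <- function(config) {
  s <- yaml::as.yaml(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else if (is.list(x)) unclass(x) else x
  }))
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", h)
}

pipeline_log <- function(...) message("[immunomark] ", ...)

#' Run the pipeline
#'
#' Executes the requested stages in order (`simulate`, `annotate`,
#' `markers`, `compare`), writing all artifacts (reference FASTA, truth
#' tables, per-tube and paired FASTQ reads, AIRR-flavored rearrangement
#' TSVs, marker and removal-log TSVs, concordance summaries, a plain-text
#' per-class render) plus a machine-readable `manifest.json` into `out_dir`.
#' Later stages consume only configuration and prior-stage files, so any
#' stage can be re-run alone.
#'
#' @param config A `run_config` (or YAML path).
#' @param stages Subset of `c("simulate", "annotate", "markers", "compare")`.
#' @param out_dir Run directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "annotate", "markers",
                                    "compare"),
                         out_dir = "immunomark_run") {
  if (is.character(config)) config <- load_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(out_dir, "reference.fasta"),
    truth = file.path(out_dir, "truth.tsv"),
    dnaamp_reads = file.path(out_dir, "reads_dnaamp"),
    rnaseq_reads = file.path(out_dir, "reads_rnaseq"),
    rearr = file.path(out_dir, "rearrangements.tsv"),
    removed = file.path(out_dir, "uniqueness_removed.tsv"),
    dnaamp_markers = file.path(out_dir, "markers_dnaamp.tsv"),
    rnaseq_records = file.path(out_dir, "rearrangements_rnaseq_filtered.tsv"),
    verdicts = file.path(out_dir, "marker_verdicts.tsv"),
    per_class = file.path(out_dir, "summary_per_class.tsv"),
    per_case = file.path(out_dir, "summary_per_case.tsv"),
    overall = file.path(out_dir, "summary_overall.json"),
    render = file.path(out_dir, "summary_per_class.txt"),
    manifest = file.path(out_dir, "manifest.json")
  )
  counts <- list()
  need <- function(path, stage) {
    if (!file.exists(path)) {
      abort(paste0("stage '", stage, "' needs missing input: ", path))
    }
    path
  }

  if ("simulate" %in% stages) {
    pipeline_log("stage simulate")
    ref <- if (is.null(config$reference_fasta)) {
      r <- build_toy_reference(config$seed, config$segments_per_type)
      write_germline_reference(r, paths$reference)
      r
    } else {
      r <- load_germline_reference(config$reference_fasta)
      write_germline_reference(r, paths$reference)
      r
    }
    truth <- simulate_cohort(ref, config$sim, config$seed)
    write_tsv_file(truth, paths$truth)
    counts$truth_rows <- nrow(truth)
    dna <- simulate_dnaamp_reads(truth, config$sim, config$seed)
    dir.create(paths$dnaamp_reads, showWarnings = FALSE)
    for (cid in unique(dna$case_id)) {
      for (tb in unique(dna$tube[dna$case_id == cid])) {
        sub <- dna[dna$case_id == cid & dna$tube == tb, ]
        write_fastq(sub, file.path(paths$dnaamp_reads,
                                   paste0(cid, "_", gsub("[/ ]", "-", tb),
                                          ".fastq")))
      }
    }
    readr::write_tsv(dna, file.path(paths$dnaamp_reads, "reads.tsv"))
    counts$dnaamp_reads <- nrow(dna)
    rna <- simulate_rnaseq_reads(truth, config$sim, config$seed)
    dir.create(paths$rnaseq_reads, showWarnings = FALSE)
    for (cid in unique(rna$case_id)) {
      sub <- rna[rna$case_id == cid, ]
      write_fastq(sub, file.path(paths$rnaseq_reads, paste0(cid, "_R1.fastq")))
      write_fastq(dplyr::mutate(sub, sequence = .data$sequence2),
                  file.path(paths$rnaseq_reads, paste0(cid, "_R2.fastq")))
    }
    readr::write_tsv(rna, file.path(paths$rnaseq_reads, "reads.tsv"))
    counts$rnaseq_fragments <- nrow(rna)
  }

  if ("annotate" %in% stages) {
    pipeline_log("stage annotate")
    ref <- load_germline_reference(need(paths$reference, "annotate"))
    idx <- build_alignment_index(ref, config$annotation)
    dna <- readr::read_tsv(need(file.path(paths$dnaamp_reads, "reads.tsv"),
                                "annotate"), show_col_types = FALSE)
    rna <- readr::read_tsv(need(file.path(paths$rnaseq_reads, "reads.tsv"),
                                "annotate"), show_col_types = FALSE)
    ann <- dplyr::bind_rows(
      deduplicate(annotate_reads(dna, idx, config$annotation)),
      deduplicate(annotate_reads(rna, idx, config$annotation)))
    write_tsv_file(ann, paths$rearr)
    counts$rearrangements <- nrow(ann)
  }

  if ("markers" %in% stages) {
    pipeline_log("stage markers")
    rearr <- readr::read_tsv(need(paths$rearr, "markers"),
                             show_col_types = FALSE)
    fl <- apply_uniqueness_filter(rearr)
    write_tsv_file(fl$removed, paths$removed)
    mk <- identify_dnaamp_markers(fl$kept, config$thresholds)
    write_tsv_file(mk, paths$dnaamp_markers)
    rn <- identify_rnaseq_rearrangements(fl$kept, config$thresholds)
    write_tsv_file(rn, paths$rnaseq_records)
    counts$removed_rows <- nrow(fl$removed)
    counts$dnaamp_markers <- nrow(mk)
    counts$rnaseq_records <- nrow(rn)
  }

  if ("compare" %in% stages) {
    pipeline_log("stage compare")
    rearr <- readr::read_tsv(need(paths$rearr, "compare"),
                             show_col_types = FALSE)
    mk <- readr::read_tsv(need(paths$dnaamp_markers, "compare"),
                          show_col_types = FALSE)
    rn <- readr::read_tsv(need(paths$rnaseq_records, "compare"),
                          show_col_types = FALSE)
    fl <- apply_uniqueness_filter(rearr)
    verdicts <- match_markers(mk, rn, config$match_mode)
    write_tsv_file(verdicts, paths$verdicts)
    summ <- summarize_concordance(fl$kept, verdicts)
    write_tsv_file(summ$per_class, paths$per_class)
    write_tsv_file(summ$per_case, paths$per_case)
    jsonlite::write_json(summ$overall, paths$overall, auto_unbox = TRUE,
                         digits = NA)
    writeLines(utils::capture.output(print(summ)), paths$render)
    counts$verdicts <- nrow(verdicts)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("immunomark")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_fingerprint = config_fingerprint(config),
    stages = stages,
    row_counts = counts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(manifest)
}
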