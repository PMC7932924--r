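# MRD marker identification: cross-case uniqueness filter and
# abundance/fraction thresholds.

#' Marker abundance thresholds
#'
#' Thresholds for calling candidate MRD markers: a minimum absolute
#' abundance and a minimum fraction of the reads in the marker's primer
#' tube. Both bounds are inclusive (a "minimum of 10 reads" admits 10).
#' RNAseq rearrangements are searched at any abundance by default;
#' `apply_to_rnaseq = TRUE` imposes the same thresholds with per-locus
#' denominators (RNAseq has no tubes).
#'
#' @param min_reads Minimum de-duplicated count (default 10).
#' @param min_fraction Minimum within-tube (or within-locus) fraction
#'   (default 0.05).
#' @param apply_to_rnaseq Apply thresholds to RNAseq too (default `FALSE`).
#' @return A list of class `marker_thresholds`.
#' @export
marker_thresholds <- function(min_reads = 10, min_fraction = 0.05,
                              apply_to_rnaseq = FALSE) {
  if (min_reads < 0) abort("min_reads must be >= 0")
  if (min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must lie in [0, 1]")
  }
  structure(list(min_reads = min_reads, min_fraction = min_fraction,
                 apply_to_rnaseq = apply_to_rnaseq),
            class = "marker_thresholds")
}

#' Remove rearrangements shared across cases
#'
#' Any complete identity key observed in more than one case (on either
#' platform) is removed from every case: true clone-specific rearrangements
#' appear uniquely across cases, so recurrence signals contamination or
#' artefacts. Damaged records carry partial keys, which are not comparable
#' identities, and are never removed. The filter is idempotent.
#'
#' @param tbl Rearrangement table (from [deduplicate()]) over one or more
#'   cases, with columns `case_id`, `platform`, `key`, `damaged`.
#' @return List with `kept` (filtered table) and `removed` (removal log:
#'   one row per removed table row, plus the set of cases sharing the key).
#' @export
apply_uniqueness_filter <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0) {
    return(list(kept = tbl, removed = dplyr::mutate(tbl, shared_cases =
                                                      character(0))))
  }
  complete <- dplyr::filter(tbl, !.data$damaged)
  shared <- complete |>
    dplyr::distinct(.data$key, .data$case_id) |>
    dplyr::count(.data$key, name = "n_cases") |>
    dplyr::filter(.data$n_cases > 1)
  flagged <- dplyr::semi_join(complete, shared, by = "key")
  case_sets <- flagged |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(shared_cases = paste(sort(unique(.data$case_id)),
                                          collapse = ","),
                     .groups = "drop")
  removed <- dplyr::left_join(flagged, case_sets, by = "key")
  kept <- dplyr::anti_join(tbl, dplyr::mutate(shared, damaged = FALSE),
                           by = c("key", "damaged"))
  list(kept = kept, removed = removed)
}

# within-group totals and fractions
add_fraction <- function(tbl, group_col) {
  tbl |>
    dplyr::group_by(.data$case_id, .data[[group_col]]) |>
    dplyr::mutate(group_total = sum(.data$count),
                  fraction = .data$count / .data$group_total) |>
    dplyr::ungroup()
}

#' Identify candidate MRD markers in DNAamp data
#'
#' Applies the abundance thresholds to a uniqueness-filtered DNAamp
#' rearrangement table: a key qualifies when its de-duplicated read count is
#' at least `min_reads` and its fraction of all annotated,
#' uniqueness-surviving reads in the same primer tube is at least
#' `min_fraction` (both inclusive). The tube total is the denominator.
#'
#' @param tbl DNAamp rearrangement table (post uniqueness filter) with
#'   columns `case_id`, `tube`, `key`, `count`.
#' @param thresholds [marker_thresholds()].
#' @return Marker tibble sorted by case then descending fraction, with
#'   `count`, `tube_total`, `fraction`.
#' @export
identify_dnaamp_markers <- function(tbl, thresholds = marker_thresholds()) {
  tbl <- dplyr::filter(tibble::as_tibble(tbl), .data$platform == "DNAamp")
  if (nrow(tbl) == 0) {
    return(dplyr::mutate(tbl, group_total = integer(0), fraction = numeric(0)))
  }
  bad_tube <- setdiff(unique(tbl$tube), unique(tube_definitions()$tube))
  if (length(bad_tube) > 0) {
    abort(paste0("unknown tube label(s): ", paste(bad_tube, collapse = ", ")))
  }
  tbl |>
    add_fraction("tube") |>
    dplyr::filter(!.data$damaged,
                  .data$count >= thresholds$min_reads,
                  .data$fraction >= thresholds$min_fraction) |>
    dplyr::rename(tube_total = "group_total") |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$fraction), .data$key)
}

#' Collect RNAseq rearrangements for marker matching
#'
#' With thresholds off (`apply_to_rnaseq = FALSE`, the default) every
#' uniqueness-surviving RNAseq key is returned at any abundance (count >= 1).
#' With thresholds on, `min_reads`/`min_fraction` are applied with the
#' fraction computed within the key's locus group (RNAseq has no primer
#' tubes).
#'
#' @param tbl RNAseq rearrangement table (post uniqueness filter).
#' @param thresholds [marker_thresholds()].
#' @return Tibble of RNAseq rearrangements with `count`, `locus_total`,
#'   `fraction`.
#' @export
identify_rnaseq_rearrangements <- function(tbl,
                                           thresholds = marker_thresholds()) {
  tbl <- dplyr::filter(tibble::as_tibble(tbl), .data$platform == "RNAseq")
  if (nrow(tbl) == 0) {
    return(dplyr::mutate(tbl, group_total = integer(0), fraction = numeric(0)))
  }
  out <- add_fraction(tbl, "locus_group") |>
    dplyr::rename(locus_total = "group_total")
  if (isTRUE(thresholds$apply_to_rnaseq)) {
    out <- dplyr::filter(out, !.data$damaged,
                         .data$count >= thresholds$min_reads,
                         .data$fraction >= thresholds$min_fraction)
  }
  dplyr::arrange(out, .data$case_id, dplyr::desc(.data$fraction), .data$key)
}
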