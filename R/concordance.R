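# Cross-platform concordance: match DNAamp markers against RNAseq
# rearrangements; per-class and per-case summaries.

#' Match DNAamp markers against RNAseq rearrangements
#'
#' For every DNAamp marker, searches the RNAseq rearrangements of the same
#' case for the marker's identity key at any abundance. Under `exact_key`
#' (default) only undamaged RNAseq records with an equal key match. Under
#' `allow_damaged_partial`, a damaged RNAseq record additionally matches
#' when it agrees on junction class, both genes, and every segmentation
#' statistic its coverage determined (undetermined components are not
#' compared).
#'
#' @param dnaamp_markers Marker tibble from [identify_dnaamp_markers()].
#' @param rnaseq_records RNAseq rearrangement tibble (same cases, post
#'   uniqueness filter), e.g. from [identify_rnaseq_rearrangements()].
#' @param mode `"exact_key"` or `"allow_damaged_partial"`.
#' @return The marker tibble plus `matched`, `match_type` (`exact`,
#'   `damaged_partial` or `NA`) and `rnaseq_count`.
#' @export
match_markers <- function(dnaamp_markers, rnaseq_records,
                          mode = c("exact_key", "allow_damaged_partial")) {
  mode <- match.arg(mode)
  m <- tibble::as_tibble(dnaamp_markers)
  r <- tibble::as_tibble(rnaseq_records)
  if (nrow(m) > 0 && nrow(r) > 0 &&
      length(unique(m$case_id)) == 1 && length(unique(r$case_id)) == 1 &&
      unique(m$case_id) != unique(r$case_id)) {
    abort(paste0("case-id mismatch: markers from ", unique(m$case_id),
                 ", RNAseq records from ", unique(r$case_id)))
  }
  m$matched <- FALSE
  m$match_type <- NA_character_
  m$rnaseq_count <- NA_integer_
  if (nrow(m) == 0) return(m)
  intact <- r[!r$damaged, ]
  hit <- match(paste(m$case_id, m$key), paste(intact$case_id, intact$key))
  found <- !is.na(hit)
  m$matched[found] <- TRUE
  m$match_type[found] <- "exact"
  m$rnaseq_count[found] <- intact$count[hit[found]]
  if (mode == "allow_damaged_partial") {
    dam <- r[r$damaged, ]
    for (i in which(!m$matched)) {
      cand <- dam[dam$case_id == m$case_id[i] &
                    dam$junction_class == m$junction_class[i] &
                    dam$five_gene == m$five_gene[i] &
                    dam$three_gene == m$three_gene[i], ]
      if (nrow(cand) == 0) next
      ok <- rep(TRUE, nrow(cand))
      for (f in c("five_del", "ndn_length", "three_del")) {
        known <- !is.na(cand[[f]])
        ok <- ok & (!known | cand[[f]] == m[[f]][i])
      }
      if (any(ok)) {
        m$matched[i] <- TRUE
        m$match_type[i] <- "damaged_partial"
        m$rnaseq_count[i] <- max(cand$count[ok])
      }
    }
  }
  m
}

# per-case-and-class mean count of distinct rearrangements for one platform
mean_per_case <- function(tbl, platform, cases, filter_expr = NULL) {
  sub <- tbl[tbl$platform == platform, ]
  if (!is.null(filter_expr)) sub <- sub[filter_expr(sub), ]
  counts <- sub |>
    dplyr::count(.data$junction_class, .data$case_id) |>
    dplyr::group_by(.data$junction_class) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  setNames(counts$total / length(cases), counts$junction_class)
}

lookup0 <- function(v, labels) {
  out <- unname(v[labels])
  out[is.na(out)] <- 0
  out
}

#' Per-class concordance summary
#'
#' Builds the per-junction-class table: mean rearrangements per case on each
#' platform (with the RNAseq damaged and productive components), DNAamp
#' marker counts, RNAseq-recovered counts, and recovery percentages (one
#' decimal). Classes no primer tube amplifies carry `NA` marker columns.
#' Rows are in the canonical 22-row order.
#'
#' @param rearr Combined rearrangement table (both platforms, post
#'   uniqueness filter).
#' @param verdicts Marker match verdicts from [match_markers()].
#' @return Tibble with one row per junction class.
#' @export
summarize_by_class <- function(rearr, verdicts) {
  reg <- junction_classes()
  cases <- sort(unique(rearr$case_id))
  dna <- mean_per_case(rearr, "DNAamp", cases)
  rna <- mean_per_case(rearr, "RNAseq", cases)
  rna_dam <- mean_per_case(rearr, "RNAseq", cases,
                           function(s) s$damaged)
  rna_prod <- mean_per_case(rearr, "RNAseq", cases,
                            function(s) s$productivity %in% "productive")
  mk <- verdicts |>
    dplyr::count(.data$junction_class, name = "dnaamp_markers")
  rec <- verdicts |>
    dplyr::filter(.data$matched) |>
    dplyr::count(.data$junction_class, name = "rnaseq_recovered")
  amplifiable <- reg$label %in% tube_definitions()$junction_class
  out <- tibble::tibble(
    junction_class = reg$label,
    locus_group = reg$locus_group,
    category = reg$category,
    dnaamp_per_case = lookup0(dna, reg$label),
    rnaseq_per_case = lookup0(rna, reg$label),
    rnaseq_damaged_per_case = lookup0(rna_dam, reg$label),
    rnaseq_productive_per_case = lookup0(rna_prod, reg$label),
    dnaamp_markers = lookup0(setNames(mk$dnaamp_markers, mk$junction_class),
                             reg$label),
    rnaseq_recovered = lookup0(setNames(rec$rnaseq_recovered,
                                        rec$junction_class), reg$label)
  )
  out$recovery_pct <- ifelse(out$dnaamp_markers > 0,
                             round(100 * out$rnaseq_recovered /
                                     out$dnaamp_markers, 1), NA_real_)
  out$dnaamp_markers[!amplifiable] <- NA_integer_
  out$rnaseq_recovered[!amplifiable] <- NA_integer_
  out$recovery_pct[!amplifiable] <- NA_real_
  out$dnaamp_per_case[!amplifiable] <- NA_real_
  out
}

#' Per-case marker counts
#'
#' Per case: number of DNAamp markers, number recovered in RNAseq, RNAseq
#' marker count (thresholded when `rnaseq_markers` comes from
#' `apply_to_rnaseq = TRUE`), and the 0/1/2/3/>=4 availability categories
#' used in clinical protocols (>=2 markers required by most).
#'
#' @param verdicts Marker match verdicts from [match_markers()].
#' @param rnaseq_markers Optional RNAseq marker tibble (e.g.
#'   [identify_rnaseq_rearrangements()] with thresholds applied).
#' @param cases Optional character vector of all case ids (cases with zero
#'   markers on both platforms are kept as all-zero rows).
#' @return Tibble with one row per case.
#' @export
summarize_per_case <- function(verdicts, rnaseq_markers = NULL,
                               cases = NULL) {
  cases <- cases %||% sort(unique(c(verdicts$case_id,
                                    rnaseq_markers$case_id)))
  dn <- verdicts |> dplyr::count(.data$case_id, name = "dnaamp_markers")
  rc <- verdicts |> dplyr::filter(.data$matched) |>
    dplyr::count(.data$case_id, name = "recovered")
  out <- tibble::tibble(case_id = cases) |>
    dplyr::left_join(dn, by = "case_id") |>
    dplyr::left_join(rc, by = "case_id") |>
    tidyr::replace_na(list(dnaamp_markers = 0L, recovered = 0L))
  if (!is.null(rnaseq_markers)) {
    rn <- rnaseq_markers |> dplyr::count(.data$case_id,
                                         name = "rnaseq_markers")
    out <- dplyr::left_join(out, rn, by = "case_id") |>
      tidyr::replace_na(list(rnaseq_markers = 0L))
  } else {
    out$rnaseq_markers <- NA_integer_
  }
  band <- function(n) dplyr::case_when(n == 0 ~ "0", n == 1 ~ "1",
                                       n == 2 ~ "2", n == 3 ~ "3",
                                       TRUE ~ ">=4")
  out$dnaamp_band <- band(out$dnaamp_markers)
  out$recovered_band <- band(out$recovered)
  out$ge2_dnaamp <- out$dnaamp_markers >= 2
  out$ge2_recovered <- out$recovered >= 2
  out
}

#' Full concordance summary
#'
#' Convenience wrapper building the per-class table, the per-case table and
#' overall totals from a combined rearrangement table and marker match
#' verdicts. Returns a `concordance_summary` object with [print()],
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams summarize_by_class
#' @inheritParams summarize_per_case
#' @return A `concordance_summary` object (list with `per_class`,
#'   `per_case`, `overall`).
#' @export
summarize_concordance <- function(rearr, verdicts, rnaseq_markers = NULL) {
  cases <- sort(unique(rearr$case_id))
  per_class <- summarize_by_class(rearr, verdicts)
  per_case <- summarize_per_case(verdicts, rnaseq_markers, cases)
  rna <- rearr[rearr$platform == "RNAseq", ]
  dna <- rearr[rearr$platform == "DNAamp", ]
  overall <- list(
    n_cases = length(cases),
    dnaamp_markers = sum(per_case$dnaamp_markers),
    rnaseq_recovered = sum(per_case$recovered),
    recovery_pct = ifelse(sum(per_case$dnaamp_markers) > 0,
                          round(100 * sum(per_case$recovered) /
                                  sum(per_case$dnaamp_markers), 1), NA_real_),
    dnaamp_rearr_per_case = nrow(dna) / length(cases),
    rnaseq_rearr_per_case = nrow(rna) / length(cases),
    rnaseq_damaged_fraction = if (nrow(rna) > 0) mean(rna$damaged) else
      NA_real_,
    dnaamp_unproductive_fraction = if (nrow(dna) > 0)
      mean(dna$productivity == "unproductive") else NA_real_,
    rnaseq_unproductive_fraction = if (nrow(rna) > 0)
      mean(rna$productivity == "unproductive") else NA_real_,
    ge2_dnaamp_cases = sum(per_case$ge2_dnaamp),
    ge2_recovered_cases = sum(per_case$ge2_recovered)
  )
  structure(list(per_class = per_class, per_case = per_case,
                 overall = overall),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  pc <- x$per_class
  fmt <- function(v, digits = 1) ifelse(is.na(v), "na",
                                        formatC(v, format = "f",
                                                digits = digits))
  cat("IG/TR rearrangements and MRD marker recovery by junction class\n")
  cat(sprintf("%-12s %-8s %9s %16s %8s %8s %8s\n", "class", "group",
              "DNAamp/c", "RNAseq/c (dmg)", "mDNAamp", "mRNAseq", "rec%"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("%-12s %-8s %9s %10s (%s) %8s %8s %8s\n",
                pc$junction_class[i], pc$locus_group[i],
                fmt(pc$dnaamp_per_case[i]),
                fmt(pc$rnaseq_per_case[i]),
                fmt(pc$rnaseq_damaged_per_case[i]),
                ifelse(is.na(pc$dnaamp_markers[i]), "na",
                       pc$dnaamp_markers[i]),
                ifelse(is.na(pc$rnaseq_recovered[i]), "na",
                       pc$rnaseq_recovered[i]),
                fmt(pc$recovery_pct[i])))
  }
  ov <- x$overall
  cat(sprintf("\n%d cases; %d DNAamp markers, %d recovered by RNAseq (%s%%)\n",
              ov$n_cases, ov$dnaamp_markers, ov$rnaseq_recovered,
              fmt(ov$recovery_pct)))
  cat(sprintf(">=2 markers: %d/%d cases by DNAamp, %d/%d by RNAseq recovery\n",
              ov$ge2_dnaamp_cases, ov$n_cases, ov$ge2_recovered_cases,
              ov$n_cases))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance summary
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return The per-class tibble (22 rows).
#' @method tidy concordance_summary
#' @export
tidy.concordance_summary <- function(x, ...) x$per_class

#' One-row overall summary of a concordance analysis
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return One-row tibble of cohort-level totals.
#' @method glance concordance_summary
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble::as_tibble(x$overall)
}
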