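# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_ref <- function() fixture("toy_ref", build_toy_reference(1, 3))

toy_index <- function() {
  fixture("toy_index", build_alignment_index(toy_ref()))
}

# small but complete two-case simulation used by several unit tests
mini_params <- function(...) {
  simulation_params(n_cases = 2, background_size = 20,
                    dnaamp_depth_per_tube = 400, rnaseq_fragments = 400, ...)
}

mini_sim <- function() {
  fixture("mini_sim", {
    p <- mini_params()
    ref <- toy_ref()
    truth <- suppressWarnings(simulate_cohort(ref, p, seed = 11))
    dna <- suppressWarnings(simulate_dnaamp_reads(truth, p, seed = 11))
    rna <- suppressWarnings(simulate_rnaseq_reads(truth, p, seed = 11))
    idx <- toy_index()
    adna <- annotate_reads(dna, idx)
    arna <- annotate_reads(rna, idx)
    rearr <- dplyr::bind_rows(deduplicate(adna), deduplicate(arna))
    list(params = p, truth = truth, dna = dna, rna = rna,
         adna = adna, arna = arna, rearr = rearr)
  })
}

# independent productivity oracle: locates the 3' (J) segment in the full
# rearranged sequence by longest-common-suffix string search, derives the
# frame of the J anchor from that position, and translates the whole
# V-anchored span for stop codons.
oracle_productivity_complete <- function(sequence, five_gene, three_gene,
                                         ref) {
  v0 <- ref$frame_anchor[ref$name == five_gene]
  j_seq <- ref$sequence[ref$name == three_gene]
  j0 <- ref$frame_anchor[ref$name == three_gene]
  s_chars <- strsplit(sequence, "")[[1]]
  j_chars <- strsplit(j_seq, "")[[1]]
  ls <- length(s_chars)
  lj <- length(j_chars)
  # longest common suffix of sequence and the J segment
  n <- min(ls, lj)
  eq <- rev(s_chars)[1:n] == rev(j_chars)[1:n]
  lcs <- if (all(eq)) n else which(!eq)[1] - 1L
  stopifnot(lcs >= 1)
  td <- lj - lcs                      # bases trimmed from the J 5' end
  p0 <- td + ((j0 - td) %% 3L)        # first in-frame J base kept
  pos_in_s <- ls - lcs + (p0 - td)    # 0-based position of that base
  in_frame <- ((pos_in_s - v0) %% 3L) == 0L
  aa <- translate_junction(substring(sequence, v0 + 1), 0)
  if (in_frame && !grepl("*", aa, fixed = TRUE)) "productive" else
    "unproductive"
}

# Full-size study-condition run shared by the acceptance tests: 20 cases
# under default simulation parameters, both platforms, annotated end to end.
acceptance_run <- function() {
  fixture("acceptance_run", {
    ref <- build_toy_reference(42, 3)
    p <- simulation_params()
    idx <- build_alignment_index(ref)
    truth <- suppressWarnings(simulate_cohort(ref, p, seed = 42))
    dna <- suppressWarnings(simulate_dnaamp_reads(truth, p, seed = 42))
    rna <- suppressWarnings(simulate_rnaseq_reads(truth, p, seed = 42))
    adna <- annotate_reads(dna, idx)
    arna <- annotate_reads(rna, idx)
    rearr <- dplyr::bind_rows(deduplicate(adna), deduplicate(arna))
    fl <- apply_uniqueness_filter(rearr)
    markers <- identify_dnaamp_markers(fl$kept, marker_thresholds())
    rnaseq_records <- identify_rnaseq_rearrangements(fl$kept,
                                                     marker_thresholds())
    verdicts <- match_markers(markers, rnaseq_records, "exact_key")
    verdicts_partial <- match_markers(markers, rnaseq_records,
                                      "allow_damaged_partial")
    summary <- summarize_concordance(fl$kept, verdicts)
    list(ref = ref, params = p, idx = idx, truth = truth, dna = dna,
         rna = rna, adna = adna, arna = arna, rearr = rearr,
         kept = fl$kept, removed = fl$removed, markers = markers,
         rnaseq_records = rnaseq_records, verdicts = verdicts,
         verdicts_partial = verdicts_partial, summary = summary)
  })
}
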