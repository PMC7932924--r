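# Synthetic ground truth: clonal + polyclonal rearrangements per case, and
# platform-specific reads (per-tube amplicons; paired-end transcriptome
# fragments under a three-tier transcription model).

#' EuroClonality-style primer-set tubes
#'
#' The eight DNA-amplicon tubes and the junction classes each amplifies.
#' IGL and TRA-5' classes (Vl-Jl, Va-Ja, Va-Jd, Va-Dd), the TRB classes
#' without a primer pair (Vb-Db, Db-Db) and the TRD classes lacking a
#' forward Dd3 primer (Dd3-Jd, Dd3-Dd2) belong to no tube and are therefore
#' RNAseq-only.
#'
#' @return Tibble with columns `tube` and `junction_class` (long form; one
#'   row per amplifiable class).
#' @export
tube_definitions <- function() {
  tibble::tribble(
    ~tube,             ~junction_class,
    "IGHV-IGHD-IGHJ",  "Vh-(Dh)-Jh",
    "IGHD-IGHJ",       "Dh-Jh",
    "IGKV-IGKJ/Kde",   "Vk-Jk",
    "IGKV-IGKJ/Kde",   "Vk-Kde",
    "intronRSS-Kde",   "intron-Kde",
    "TRBV-TRBD-TRBJ",  "Vb-(Db)-Jb",
    "TRBD-TRBJ",       "Db-Jb",
    "TRG",             "Vg-Jg",
    "TRD",             "Vd-(Dd)-Jd",
    "TRD",             "Dd2-Jd1",
    "TRD",             "Vd-Dd3",
    "TRD",             "Dd2-Dd3",
    "TRD",             "Vd-(Dd)-Ja",
    "TRD",             "Dd-Ja"
  )
}

#' Default clonal plan
#'
#' One leukemic clone per case: two complete IGH alleles (each unproductive
#' with probability 0.7, the typical fraction in ALL), one incomplete IGH
#' DJ, one IGK VJ, one IGK Kde, and one complete TRB, TRG and TRD
#' rearrangement each. `unproductive_prob` of `NA` leaves productivity to
#' the junction lottery.
#'
#' @return Tibble with columns `junction_class`, `n`, `unproductive_prob`.
#' @export
default_clonal_plan <- function() {
  tibble::tribble(
    ~junction_class, ~n, ~unproductive_prob,
    "Vh-(Dh)-Jh",    2L, 0.7,
    "Dh-Jh",         1L, NA,
    "Vk-Jk",         1L, NA,
    "Vk-Kde",        1L, NA,
    "Vb-(Db)-Jb",    1L, NA,
    "Vg-Jg",         1L, NA,
    "Vd-(Dd)-Jd",    1L, NA
  )
}

#' Simulation parameters
#'
#' Study conditions for the synthetic cohort. Defaults: clones carry the
#' [default_clonal_plan()]; the polyclonal background is >98% productive
#' among complete rearrangements; junctional deletions are uniform on
#' 0..`deletion_max`; N-(D)-N lengths are geometric with mean `ndn_mean`;
#' amplicon reads are drawn per tube with the clone holding `blast_fraction`
#' of tube reads; transcriptome fragments are 2 x `read_length` bp pairs with
#' truncated-normal fragment lengths, sampled proportional to cellular
#' abundance times a three-tier transcription rate (productive complete
#' 1.0, unproductive complete `sterile_rate`, incomplete/other
#' `incomplete_rate`).
#'
#' @param n_cases Number of simulated cases (default 20).
#' @param clonal_plan Tibble as [default_clonal_plan()].
#' @param background_size Background rearrangements per case (default 80).
#' @param background_productive_fraction Productive fraction among complete
#'   background rearrangements (default 0.98).
#' @param background_class_weights Named numeric vector of per-class
#'   sampling weights for background draws; default weights complete-VJ
#'   classes 3, all other classes 1.
#' @param deletion_max Maximum junctional deletion per segment end
#'   (default 10, uniform; clamped so segments stay alignable).
#' @param ndn_mean Mean N-(D)-N insertion length (geometric, default 8).
#' @param blast_fraction Clonal share of tube reads / leukemic cell fraction
#'   (default 0.9).
#' @param dnaamp_depth_per_tube Amplicon reads per tube (default 1500).
#' @param rnaseq_fragments Transcriptome fragments per case (default 2500).
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   Fragment length model (normal, truncated at `fragment_length_min`;
#'   defaults 250/50/150).
#' @param read_length Read length, paired (default 75).
#' @param context_length Junction-centered transcript context for fragment
#'   placement (default 600 nt).
#' @param productive_rate,sterile_rate,incomplete_rate Relative transcription
#'   of productive complete / unproductive complete / incomplete-or-other
#'   rearrangements (defaults 1.0 / 0.01 / 0.001).
#' @param error_rate Per-base substitution rate applied to reads (default 0;
#'   reads are error-free).
#' @param annotation [annotation_params()] used for canonical truth
#'   annotation.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_cases = 20,
                              clonal_plan = default_clonal_plan(),
                              background_size = 80,
                              background_productive_fraction = 0.98,
                              background_class_weights = NULL,
                              deletion_max = 10,
                              ndn_mean = 8,
                              blast_fraction = 0.9,
                              dnaamp_depth_per_tube = 1500,
                              rnaseq_fragments = 2500,
                              fragment_length_mean = 250,
                              fragment_length_sd = 50,
                              fragment_length_min = 150,
                              read_length = 75,
                              context_length = 600,
                              productive_rate = 1.0,
                              sterile_rate = 0.01,
                              incomplete_rate = 0.001,
                              error_rate = 0,
                              annotation = annotation_params()) {
  probs <- c(background_productive_fraction, blast_fraction, error_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (read_length < 30) abort("read_length must be >= 30")
  if (any(c(productive_rate, sterile_rate, incomplete_rate) < 0)) {
    abort("transcription rates must be non-negative")
  }
  if (is.null(background_class_weights)) {
    reg <- junction_classes()
    background_class_weights <- setNames(
      ifelse(reg$category == "complete_VJ", 3, 1), reg$label)
  }
  structure(list(
    n_cases = as.integer(n_cases), clonal_plan = clonal_plan,
    background_size = as.integer(background_size),
    background_productive_fraction = background_productive_fraction,
    background_class_weights = background_class_weights,
    deletion_max = as.integer(deletion_max), ndn_mean = ndn_mean,
    blast_fraction = blast_fraction,
    dnaamp_depth_per_tube = as.integer(dnaamp_depth_per_tube),
    rnaseq_fragments = as.integer(rnaseq_fragments),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    fragment_length_min = as.integer(fragment_length_min),
    read_length = as.integer(read_length),
    context_length = as.integer(context_length),
    productive_rate = productive_rate, sterile_rate = sterile_rate,
    incomplete_rate = incomplete_rate, error_rate = error_rate,
    annotation = annotation), class = "simulation_params")
}

# minimum retained segment length after junctional trimming, per type
min_keep_for_type <- function(type) {
  c(V = 30L, D = 10L, J = 14L, KDE = 14L, INTRON_RSS = 12L)[[type]]
}

# raw draw of one rearrangement (no truth annotation yet)
draw_rearrangement_raw <- function(ref, label, params) {
  pool5 <- class_gene_pool(ref, label, "five")
  pool3 <- class_gene_pool(ref, label, "three")
  if (length(pool5) == 0 || length(pool3) == 0) {
    abort(paste0("reference lacks segments for class ", label))
  }
  five <- pool5[sample.int(length(pool5), 1)]
  three <- pool3[sample.int(length(pool3), 1)]
  s5 <- ref$sequence[ref$name == five]
  s3 <- ref$sequence[ref$name == three]
  t5 <- ref$segment_type[ref$name == five]
  t3 <- ref$segment_type[ref$name == three]
  five_del <- min(sample.int(params$deletion_max + 1L, 1) - 1L,
                  max(0L, nchar(s5) - min_keep_for_type(t5)))
  three_del <- min(sample.int(params$deletion_max + 1L, 1) - 1L,
                   max(0L, nchar(s3) - min_keep_for_type(t3)))
  ndn <- stats::rgeom(1, prob = 1 / (1 + params$ndn_mean))
  sequence <- paste0(substr(s5, 1, nchar(s5) - five_del),
                     random_dna(ndn),
                     substr(s3, three_del + 1, nchar(s3)))
  list(five = five, three = three, sequence = sequence)
}

#' Simulate one rearrangement with canonical truth annotation
#'
#' Draws 5'/3' genes uniformly among the class's eligible segments,
#' junctional deletions uniform on 0..`deletion_max` (clamped to keep the
#' segment alignable), a geometric N-(D)-N insertion filled uniformly over
#' ACGT, assembles the full rearranged sequence, and annotates that sequence
#' with the package's own annotator to obtain the canonical truth record
#' (class, segmentation statistics, junction, productivity, identity key).
#' Draws whose assembled sequence does not annotate back to the intended
#' class (pathological junction coincidences) are redrawn.
#'
#' @param ref A `germline_reference` tibble.
#' @param class_label One of the 22 junction-class labels.
#' @param params [simulation_params()].
#' @param seed Optional integer seed; if `NULL`, uses the current RNG state.
#' @param index Optional prebuilt alignment index for `ref`.
#' @return One-row truth tibble including the full `sequence`, the junction
#'   window coordinates (`win_start`, `win_end`, 0-based half-open) and the
#'   identity `key`.
#' @export
simulate_rearrangement <- function(ref, class_label, params = simulation_params(),
                                   seed = NULL, index = NULL) {
  if (!class_label %in% JUNCTION_CLASS_REGISTRY$label) {
    abort(paste0("unknown junction class: ", class_label))
  }
  idx <- index %||% build_alignment_index(ref, params$annotation)
  run <- function() {
    for (try in 1:50) {
      raw <- draw_rearrangement_raw(ref, class_label, params)
      ann <- annotate_fragment(raw$sequence, NA_character_, idx,
                               params$annotation)
      if (ann$status == "assigned" && !ann$damaged &&
          ann$junction_class == class_label &&
          ann$five_gene == raw$five && ann$three_gene == raw$three) {
        out <- annotation_list_to_tibble(list(ann))
        out <- dplyr::select(out, -"status", -"reason", -"strand")
        out$sequence <- raw$sequence
        out$key <- identity_key(out)
        return(out)
      }
    }
    abort(paste0("could not simulate a self-consistent ", class_label,
                 " rearrangement in 50 draws"))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# resample a rearrangement until a productivity predicate holds
draw_with_productivity <- function(ref, label, params, idx, want = NULL,
                                   max_tries = 200) {
  for (i in seq_len(max_tries)) {
    r <- simulate_rearrangement(ref, label, params, index = idx)
    if (is.null(want) || r$productivity == want) return(r)
  }
  abort(paste0("could not draw a ", want %||% "any", " ", label,
               " rearrangement in ", max_tries, " tries"))
}

#' Simulate one patient-like case
#'
#' Emits the clonal rearrangements of `params$clonal_plan` (productivity
#' resampled to the plan's `unproductive_prob` where given; identity keys
#' distinct within the case) plus `background_size` polyclonal background
#' rearrangements whose class follows `background_class_weights` and whose
#' complete-VJ draws are productive with probability
#' `background_productive_fraction`. Cellular abundance: each clonal
#' rearrangement carries `blast_fraction`; each background rearrangement
#' carries `(1 - blast_fraction) / background_size`.
#'
#' @param ref A `germline_reference` tibble.
#' @param params [simulation_params()].
#' @param case_id Case identifier string.
#' @param seed Integer seed (the case derives its own child seed).
#' @param index Optional prebuilt alignment index.
#' @return Truth tibble, one row per ground-truth rearrangement.
#' @export
simulate_case <- function(ref, params = simulation_params(), case_id = "case_01",
                          seed = 1, index = NULL) {
  idx <- index %||% build_alignment_index(ref, params$annotation)
  with_seed(derive_seed(seed, "case", case_id), {
    rows <- list()
    keys <- character(0)
    plan <- params$clonal_plan
    for (p in seq_len(nrow(plan))) {
      for (i in seq_len(plan$n[p])) {
        want <- NULL
        up <- plan$unproductive_prob[p]
        if (!is.na(up)) {
          want <- if (stats::runif(1) < up) "unproductive" else "productive"
        }
        repeat {
          r <- draw_with_productivity(ref, plan$junction_class[p], params,
                                      idx, want)
          if (!r$key %in% keys) break
        }
        keys <- c(keys, r$key)
        r$is_clonal <- TRUE
        rows[[length(rows) + 1]] <- r
      }
    }
    w <- params$background_class_weights
    bg_classes <- sample(names(w), params$background_size, replace = TRUE,
                         prob = w)
    for (label in bg_classes) {
      want <- NULL
      if (class_category(label) == "complete_VJ") {
        want <- if (stats::runif(1) < params$background_productive_fraction)
          "productive" else "unproductive"
      }
      r <- draw_with_productivity(ref, label, params, idx, want)
      r$is_clonal <- FALSE
      rows[[length(rows) + 1]] <- r
    }
    truth <- dplyr::bind_rows(rows)
    truth$case_id <- case_id
    truth$truth_id <- paste0(case_id, "_t",
                             formatC(seq_len(nrow(truth)), width = 3,
                                     flag = "0"))
    truth$abundance <- ifelse(truth$is_clonal, params$blast_fraction,
                              (1 - params$blast_fraction) /
                                params$background_size)
    truth$rnaseq_rate <- expression_level(truth, params)
    dplyr::relocate(truth, "case_id", "truth_id", "is_clonal")
  })
}

#' Simulate a cohort of cases
#'
#' @inheritParams simulate_case
#' @return Truth tibble over `params$n_cases` cases (`case_01`, ...).
#' @export
simulate_cohort <- function(ref, params = simulation_params(), seed = 1) {
  idx <- build_alignment_index(ref, params$annotation)
  ids <- sprintf("case_%02d", seq_len(params$n_cases))
  dplyr::bind_rows(lapply(ids, function(cid) {
    simulate_case(ref, params, cid, seed, index = idx)
  }))
}

#' Relative transcription rate of rearrangements
#'
#' Three-tier transcription model: productive complete rearrangements
#' transcribe at `productive_rate`; unproductive complete rearrangements at
#' the sterile rate; incomplete, other and non-coding rearrangements at the
#' incomplete rate. Non-transcribed rearrangements (rate 0) are absent from
#' RNAseq.
#'
#' @param truth Truth tibble with columns `category` and `productivity`.
#' @param params [simulation_params()].
#' @return Numeric vector of non-negative relative rates.
#' @export
expression_level <- function(truth, params = simulation_params()) {
  ifelse(truth$category == "complete_VJ" &
           truth$productivity == "productive", params$productive_rate,
         ifelse(truth$category == "complete_VJ", params$sterile_rate,
                params$incomplete_rate))
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit) > 0) {
      for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate per-tube DNA-amplicon reads
#'
#' For each case and primer tube, samples `dnaamp_depth_per_tube` reads
#' multinomially over the tube's amplifiable rearrangements: clonal
#' rearrangements jointly receive `blast_fraction` of the tube's expected
#' reads (split equally), background the remainder (split equally). Every
#' read is the full rearranged sequence, so amplicon junctions are always
#' fully covered (never damaged). Tubes with no eligible rearrangement yield
#' no reads, with a warning.
#'
#' @param truth Truth tibble from [simulate_case()]/[simulate_cohort()].
#' @param params [simulation_params()].
#' @param seed Integer seed.
#' @param tubes Tube definitions, default [tube_definitions()].
#' @return Read tibble: `read_id`, `sequence`, `case_id`, `platform`,
#'   `tube`, `truth_id` (one row per read).
#' @export
simulate_dnaamp_reads <- function(truth, params = simulation_params(),
                                  seed = 1, tubes = tube_definitions()) {
  out <- list()
  for (cid in unique(truth$case_id)) {
    ct <- truth[truth$case_id == cid, ]
    for (tb in unique(tubes$tube)) {
      classes <- tubes$junction_class[tubes$tube == tb]
      el <- ct[ct$junction_class %in% classes, ]
      if (nrow(el) == 0) {
        warn(paste0("tube ", tb, " has no eligible rearrangement in ", cid))
        next
      }
      if (params$dnaamp_depth_per_tube == 0) next
      with_seed(derive_seed(seed, "dnaamp", cid, tb), {
        f <- params$blast_fraction
        n_cl <- sum(el$is_clonal)
        n_bg <- sum(!el$is_clonal)
        w <- numeric(nrow(el))
        if (n_cl > 0 && n_bg > 0) {
          w[el$is_clonal] <- f / n_cl
          w[!el$is_clonal] <- (1 - f) / n_bg
        } else if (n_cl > 0) {
          w[el$is_clonal] <- 1 / n_cl
        } else {
          w[!el$is_clonal] <- 1 / n_bg
        }
        counts <- as.vector(rmultinom(1, params$dnaamp_depth_per_tube, w))
        i_rep <- rep(seq_len(nrow(el)), counts)
        if (length(i_rep) > 0) {
          seqs <- apply_substitutions(el$sequence[i_rep], params$error_rate)
          out[[length(out) + 1]] <- tibble::tibble(
            read_id = paste0(cid, "|", tb, "|", el$truth_id[i_rep], "|",
                             seq_along(i_rep)),
            sequence = seqs, case_id = cid, platform = "DNAamp", tube = tb,
            truth_id = el$truth_id[i_rep])
        }
      })
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(read_id = character(0), sequence = character(0),
                          case_id = character(0), platform = character(0),
                          tube = character(0), truth_id = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Simulate paired-end transcriptome reads
#'
#' Samples `rnaseq_fragments` fragments per case over rearrangements
#' proportional to cellular abundance times the transcription rate
#' ([expression_level()], recomputed from `params` so rate settings can be
#' varied over one truth set). Each rearrangement is embedded in a
#' junction-centered transcript context of `context_length` nt (random
#' flanks stand in for upstream leader and downstream constant-region
#' sequence); fragment lengths are normal (`fragment_length_mean`/`_sd`),
#' truncated at `fragment_length_min`, and placed uniformly; a pair of
#' `read_length` reads is taken from the fragment ends. The truth `damaged`
#' flag records whether the junction window is fully contained in the read
#' coverage of the fragment.
#'
#' @inheritParams simulate_dnaamp_reads
#' @return Read-pair tibble: `read_id`, `sequence` (mate 1), `sequence2`
#'   (mate 2, reverse-complemented), `fragment_id`, `frag_start`,
#'   `frag_len`, `damaged_truth`, `case_id`, `platform`, `tube`, `truth_id`.
#' @export
simulate_rnaseq_reads <- function(truth, params = simulation_params(),
                                  seed = 1) {
  out <- list()
  rl <- params$read_length
  for (cid in unique(truth$case_id)) {
    ct <- truth[truth$case_id == cid, ]
    w <- ct$abundance * expression_level(ct, params)
    if (sum(w) <= 0) {
      warn(paste0("all transcription rates are zero in ", cid,
                  "; no RNAseq fragments emitted"))
      next
    }
    if (params$rnaseq_fragments == 0) next
    with_seed(derive_seed(seed, "rnaseq", cid), {
      counts <- as.vector(rmultinom(1, params$rnaseq_fragments, w / sum(w)))
      for (r in which(counts > 0)) {
        n <- counts[r]
        len <- nchar(ct$sequence[r])
        win_center <- (ct$win_start[r] + ct$win_end[r]) %/% 2L
        pad5 <- max(0L, params$context_length %/% 2L - win_center)
        pad3 <- max(0L, params$context_length - pad5 - len)
        context <- paste0(random_dna(pad5), ct$sequence[r], random_dna(pad3))
        lc <- nchar(context)
        ws <- ct$win_start[r] + pad5
        we <- ct$win_end[r] + pad5
        fl <- as.integer(round(rnorm(n, params$fragment_length_mean,
                                     params$fragment_length_sd)))
        fl <- pmin(pmax(fl, params$fragment_length_min), lc)
        s <- vapply(fl, function(f) sample.int(lc - f + 1L, 1) - 1L, 1L)
        r1 <- substr(rep(context, n), s + 1L, s + pmin(rl, fl))
        r2 <- revcomp(substr(rep(context, n), s + fl - pmin(rl, fl) + 1L,
                             s + fl))
        cov1_end <- s + pmin(rl, fl)
        cov2_start <- s + fl - pmin(rl, fl)
        # junction reconstructable: window inside one mate, or the mates
        # overlap enough to merge and the window lies inside the fragment
        mergeable <- cov1_end - cov2_start >=
          params$annotation$merge_min_overlap
        undamaged <- (ws >= s & we <= cov1_end) |
          (ws >= cov2_start & we <= s + fl) |
          (mergeable & ws >= s & we <= s + fl)
        if (params$error_rate > 0) {
          r1 <- apply_substitutions(r1, params$error_rate)
          r2 <- apply_substitutions(r2, params$error_rate)
        }
        out[[length(out) + 1]] <- tibble::tibble(
          read_id = paste0(cid, "|RNAseq|", ct$truth_id[r], "|", seq_len(n)),
          sequence = r1, sequence2 = r2,
          fragment_id = paste0(ct$truth_id[r], ":", s, ":", fl),
          frag_start = s, frag_len = fl, damaged_truth = !undamaged,
          case_id = cid, platform = "RNAseq", tube = NA_character_,
          truth_id = ct$truth_id[r])
      }
    })
  }
  if (length(out) == 0) {
    return(tibble::tibble(read_id = character(0), sequence = character(0),
                          sequence2 = character(0), fragment_id = character(0),
                          frag_start = integer(0), frag_len = integer(0),
                          damaged_truth = logical(0), case_id = character(0),
                          platform = character(0), tube = character(0),
                          truth_id = character(0)))
  }
  dplyr::bind_rows(out)
}
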