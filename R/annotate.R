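# Read annotation: orient reads, find 5'/3' segment alignments, compute
# junctional segmentation statistics, classify, translate, flag damage.
#
# Internals work on plain lists/data.frames for speed; annotate_reads()
# assembles the user-facing tibble.

ANNOTATION_FIELDS <- list(
  status = NA_character_, reason = NA_character_,
  junction_class = NA_character_, category = NA_character_,
  locus_group = NA_character_, five_gene = NA_character_,
  three_gene = NA_character_, five_del = NA_integer_,
  ndn_length = NA_integer_, three_del = NA_integer_,
  junction = NA_character_, junction_aa = NA_character_,
  in_frame = NA, productivity = NA_character_, damaged = NA,
  strand = NA_character_, win_start = NA_integer_, win_end = NA_integer_)

unassigned_result <- function(reason, strand = "+") {
  out <- ANNOTATION_FIELDS
  out$status <- "unassigned"
  out$reason <- reason
  out$strand <- strand
  out
}

annotation_list_to_tibble <- function(results) {
  grab <- function(field, proto) {
    vapply(results, function(r) r[[field]] %||% proto, proto)
  }
  tibble::tibble(
    status = grab("status", NA_character_),
    reason = grab("reason", NA_character_),
    junction_class = grab("junction_class", NA_character_),
    category = grab("category", NA_character_),
    locus_group = grab("locus_group", NA_character_),
    five_gene = grab("five_gene", NA_character_),
    three_gene = grab("three_gene", NA_character_),
    five_del = grab("five_del", NA_integer_),
    ndn_length = grab("ndn_length", NA_integer_),
    three_del = grab("three_del", NA_integer_),
    junction = grab("junction", NA_character_),
    junction_aa = grab("junction_aa", NA_character_),
    in_frame = grab("in_frame", NA),
    productivity = grab("productivity", NA_character_),
    damaged = grab("damaged", NA),
    strand = grab("strand", NA_character_),
    win_start = grab("win_start", NA_integer_),
    win_end = grab("win_end", NA_integer_))
}

# Segmentation statistics, junction window and coverage for a candidate
# (5' alignment a, 3' alignment b) pair. Alignments are lists with fields
# seg, mate, rs, re (read interval), ss, se (segment interval), score;
# coordinates 0-based half-open. Returns NULL for invalid geometry.
pair_stats <- function(a, b, label, idx, params, mate_len) {
  flank <- 3L * params$junction_flank_codons
  same_mate <- a$mate == b$mate
  if (a$mate > b$mate) return(NULL)
  if (same_mate) {
    if (b$rs < a$rs || b$re <= a$re) return(NULL)
    o <- a$re - b$rs
    if (o > 15L) return(NULL)
    if (o > 0L) {
      # junctional micro-homology: clamp N-(D)-N to 0, shift 3' deletions
      if (b$rs + o >= b$re) return(NULL)
      b$rs <- b$rs + o
      b$ss <- b$ss + o
    }
    ndn <- b$rs - a$re
  } else {
    ndn <- NA_integer_
  }
  len_a <- idx$len[a$seg]
  five_del <- if (a$se == len_a || a$re < mate_len[a$mate]) {
    len_a - a$se
  } else NA_integer_
  three_del <- if (b$ss == 0L || b$rs > 0L) b$ss else NA_integer_
  regions <- c(five_del, ndn, three_del)
  if (any(!is.na(regions) & regions > params$max_region)) return(NULL)

  category <- class_category(label)
  in_frame <- NA
  anchor_read_j <- NA_integer_
  if (category == "complete_VJ") {
    anchor_read_v <- a$rs - a$ss + idx$anchor[a$seg]
    raw_ws <- a$re - flank
    ws <- raw_ws - ((raw_ws - anchor_read_v) %% 3L)
    raw_we <- b$rs + flank
    we <- raw_we + ((anchor_read_v - raw_we) %% 3L)
    anchor_read_j <- b$rs - b$ss + idx$anchor[b$seg]
    if (same_mate) in_frame <- ((anchor_read_j - anchor_read_v) %% 3L) == 0L
  } else {
    ws <- a$re - flank
    we <- b$rs + flank
    if (category == "incomplete_DJ") {
      anchor_read_j <- b$rs - b$ss + idx$anchor[b$seg]
    }
  }
  covered <- same_mate && ws >= 0L && we <= mate_len[a$mate]
  list(a = a, b = b, label = label, category = category,
       same_mate = same_mate, five_del = five_del, ndn = ndn,
       three_del = three_del, ws = ws, we = we, covered = covered,
       in_frame = in_frame, anchor_read_j = anchor_read_j,
       score = a$score + b$score)
}

finalize_record <- function(ps, mates, idx, strand) {
  junction_nt <- NA_character_
  junction_aa <- ""
  damaged <- !ps$covered
  if (ps$covered) {
    junction_nt <- substr(mates[ps$a$mate], ps$ws + 1L, ps$we)
    if (ps$category == "complete_VJ") {
      junction_aa <- translate_junction(junction_nt, 0)
    } else if (ps$category == "incomplete_DJ") {
      p <- ps$ws + ((ps$anchor_read_j - ps$ws) %% 3L)
      junction_aa <- translate_junction(
        substr(mates[ps$a$mate], p + 1L, ps$we), 0)
    }
  }
  in_frame <- if (damaged) NA else ps$in_frame
  productivity <- determine_productivity(ps$category, in_frame, junction_aa,
                                         damaged)
  list(status = "assigned", reason = NA_character_,
       junction_class = ps$label, category = ps$category,
       locus_group = class_locus_group(ps$label),
       five_gene = idx$name[ps$a$seg], three_gene = idx$name[ps$b$seg],
       five_del = as.integer(ps$five_del),
       ndn_length = as.integer(ps$ndn),
       three_del = as.integer(ps$three_del),
       junction = junction_nt, junction_aa = junction_aa,
       in_frame = in_frame, productivity = productivity, damaged = damaged,
       strand = strand,
       win_start = if (ps$covered) as.integer(ps$ws) else NA_integer_,
       win_end = if (ps$covered) as.integer(ps$we) else NA_integer_)
}

# Terminal-stub rescue. When the best pair spans both mates the junction may
# still be fully covered by the mate holding the 3' segment (a short 5'-gene
# terminus at that mate's start) or the mate holding the 5' segment (a short
# 3'-gene start at that mate's end). These stubs are too short for the
# global minima but are corroborated by the full-length alignment of the
# same gene on the other mate; they anchor at the mate boundary.

# best prefix alignment of segment `seg` starting at mate position 0,
# trying junction-proximal segment start positions
stub_prefix_alignment <- function(seg, mate_chars, idx, params) {
  sc <- idx$chars[[seg]]
  len <- idx$len[seg]
  lm <- length(mate_chars)
  best <- NULL
  for (p in seq(max(0L, len - params$max_region - 10L), len - 6L)) {
    n <- min(len - p, lm)
    if (n < 6L) next
    m <- sc[(p + 1L):(p + n)] == mate_chars[1:n]
    run <- if (all(m)) n else which(!m)[1] - 1L   # exact run only
    if (run < 9L) next
    if (is.null(best) || run > best$score ||
        (run == best$score && p > best$ss)) {
      best <- list(seg = seg, score = run, rs = 0L, re = run,
                   ss = p, se = p + run)
    }
  }
  best
}

# best suffix alignment of segment `seg` ending at the mate's end, trying
# junction-proximal segment end positions
stub_suffix_alignment <- function(seg, mate_chars, idx, params) {
  sc <- idx$chars[[seg]]
  len <- idx$len[seg]
  lm <- length(mate_chars)
  best <- NULL
  for (rp in seq(6L, min(len, params$max_region + 10L))) {
    n <- min(rp, lm)
    if (n < 6L) next
    mr <- rev(mate_chars[(lm - n + 1L):lm] == sc[(rp - n + 1L):rp])
    run <- if (all(mr)) n else which(!mr)[1] - 1L   # exact run only
    if (run < 9L) next
    if (is.null(best) || run > best$score ||
        (run == best$score && rp < best$se)) {
      best <- list(seg = seg, score = run, rs = lm - run, re = lm,
                   ss = rp - run, se = rp)
    }
  }
  best
}

# annotate one fragment given mates already in fragment-forward orientation
annotate_oriented <- function(mates, idx, params, strand) {
  seg <- integer(0); score <- integer(0); rs <- integer(0); re <- integer(0)
  ss <- integer(0); se <- integer(0); mate <- integer(0)
  for (m in seq_along(mates)) {
    a <- align_all_segments(mates[m], idx, params)
    if (!is.null(a)) {
      seg <- c(seg, a$seg); score <- c(score, a$score)
      rs <- c(rs, a$rs); re <- c(re, a$re)
      ss <- c(ss, a$ss); se <- c(se, a$se)
      mate <- c(mate, rep(m, length(a$seg)))
    }
  }
  if (length(seg) == 0) return(unassigned_result("no_5prime", strand))
  mate_len <- nchar(mates)
  five_cap <- idx$five_cap[seg]
  three_cap <- idx$three_cap[seg]
  if (!any(five_cap)) return(unassigned_result("no_5prime", strand))
  if (!any(three_cap)) return(unassigned_result("no_3prime", strand))

  as_al <- function(i) list(seg = seg[i], mate = mate[i], rs = rs[i],
                            re = re[i], ss = ss[i], se = se[i],
                            score = score[i])
  candidates <- list()
  saw_wrong_order <- FALSE
  n <- length(seg)
  for (i in seq_len(n)) {
    if (!five_cap[i]) next
    for (j in seq_len(n)) {
      if (i == j || !three_cap[j]) next
      lab <- idx$class_mat[seg[i], seg[j]]
      if (is.na(lab)) next
      ps <- pair_stats(as_al(i), as_al(j), lab, idx, params, mate_len)
      if (is.null(ps)) {
        saw_wrong_order <- TRUE
        next
      }
      candidates[[length(candidates) + 1]] <- ps
    }
  }
  if (length(candidates) == 0) {
    if (saw_wrong_order) return(unassigned_result("wrong_order", strand))
    return(unassigned_result("cross_class", strand))
  }
  # gene assignment follows raw alignment score; among pairs calling the
  # same class and genes, a junction-resolving (covered) variant is
  # preferred over a higher-scoring uncovered one
  scores <- vapply(candidates, function(ps) ps$score, 0L)
  best <- candidates[[which.max(scores)]]
  if (!best$covered) {
    same <- Filter(function(ps) {
      ps$covered && ps$label == best$label &&
        ps$a$seg == best$a$seg && ps$b$seg == best$b$seg
    }, candidates)
    if (length(same) > 0) {
      same_scores <- vapply(same, function(ps) ps$score, 0L)
      best <- same[[which.max(same_scores)]]
    }
  }

  if (!best$covered && length(mates) == 2) {
    rescue <- NULL
    # junction on the 3' mate: 5'-gene terminus as prefix of that mate
    if (best$b$mate == 2L) {
      stub <- stub_prefix_alignment(best$a$seg,
                                    seq_chars(mates[2]), idx, params)
      if (!is.null(stub)) {
        stub$mate <- 2L
        ps <- pair_stats(stub, best$b, best$label, idx, params, mate_len)
        if (!is.null(ps) && ps$covered) rescue <- ps
      }
    }
    # junction on the 5' mate: 3'-gene start as suffix of that mate
    if (is.null(rescue) && best$a$mate == 1L) {
      stub <- stub_suffix_alignment(best$b$seg,
                                    seq_chars(mates[1]), idx, params)
      if (!is.null(stub)) {
        stub$mate <- 1L
        ps <- pair_stats(best$a, stub, best$label, idx, params, mate_len)
        if (!is.null(ps) && ps$covered) rescue <- ps
      }
    }
    if (!is.null(rescue)) best <- rescue
  }

  finalize_record(best, mates, idx, strand)
}

# orient a read or pair into fragment-forward mates, then annotate; the
# reverse orientation is tried when the forward one yields nothing
annotate_fragment <- function(read1, read2, idx, params) {
  if (is.na(read2)) {
    res <- annotate_oriented(read1, idx, params, "+")
    if (res$status == "assigned") return(res)
    res2 <- annotate_oriented(revcomp(read1), idx, params, "-")
    if (res2$status == "assigned") res2 else res
  } else {
    mg <- merge_pair(read1, read2, params$merge_min_overlap)
    if (mg$merged) {
      return(annotate_fragment(mg$sequence, NA_character_, idx, params))
    }
    res <- annotate_oriented(c(read1, revcomp(read2)), idx, params, "+")
    if (res$status == "assigned") return(res)
    res2 <- annotate_oriented(c(read2, revcomp(read1)), idx, params, "-")
    if (res2$status == "assigned") res2 else res
  }
}

#' Annotate a single read or read pair
#'
#' Orients the read(s), finds the best 5'-role and 3'-role germline segment
#' alignments, computes segmentation statistics (5' gene deletions, N-(D)-N
#' length, 3' gene deletions, with junctional micro-homology clamped to an
#' N-(D)-N length of 0), classifies the pair into one of the 22 junction
#' classes, extracts and translates the junction window, and flags the record
#' damaged when read coverage does not span the full junction window (then
#' the junction amino-acid sequence is empty and productivity unknown).
#' Candidate pairs that fully resolve the junction are preferred; for
#' unmerged pairs whose junction lies on one mate, a boundary-anchored
#' terminal stub of the partner gene (corroborated by its full alignment on
#' the other mate) recovers the junction.
#'
#' @param read1 Read sequence.
#' @param read2 Optional mate sequence (fragment 3' read); `NA` for single
#'   or merged reads.
#' @param ref A `germline_reference` or prebuilt alignment index.
#' @param params [annotation_params()].
#' @return One-row tibble; `status` is `assigned` or `unassigned` with a
#'   `reason` code (`no_5prime`, `no_3prime`, `wrong_order`, `cross_class`).
#' @export
annotate_read <- function(read1, read2 = NA_character_, ref,
                          params = annotation_params()) {
  idx <- as_alignment_index(ref, params)
  out <- annotation_list_to_tibble(
    list(annotate_fragment(read1, read2, idx, params)))
  out$key <- ifelse(out$status == "assigned", identity_key(out),
                    NA_character_)
  out
}

#' Annotate a table of reads
#'
#' Vectorized driver over a read table. Identical sequences (or sequence
#' pairs) are annotated once and the result replicated, so amplicon data
#' with deep identical coverage annotate quickly. All input columns are
#' passed through; annotation columns and the identity `key` are appended.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, and optionally
#'   `sequence2` for read pairs; other columns (e.g. `case_id`, `platform`,
#'   `tube`, `fragment_id`) pass through.
#' @param ref A `germline_reference` or prebuilt alignment index.
#' @param params [annotation_params()].
#' @return Tibble with one row per input read/pair.
#' @export
annotate_reads <- function(reads, ref, params = annotation_params()) {
  idx <- as_alignment_index(ref, params)
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0) {
    out <- dplyr::bind_cols(reads, annotation_list_to_tibble(list()))
    out$key <- character(0)
    return(out)
  }
  has_pair <- "sequence2" %in% names(reads)
  sig <- if (has_pair) paste(reads$sequence, reads$sequence2, sep = "::")
  else reads$sequence
  u <- which(!duplicated(sig))
  res_u <- vector("list", length(u))
  for (k in seq_along(u)) {
    i <- u[k]
    r2 <- if (has_pair) reads$sequence2[i] else NA_character_
    res_u[[k]] <- annotate_fragment(reads$sequence[i], r2, idx, params)
  }
  ann <- annotation_list_to_tibble(res_u)[match(sig, sig[u]), ]
  out <- dplyr::bind_cols(reads, ann)
  out$key <- NA_character_
  assigned <- out$status == "assigned"
  if (any(assigned)) {
    out$key[assigned] <- identity_key(out[assigned, ])
  }
  out
}

#' De-duplicate annotated reads into a rearrangement table
#'
#' Collapses assigned annotations to one row per identity key (damaged
#' partial keys are kept apart from complete keys). Abundance (`count`)
#' is platform-aware: DNAamp counts reads; RNAseq counts distinct fragment
#' identities (de-duplicated fragments), taken from `fragment_id` when
#' present, else from the sequence content of the pair. Output is sorted by
#' descending count, then key.
#'
#' @param records Annotated read table from [annotate_reads()] with a
#'   `platform` column (`DNAamp` or `RNAseq`).
#' @return Rearrangement table: one row per (case, platform, tube, key,
#'   damaged) with `count`.
#' @export
deduplicate <- function(records) {
  records <- tibble::as_tibble(records)
  keep_cols <- c("case_id", "platform", "tube", "junction_class", "category",
                 "locus_group", "five_gene", "three_gene", "five_del",
                 "ndn_length", "three_del", "junction", "junction_aa",
                 "productivity", "damaged", "key")
  if (nrow(records) == 0 || !any(records$status == "assigned")) {
    out <- records[0, intersect(keep_cols, names(records))]
    out$count <- integer(0)
    return(out)
  }
  df <- dplyr::filter(records, .data$status == "assigned")
  if (!"platform" %in% names(df)) abort("records must carry a platform tag")
  if (!"case_id" %in% names(df)) df$case_id <- "case"
  if (!"tube" %in% names(df)) df$tube <- NA_character_
  frag_id <- if ("fragment_id" %in% names(df)) {
    df$fragment_id
  } else if ("sequence2" %in% names(df)) {
    paste(df$sequence, df$sequence2, sep = "::")
  } else {
    df$sequence
  }
  df$.frag <- frag_id
  df |>
    dplyr::group_by(.data$case_id, .data$platform, .data$tube, .data$key,
                    .data$damaged) |>
    dplyr::summarise(
      junction_class = dplyr::first(.data$junction_class),
      category = dplyr::first(.data$category),
      locus_group = dplyr::first(.data$locus_group),
      five_gene = dplyr::first(.data$five_gene),
      three_gene = dplyr::first(.data$three_gene),
      five_del = dplyr::first(.data$five_del),
      ndn_length = dplyr::first(.data$ndn_length),
      three_del = dplyr::first(.data$three_del),
      junction = dplyr::first(.data$junction),
      junction_aa = dplyr::first(.data$junction_aa),
      productivity = dplyr::first(.data$productivity),
      count = dplyr::if_else(dplyr::first(.data$platform) == "RNAseq",
                             dplyr::n_distinct(.data$.frag),
                             dplyr::n()),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$key)
}
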