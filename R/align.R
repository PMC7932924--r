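# Segment alignment: k-mer seeded, per-diagonal ungapped local alignment.
# Scoring is +1 match / -2 mismatch; the default read model is
# substitution-only, where gapped alignment never improves the optimum.

#' Annotation parameters
#'
#' Tuning knobs for read annotation. `seed_kmer` seeds V/J/Kde/intronRSS
#' candidates; the shorter `seed_kmer_d` seeds D segments (12-25 nt, too
#' short to carry a 12-mer after junctional trimming). Minimum aligned
#' lengths are per segment type; `min_identity` applies to all accepted
#' alignments. `junction_flank_codons` sets the junction window at 3 codons
#' on either side of the joined segment boundaries.
#'
#' @param seed_kmer Seed k-mer length for V/J-type segments (default 12).
#' @param seed_kmer_d Seed k-mer length for D segments (default 7).
#' @param min_identity Minimum alignment identity in \[0,1\] (default 0.9).
#' @param min_v_match Minimum aligned nt for V segments (default 20).
#' @param min_j_match Minimum aligned nt for J/Kde/intronRSS (default 12).
#' @param min_d_match Minimum aligned nt for D segments (default 8).
#' @param junction_flank_codons Codons flanking the junction window
#'   (default 3).
#' @param merge_min_overlap Minimum mate overlap for pair merging
#'   (default 15).
#' @param max_region Sanity maximum for five_del/ndn_length/three_del
#'   (default 60).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(seed_kmer = 12, seed_kmer_d = 7,
                              min_identity = 0.9, min_v_match = 20,
                              min_j_match = 12, min_d_match = 8,
                              junction_flank_codons = 3,
                              merge_min_overlap = 15, max_region = 60) {
  if (seed_kmer > min_j_match) abort("seed_kmer must be <= min_j_match")
  if (seed_kmer_d > min_d_match) abort("seed_kmer_d must be <= min_d_match")
  if (min_identity < 0 || min_identity > 1) {
    abort("min_identity must lie in [0, 1]")
  }
  structure(list(seed_kmer = as.integer(seed_kmer),
                 seed_kmer_d = as.integer(seed_kmer_d),
                 min_identity = min_identity,
                 min_v_match = as.integer(min_v_match),
                 min_j_match = as.integer(min_j_match),
                 min_d_match = as.integer(min_d_match),
                 junction_flank_codons = as.integer(junction_flank_codons),
                 merge_min_overlap = as.integer(merge_min_overlap),
                 max_region = as.integer(max_region)),
            class = "annotation_params")
}

kmer_strings <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

# one k-mer index: environment mapping kmer -> matrix(seg, pos0)
build_kmer_env <- function(sequences, seg_ids, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(sequences)) {
    km <- kmer_strings(sequences[j], k)
    for (p in seq_along(km)) {
      key <- km[p]
      entry <- env[[key]]
      row <- c(seg_ids[j], p - 1L)
      env[[key]] <- if (is.null(entry)) matrix(row, ncol = 2) else
        rbind(entry, row)
    }
  }
  env
}

#' Build an alignment index over a germline reference
#'
#' Precomputes per-segment character vectors, k-mer seed tables, and the
#' segment-pair junction-class lookup. Annotation functions accept either a
#' reference (index built on the fly) or a prebuilt index when annotating
#' many read sets.
#'
#' @param ref A `germline_reference` tibble.
#' @param params [annotation_params()].
#' @return An opaque index object.
#' @export
build_alignment_index <- function(ref, params = annotation_params()) {
  validate_germline_reference(ref)
  is_d <- ref$segment_type == "D"
  n <- nrow(ref)
  # segment-pair -> class label lookup (NA where unclassifiable)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  class_mat <- matrix(
    match_class_label(ref$locus[ii], ref$segment_type[ii], ref$name[ii],
                      ref$locus[jj], ref$segment_type[jj], ref$name[jj]),
    nrow = n)
  min_match <- ifelse(ref$segment_type == "V", params$min_v_match,
                      ifelse(ref$segment_type == "D", params$min_d_match,
                             params$min_j_match))
  list(
    ref = ref,
    name = ref$name,
    locus = ref$locus,
    type = ref$segment_type,
    anchor = ref$frame_anchor,
    len = nchar(ref$sequence),
    chars = lapply(ref$sequence, seq_chars),
    min_match = as.integer(min_match),
    five_cap = apply(class_mat, 1, function(x) any(!is.na(x))),
    three_cap = apply(class_mat, 2, function(x) any(!is.na(x))),
    class_mat = class_mat,
    k_main = params$seed_kmer,
    k_d = params$seed_kmer_d,
    env_main = build_kmer_env(ref$sequence[!is_d], which(!is_d),
                              params$seed_kmer),
    env_d = build_kmer_env(ref$sequence[is_d], which(is_d),
                           params$seed_kmer_d)
  )
}

as_alignment_index <- function(x, params) {
  if (is.data.frame(x)) build_alignment_index(x, params) else x
}

# best ungapped local alignment of read vs one segment on one diagonal
# (0-based diag = read_pos - seg_pos); returns c(score, rs, re, matches) or
# NULL. Interval [rs, re) on the read.
diag_align <- function(read_chars, seg_chars, diag) {
  lr <- length(read_chars)
  ls <- length(seg_chars)
  lo <- max(0L, diag)
  hi <- min(lr, ls + diag)
  if (hi - lo < 1L) return(NULL)
  m <- read_chars[(lo + 1L):hi] == seg_chars[(lo - diag + 1L):(hi - diag)]
  sc <- 3L * m - 2L
  prefix <- c(0L, cumsum(sc))
  cm <- cummin(prefix[-length(prefix)])
  vals <- prefix[-1L] - cm
  best <- max(vals)
  if (best <= 0L) return(NULL)
  end_rel <- which.max(vals)
  start_rel <- which.min(prefix[1:end_rel]) - 1L
  c(best, lo + start_rel, lo + end_rel,
    sum(m[(start_rel + 1L):end_rel]))
}

# seed hits of a read against an index environment; returns list(seg, diag)
# vectors of unique (segment, diagonal) pairs, or NULL
seed_hits <- function(read, k, env) {
  km <- kmer_strings(read, k)
  if (length(km) == 0) return(NULL)
  found <- mget(unique(km), envir = env, ifnotfound = list(NULL))
  keep <- !vapply(found, is.null, TRUE)
  if (!any(keep)) return(NULL)
  found <- found[keep]
  pos_by_key <- split(seq_along(km) - 1L, km)[names(found)]
  segs <- vector("list", length(found))
  diags <- vector("list", length(found))
  for (i in seq_along(found)) {
    entry <- found[[i]]
    rp <- pos_by_key[[i]]
    m <- nrow(entry)
    segs[[i]] <- rep(entry[, 1], times = length(rp))
    diags[[i]] <- rep(rp, each = m) - rep(entry[, 2], times = length(rp))
  }
  seg <- unlist(segs, use.names = FALSE)
  diag <- unlist(diags, use.names = FALSE)
  code <- seg * 8192L + (diag + 2048L)
  keep <- !duplicated(code)
  list(seg = seg[keep], diag = diag[keep])
}

# All accepted segment alignments of a read (forward orientation assumed).
# Returns a list of parallel vectors (seg, score, rs, re, ss, se, matches)
# or NULL.
align_all_segments <- function(read, idx, params) {
  h1 <- seed_hits(read, idx$k_main, idx$env_main)
  h2 <- seed_hits(read, idx$k_d, idx$env_d)
  seg_all <- c(h1$seg, h2$seg)
  if (length(seg_all) == 0) return(NULL)
  diag_all <- c(h1$diag, h2$diag)
  read_chars <- seq_chars(read)
  out_seg <- integer(0)
  out <- matrix(0L, nrow = 0, ncol = 5)
  for (seg in unique(seg_all)) {
    best <- NULL
    for (diag in unique(diag_all[seg_all == seg])) {
      a <- diag_align(read_chars, idx$chars[[seg]], diag)
      if (is.null(a)) next
      if (is.null(best) || a[1] > best[1] ||
          (a[1] == best[1] && (a[3] - a[2]) > (best[3] - best[2]))) {
        best <- c(a, diag)
      }
    }
    if (is.null(best)) next
    len <- best[3] - best[2]
    if (len < idx$min_match[seg]) next
    if (best[4] / len < params$min_identity) next
    out_seg <- c(out_seg, seg)
    out <- rbind(out, c(best[1], best[2], best[3], best[2] - best[5],
                        best[3] - best[5]))
  }
  if (length(out_seg) == 0) return(NULL)
  list(seg = out_seg, score = out[, 1], rs = out[, 2], re = out[, 3],
       ss = out[, 4], se = out[, 5])
}

#' Align a read against candidate segments of one type
#'
#' Finds the best-scoring accepted alignment of `read` against the reference
#' segments of `segment_type`, trying both strands. Ties break to the longer
#' alignment, then the lexicographically smaller gene name. Absence of an
#' acceptable alignment returns an empty tibble, not an error.
#'
#' @param read Read sequence (character scalar).
#' @param ref A `germline_reference` tibble or prebuilt alignment index.
#' @param segment_type One of `V`, `D`, `J`, `KDE`, `INTRON_RSS`, or `NULL`
#'   for all types.
#' @param params [annotation_params()].
#' @return Tibble with at most one row: `gene`, `read_start`, `read_end`,
#'   `seg_start`, `seg_end`, `score`, `identity`, `strand` (0-based
#'   half-open intervals).
#' @export
align_segment <- function(read, ref, segment_type = NULL,
                          params = annotation_params()) {
  idx <- as_alignment_index(ref, params)
  empty <- tibble::tibble(gene = character(0), read_start = integer(0),
                          read_end = integer(0), seg_start = integer(0),
                          seg_end = integer(0), score = integer(0),
                          identity = numeric(0), strand = character(0))
  pick <- function(read_oriented, strand) {
    al <- align_all_segments(read_oriented, idx, params)
    if (is.null(al)) return(NULL)
    keep <- if (is.null(segment_type)) seq_along(al$seg) else
      which(idx$type[al$seg] %in% segment_type)
    if (length(keep) == 0) return(NULL)
    len <- al$re[keep] - al$rs[keep]
    ord <- order(-al$score[keep], -len, idx$name[al$seg[keep]])
    i <- keep[ord[1]]
    list(seg = al$seg[i], score = al$score[i], rs = al$rs[i], re = al$re[i],
         ss = al$ss[i], se = al$se[i], strand = strand)
  }
  fwd <- pick(read, "+")
  rev <- pick(revcomp(read), "-")
  best <- if (is.null(fwd) && is.null(rev)) NULL
  else if (is.null(rev)) fwd
  else if (is.null(fwd)) rev
  else if (rev$score > fwd$score) rev else fwd
  if (is.null(best)) return(empty)
  len <- best$re - best$rs
  ident <- NA_real_
  # identity recomputed from the stored coordinates
  rc <- seq_chars(if (best$strand == "+") read else revcomp(read))
  segc <- idx$chars[[best$seg]]
  ident <- mean(rc[(best$rs + 1):best$re] == segc[(best$ss + 1):best$se])
  tibble::tibble(gene = idx$name[best$seg], read_start = best$rs,
                 read_end = best$re, seg_start = best$ss,
                 seg_end = best$se, score = best$score,
                 identity = ident, strand = best$strand)
}

#' Merge an overlapping read pair
#'
#' Reverse-complements the second mate and searches for the longest suffix
#' overlap of at least `min_overlap` bases with at most 10% mismatches
#' (overlap candidates are proposed by an exact 12-mer seed at the mate's
#' start); if found, returns the merged consensus, else the pair unmerged.
#'
#' @param read1,read2 Mate sequences (fragment 5' read and 3' read).
#' @param min_overlap Minimum overlap length (default 15).
#' @return A list with `merged` (logical), `sequence` (merged consensus or
#'   `NA`).
#' @export
merge_pair <- function(read1, read2, min_overlap = 15) {
  r2f <- revcomp(read2)
  l1 <- nchar(read1)
  l2 <- nchar(r2f)
  no <- list(merged = FALSE, sequence = NA_character_)
  if (min(l1, l2) < max(min_overlap, 12L)) return(no)
  seed <- substr(r2f, 1, 12)
  hits <- gregexpr(seed, read1, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(no)
  c1 <- seq_chars(read1)
  c2 <- seq_chars(r2f)
  for (p in sort(hits)) {           # smallest start = longest overlap
    o <- l1 - p + 1L
    if (o < min_overlap) next
    n <- min(o, l2)
    mm <- sum(c1[p:(p + n - 1L)] != c2[1:n])
    if (mm <= max(1, floor(0.1 * n))) {
      merged <- if (l2 > n) paste0(read1, substring(r2f, n + 1L)) else
        substr(read1, 1, p + l2 - 1L)
      return(list(merged = TRUE, sequence = merged))
    }
  }
  no
}
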