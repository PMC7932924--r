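# Germline segment reference: load/validate/serve V, D, J, Kde and intronRSS
# elements for the seven IG/TR loci.

new_germline_reference <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("germline_reference", class(df))
  df
}

validate_germline_reference <- function(ref) {
  req <- c("name", "locus", "segment_type", "sequence", "frame_anchor")
  missing_cols <- setdiff(req, names(ref))
  if (length(missing_cols) > 0) {
    abort(paste0("germline reference lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(ref) == 0) abort("germline reference contains no segments")
  if (anyDuplicated(ref$name) > 0) {
    dup <- unique(ref$name[duplicated(ref$name)])
    abort(paste0("duplicate segment name(s) in reference: ",
                 paste(dup, collapse = ", ")))
  }
  bad_locus <- setdiff(unique(ref$locus), IGTR_LOCI)
  if (length(bad_locus) > 0) {
    abort(paste0("unknown locus label(s): ", paste(bad_locus, collapse = ", ")))
  }
  bad_type <- setdiff(unique(ref$segment_type), SEGMENT_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown segment type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (any(!nzchar(ref$sequence))) abort("empty sequence in reference")
  if (any(grepl("[^ACGT]", ref$sequence))) {
    bad <- ref$name[grepl("[^ACGT]", ref$sequence)]
    abort(paste0("non-ACGT characters in segment(s): ",
                 paste(bad, collapse = ", ")))
  }
  coding <- ref$segment_type %in% c("V", "J")
  if (any(coding & is.na(ref$frame_anchor))) {
    bad <- ref$name[coding & is.na(ref$frame_anchor)]
    abort(paste0("V/J segment(s) lack a frame anchor: ",
                 paste(bad, collapse = ", ")))
  }
  fa <- ref$frame_anchor[coding]
  if (any(fa < 0 | fa > 2)) abort("frame_anchor must lie in [0, 2]")
  invisible(ref)
}

#' Load a germline segment reference from FASTA
#'
#' Reads a FASTA file whose headers follow the convention
#' `name|locus|segment_type|frame_anchor` (the `frame_anchor` field is present
#' for V and J segments only, as a 0-based offset of the first base of the
#' reference reading frame). Sequences are upper-cased on load.
#'
#' @param fasta_path Path to the reference FASTA file.
#' @param strict If `TRUE` (default), non-ACGT characters are an error; if
#'   `FALSE`, offending records are dropped with a warning.
#' @return A `germline_reference` tibble with columns `name`, `locus`,
#'   `segment_type`, `sequence`, `frame_anchor` (NA for D/KDE/INTRON_RSS).
#' @export
load_germline_reference <- function(fasta_path, strict = TRUE) {
  if (!file.exists(fasta_path)) abort(paste0("file not found: ", fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3 | n_fields > 4)
  if (length(bad) > 0) {
    abort(paste0("malformed FASTA header (need name|locus|segment_type",
                 "[|frame_anchor]): '", headers[bad[1]], "'"))
  }
  df <- tibble::tibble(
    name = vapply(parts, `[`, "", 1),
    locus = vapply(parts, `[`, "", 2),
    segment_type = vapply(parts, `[`, "", 3),
    frame_anchor = vapply(parts, function(p) {
      if (length(p) >= 4) suppressWarnings(as.integer(p[4])) else NA_integer_
    }, 1L),
    sequence = unname(toupper(as.character(seqs)))
  )
  has_anchor_field <- n_fields >= 4
  if (any(has_anchor_field & is.na(df$frame_anchor))) {
    i <- which(has_anchor_field & is.na(df$frame_anchor))[1]
    abort(paste0("non-integer frame_anchor in header '", headers[i], "'"))
  }
  non_acgt <- grepl("[^ACGT]", df$sequence)
  if (any(non_acgt) && !strict) {
    warn(paste0("dropping ", sum(non_acgt),
                " record(s) with non-ACGT characters: ",
                paste(df$name[non_acgt], collapse = ", ")))
    df <- df[!non_acgt, ]
  }
  df <- df[, c("name", "locus", "segment_type", "sequence", "frame_anchor")]
  ref <- new_germline_reference(df)
  validate_germline_reference(ref)
  ref
}

#' Write a germline reference to FASTA
#'
#' Serializes a reference with the pipe-delimited header convention used by
#' [load_germline_reference()]; a reference round-trips field-by-field.
#'
#' @param ref A `germline_reference` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_reference <- function(ref, path) {
  validate_germline_reference(ref)
  hdr <- ifelse(is.na(ref$frame_anchor),
                paste(ref$name, ref$locus, ref$segment_type, sep = "|"),
                paste(ref$name, ref$locus, ref$segment_type, ref$frame_anchor,
                      sep = "|"))
  out <- as.vector(rbind(paste0(">", hdr), ref$sequence))
  writeLines(out, path)
  invisible(path)
}

#' Loci present in a reference
#'
#' @param ref A `germline_reference` tibble.
#' @return Character vector of locus labels, a subset of the 7 canonical loci.
#' @export
loci_present <- function(ref) sort(unique(ref$locus))

# stop-free random coding sequence: random codons excluding TAA/TAG/TGA in
# the frame starting at `anchor`, random bases outside that frame
random_codons_stopfree <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- random_dna(3)
      if (!cod %in% stops) break
    }
    codons[i] <- cod
  }
  paste(codons, collapse = "")
}

random_coding_segment <- function(len, anchor) {
  lead <- random_dna(anchor)
  n_codons <- (len - anchor) %/% 3
  tail_len <- len - anchor - 3 * n_codons
  paste0(lead, random_codons_stopfree(n_codons), random_dna(tail_len))
}

#' Build a deterministic synthetic germline reference
#'
#' Generates a toy reference covering all 7 IG/TR loci with
#' `segments_per_type` V/J segments per locus (sized like real segments:
#' V 250-300 nt, J 40-60 nt), D segments for IGH/TRB (12-25 nt), the two TRD
#' D elements `TRDD2`/`TRDD3`, and the IGK non-coding elements `Kde` and
#' `intronRSS`. V and J segments are generated stop-free in their reading
#' frames (real functional segments carry no stop in frame), with explicit
#' frame anchors. The same seed yields a byte-identical reference.
#'
#' @param seed Integer seed.
#' @param segments_per_type Number of V and J segments per locus (>= 1);
#'   also the number of D segments for IGH and TRB.
#' @return A validated `germline_reference` tibble.
#' @export
build_toy_reference <- function(seed = 1, segments_per_type = 3) {
  if (!is.numeric(segments_per_type) || segments_per_type < 1) {
    abort("segments_per_type must be >= 1")
  }
  segments_per_type <- as.integer(segments_per_type)
  with_seed(derive_seed(seed, "toy_reference"), {
    rows <- list()
    add <- function(name, locus, type, sequence, anchor = NA_integer_) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        name = name, locus = locus, segment_type = type,
        sequence = sequence, frame_anchor = as.integer(anchor))
    }
    for (locus in IGTR_LOCI) {
      for (i in seq_len(segments_per_type)) {
        anchor <- sample(0:2, 1)
        len <- sample(250:300, 1)
        add(paste0(locus, "V", i), locus, "V",
            random_coding_segment(len, anchor), anchor)
      }
      for (i in seq_len(segments_per_type)) {
        anchor <- sample(0:2, 1)
        len <- sample(40:60, 1)
        add(paste0(locus, "J", i), locus, "J",
            random_coding_segment(len, anchor), anchor)
      }
    }
    for (locus in c("IGH", "TRB")) {
      for (i in seq_len(segments_per_type)) {
        add(paste0(locus, "D", i), locus, "D", random_dna(sample(12:25, 1)))
      }
    }
    # TRD uses exactly the two D elements named in the junction-class taxonomy
    add("TRDD2", "TRD", "D", random_dna(sample(12:25, 1)))
    add("TRDD3", "TRD", "D", random_dna(sample(12:25, 1)))
    # IGK non-coding elements
    add("Kde", "IGK", "KDE", random_dna(60))
    add("intronRSS", "IGK", "INTRON_RSS", random_dna(50))
    ref <- new_germline_reference(dplyr::bind_rows(rows))
    validate_germline_reference(ref)
    ref
  })
}
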