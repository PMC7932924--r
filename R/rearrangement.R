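# Rearrangement-level primitives: translation, productivity, identity keys.

#' Translate a junction nucleotide sequence
#'
#' Translates `junction_nt` from `frame_offset` in codon steps with the
#' standard genetic code; stop codons render as `*`; a trailing partial codon
#' is dropped.
#'
#' @param junction_nt Nucleotide string over ACGT.
#' @param frame_offset Integer in \[0, 2\]: 0-based offset of the first codon.
#' @return Amino-acid string (possibly empty).
#' @export
translate_junction <- function(junction_nt, frame_offset = 0) {
  stopifnot(length(junction_nt) == 1, frame_offset %in% 0:2)
  if (grepl("[^ACGT]", junction_nt)) {
    abort("junction_nt contains non-ACGT characters")
  }
  n <- nchar(junction_nt)
  if (n - frame_offset < 3) return("")
  n_codons <- (n - frame_offset) %/% 3
  starts <- frame_offset + 3 * (seq_len(n_codons) - 1) + 1
  codons <- substring(junction_nt, starts, starts + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  paste(aa, collapse = "")
}

#' Determine the productivity status of rearrangements
#'
#' Applies the frame-and-stop rules per junction-class category:
#' * damaged records are `unknown` (junction residues missing);
#' * `other` and `incomplete_VD` categories are `unknown` (no reading frame
#'   spans the junction);
#' * `complete_VJ` is `productive` iff the V-to-J junction preserves the
#'   reading frame (`in_frame`) and the junction amino-acid sequence carries
#'   no stop, else `unproductive`;
#' * `incomplete_DJ` is `potentially_productive` iff the junction translated
#'   in the J reading frame carries no stop, else `unproductive`.
#'
#' @param category Junction-class category (`complete_VJ`, `incomplete_DJ`,
#'   `incomplete_VD`, `other`); vectorized.
#' @param in_frame Logical: V-to-J frame preserved (only used for
#'   `complete_VJ`; may be `NA` otherwise).
#' @param junction_aa Junction amino-acid string in the class's reading frame.
#' @param damaged Logical: junction window not fully covered.
#' @return Character vector over `productive`, `potentially_productive`,
#'   `unproductive`, `unknown`.
#' @export
determine_productivity <- function(category, in_frame, junction_aa, damaged) {
  n <- length(category)
  stopifnot(length(in_frame) == n, length(junction_aa) == n,
            length(damaged) == n)
  out <- rep("unknown", n)
  has_stop <- grepl("*", junction_aa, fixed = TRUE)
  cvj <- !damaged & category == "complete_VJ"
  if (any(cvj & is.na(in_frame))) {
    abort("in_frame is required (non-NA) for undamaged complete_VJ records")
  }
  out[cvj] <- ifelse(in_frame[cvj] & !has_stop[cvj],
                     "productive", "unproductive")
  dj <- !damaged & category == "incomplete_DJ"
  out[dj] <- ifelse(has_stop[dj], "unproductive", "potentially_productive")
  out
}

# key component formatting: NA segmentation fields (damaged records with
# undetermined statistics) render as "?" so partial keys stay distinct from
# determined zeros.
key_field <- function(x) ifelse(is.na(x), "?", as.character(x))

#' Identity key of rearrangements
#'
#' Builds the 7-component identity key that organizes rearrangements for
#' de-duplication, cross-case uniqueness filtering and cross-platform
#' matching: junction class, 5' gene, 5' gene deletions, N-(D)-N length,
#' 3' gene deletions, 3' gene, and junction amino-acid sequence. Fragment
#' counts are not part of the key. Undetermined components of damaged
#' records render as `?` (a partial key).
#'
#' @param df Data frame with columns `junction_class`, `five_gene`,
#'   `five_del`, `ndn_length`, `three_del`, `three_gene`, `junction_aa`.
#' @return Character vector of keys, one per row.
#' @export
identity_key <- function(df) {
  req <- c("junction_class", "five_gene", "five_del", "ndn_length",
           "three_del", "three_gene", "junction_aa")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("identity_key needs columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  paste(df$junction_class, df$five_gene, key_field(df$five_del),
        key_field(df$ndn_length), key_field(df$three_del), df$three_gene,
        ifelse(is.na(df$junction_aa), "", df$junction_aa),
        sep = "|")
}
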