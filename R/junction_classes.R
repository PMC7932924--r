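# The 22-class junction taxonomy and classification of segment pairs.

# Registry rows are ordered as rendered in per-class reports. Columns
# five_pattern / three_pattern restrict gene names where a class is
# gene-specific (TRD D and J elements).
JUNCTION_CLASS_REGISTRY <- tibble::tribble(
  ~label,        ~locus_group, ~category,       ~five_locus, ~five_type,   ~three_locus, ~three_type, ~five_pattern, ~three_pattern,
  "Vh-(Dh)-Jh",  "IGH",   "complete_VJ",   "IGH", "V",          "IGH", "J",   NA,        NA,
  "Dh-Jh",       "IGH",   "incomplete_DJ", "IGH", "D",          "IGH", "J",   NA,        NA,
  "Vk-Jk",       "IGK",   "complete_VJ",   "IGK", "V",          "IGK", "J",   NA,        NA,
  "Vk-Kde",      "IGK",   "other",         "IGK", "V",          "IGK", "KDE", NA,        NA,
  "intron-Kde",  "IGK",   "other",         "IGK", "INTRON_RSS", "IGK", "KDE", NA,        NA,
  "Vl-Jl",       "IGL",   "complete_VJ",   "IGL", "V",          "IGL", "J",   NA,        NA,
  "Va-Ja",       "TRA",   "complete_VJ",   "TRA", "V",          "TRA", "J",   NA,        NA,
  "Va-Jd",       "TRA+D", "complete_VJ",   "TRA", "V",          "TRD", "J",   NA,        NA,
  "Vd-(Dd)-Ja",  "TRA+D", "complete_VJ",   "TRD", "V",          "TRA", "J",   NA,        NA,
  "Dd-Ja",       "TRA+D", "incomplete_DJ", "TRD", "D",          "TRA", "J",   NA,        NA,
  "Va-Dd",       "TRA+D", "incomplete_VD", "TRA", "V",          "TRD", "D",   NA,        NA,
  "Vb-(Db)-Jb",  "TRB",   "complete_VJ",   "TRB", "V",          "TRB", "J",   NA,        NA,
  "Db-Jb",       "TRB",   "incomplete_DJ", "TRB", "D",          "TRB", "J",   NA,        NA,
  "Vb-Db",       "TRB",   "incomplete_VD", "TRB", "V",          "TRB", "D",   NA,        NA,
  "Db-Db",       "TRB",   "other",         "TRB", "D",          "TRB", "D",   NA,        NA,
  "Vd-(Dd)-Jd",  "TRD",   "complete_VJ",   "TRD", "V",          "TRD", "J",   NA,        NA,
  "Dd2-Jd1",     "TRD",   "incomplete_DJ", "TRD", "D",          "TRD", "J",   "^TRDD2$", "^TRDJ1$",
  "Dd3-Jd",      "TRD",   "incomplete_DJ", "TRD", "D",          "TRD", "J",   "^TRDD3$", NA,
  "Vd-Dd3",      "TRD",   "incomplete_VD", "TRD", "V",          "TRD", "D",   NA,        "^TRDD3$",
  "Dd2-Dd3",     "TRD",   "other",         "TRD", "D",          "TRD", "D",   "^TRDD2$", "^TRDD3$",
  "Dd3-Dd2",     "TRD",   "other",         "TRD", "D",          "TRD", "D",   "^TRDD3$", "^TRDD2$",
  "Vg-Jg",       "TRG",   "complete_VJ",   "TRG", "V",          "TRG", "J",   NA,        NA
)

#' The 22 IG/TR junction classes
#'
#' Returns the registry of rearrangement types ("junction classes") used
#' throughout the package: 22 labels over the seven IG/TR loci, grouped into
#' the categories complete VJ, incomplete DJ, incomplete VD and other
#' (Kde/intronRSS and D-D joints). Rows are in canonical report order.
#'
#' @return Tibble with columns `label`, `locus_group`, `category`, and the
#'   5'/3' segment constraints (`five_locus`, `five_type`, `three_locus`,
#'   `three_type`, plus gene-name patterns for the TRD D/J-specific classes).
#' @export
junction_classes <- function() JUNCTION_CLASS_REGISTRY

# match a (5' segment, 3' segment) pair against the registry; returns label
# or NA. Vectorized over equal-length inputs.
match_class_label <- function(five_locus, five_type, five_name,
                              three_locus, three_type, three_name) {
  reg <- JUNCTION_CLASS_REGISTRY
  n <- length(five_locus)
  out <- rep(NA_character_, n)
  for (k in seq_len(nrow(reg))) {
    hit <- five_locus == reg$five_locus[k] & five_type == reg$five_type[k] &
      three_locus == reg$three_locus[k] & three_type == reg$three_type[k]
    if (!is.na(reg$five_pattern[k])) {
      hit <- hit & grepl(reg$five_pattern[k], five_name)
    }
    if (!is.na(reg$three_pattern[k])) {
      hit <- hit & grepl(reg$three_pattern[k], three_name)
    }
    out[is.na(out) & hit] <- reg$label[k]
  }
  out
}

#' Classify a 5'/3' gene segment pair into a junction class
#'
#' Maps a pair of germline segments to one of the 22 junction classes.
#' Cross-locus TRA/TRD hybrid classes (Va-Jd, Vd-(Dd)-Ja, Dd-Ja, Va-Dd) are
#' honored, and the TRD D-gene-specific classes dispatch on gene name
#' (TRDD2 vs TRDD3; Dd2-Jd1 additionally requires TRDJ1).
#'
#' @param five_gene,three_gene Segment names (character vectors of equal
#'   length) present in `ref`.
#' @param ref A `germline_reference` tibble.
#' @param strict If `TRUE` (default) an unclassifiable pair is an error
#'   naming the pair; if `FALSE` it yields `NA`.
#' @return Character vector of class labels.
#' @export
classify_junction_class <- function(five_gene, three_gene, ref,
                                    strict = TRUE) {
  i5 <- match(five_gene, ref$name)
  i3 <- match(three_gene, ref$name)
  if (anyNA(i5) || anyNA(i3)) {
    missing_gene <- unique(c(five_gene[is.na(i5)], three_gene[is.na(i3)]))
    abort(paste0("segment(s) not in reference: ",
                 paste(missing_gene, collapse = ", ")))
  }
  lab <- match_class_label(ref$locus[i5], ref$segment_type[i5], five_gene,
                           ref$locus[i3], ref$segment_type[i3], three_gene)
  if (strict && anyNA(lab)) {
    j <- which(is.na(lab))[1]
    abort(paste0("unclassifiable segment pair: (", five_gene[j], ", ",
                 three_gene[j], ")"))
  }
  lab
}

class_category <- function(label) {
  JUNCTION_CLASS_REGISTRY$category[match(label, JUNCTION_CLASS_REGISTRY$label)]
}

class_locus_group <- function(label) {
  JUNCTION_CLASS_REGISTRY$locus_group[
    match(label, JUNCTION_CLASS_REGISTRY$label)]
}

# eligible germline 5'/3' genes for a class
class_gene_pool <- function(ref, label, side = c("five", "three")) {
  side <- match.arg(side)
  reg <- JUNCTION_CLASS_REGISTRY[JUNCTION_CLASS_REGISTRY$label == label, ]
  if (nrow(reg) == 0) abort(paste0("unknown junction class: ", label))
  locus <- reg[[paste0(side, "_locus")]]
  type <- reg[[paste0(side, "_type")]]
  pat <- reg[[paste0(side, "_pattern")]]
  pool <- ref$name[ref$locus == locus & ref$segment_type == type]
  if (!is.na(pat)) pool <- pool[grepl(pat, pool)]
  pool
}
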