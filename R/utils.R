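# Internal helpers: seed derivation, sequence primitives, FASTQ/TSV I/O.

# Splittable seeding: derive a stable child seed from a parent seed and a
# string tag, so each stage/case can be re-run independently with identical
# results. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 2147483562
  as.integer((as.numeric(seed) %% 2147483562 + h + 1) %% 2147483562)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Write reads to FASTQ
#'
#' Writes a read table (columns `read_id`, `sequence`) to a plain 4-line
#' FASTQ file with uniform qualities.
#'
#' @param reads Data frame with columns `read_id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- vapply(nchar(reads$sequence),
                 function(n) paste(rep("I", n), collapse = ""), "")
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                         "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file path.
#' @return Tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n == 0) {
    return(tibble::tibble(read_id = character(0), sequence = character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
  tibble::tibble(read_id = names(x), sequence = as.character(x))
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
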