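# Family alignments: fixed-width protein alignments over the 20 amino acids
# plus the gap character, keyed by gene identifier. FASTA I/O goes through
# Biostrings.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_family_alignment <- function(family_id, rows) {
  widths <- unique(nchar(rows))
  if (length(rows) && length(widths) != 1L) {
    stop(sprintf("alignment '%s' is ragged (row widths: %s)", family_id,
                 paste(widths, collapse = ", ")), call. = FALSE)
  }
  structure(list(family_id = family_id, rows = rows,
                 width = if (length(rows)) widths else 0L),
            class = "family_alignment")
}

#' Read a protein family alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @param family_id Family identifier; defaults to the file name without
#'   extension.
#' @return A `family_alignment`: list with `family_id`, `rows` (named
#'   character vector, gene_id to aligned sequence) and `width`.
#' @export
read_alignment <- function(path, family_id = NULL) {
  if (is.null(family_id)) family_id <- sub("\\.[^.]*$", "", basename(path))
  aa <- Biostrings::readAAStringSet(path)
  rows <- as.character(aa)
  names(rows) <- sub("\\s.*$", "", names(aa))
  new_family_alignment(family_id, rows)
}

#' Write sequences to FASTA
#'
#' @param rows Named character vector of (possibly aligned) sequences.
#' @param path Output path.
#' @export
write_fasta <- function(rows, path) {
  aa <- Biostrings::AAStringSet(rows)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Remove alignment gaps from a sequence
#'
#' Drops `-` characters; the unknown symbol `X` is retained.
#'
#' @param seq Character vector of aligned sequences.
#' @return Ungapped sequences.
#' @examples
#' ungap(c("A-C", "AX-G"))
#' @export
ungap <- function(seq) {
  gsub("-", "", seq, fixed = TRUE)
}
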