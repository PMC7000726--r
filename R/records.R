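#' Amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, optionally with the unknown
#' residue placeholder \code{X}.
#'
#' @param with_x include the placeholder \code{X}.
#' @return character vector of residue letters.
#' @export
aa_alphabet <- function(with_x = FALSE) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (with_x) c(aa, "X") else aa
}

#' Construct a protein sequence record
#'
#' The basic unit of every sequence-level stage: an identifier, a free-text
#' description and an uppercase one-letter amino-acid sequence over the 20
#' standard residues plus \code{X} for unknown residues.
#'
#' @param id record identifier (non-empty string).
#' @param sequence amino-acid sequence; lowercase letters are uppercased.
#' @param description optional free-text description.
#' @return an object of class \code{protein_record} with elements
#'   \code{id}, \code{description}, \code{sequence}.
#' @examples
#' protein_record("p1", "acdefg")
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein_record: sequence must be non-empty")
  }
  letters_seen <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters_seen), aa_alphabet(with_x = TRUE))
  if (length(bad) > 0) {
    stop("protein_record: sequence of '", id,
         "' contains disallowed characters: ",
         paste(bad, collapse = " "))
  }
  structure(list(id = id, description = description, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$sequence)
  cat("<protein_record> ", x$id,
      if (nzchar(x$description)) paste0(" (", x$description, ")") else "",
      "\n", sep = "")
  shown <- if (n > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat("  ", shown, "  [", n, " aa]\n", sep = "")
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

# sequence as a character vector of single letters
seq_chars <- function(record) {
  strsplit(record$sequence, "", fixed = TRUE)[[1]]
}
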