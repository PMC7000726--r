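#' Read a multi-record FASTA file of protein sequences
#'
#' Sequences are uppercased on input; characters outside the 20 standard
#' residue letters plus \code{X} are rejected.  An empty file yields an
#' empty list.
#'
#' @param path path to a FASTA file.
#' @return list of \code{\link{protein_record}} objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0) return(list())
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(list())
  if (!startsWith(first, ">")) {
    stop("read_fasta: malformed FASTA (first line is not a '>' header): ",
         path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    out[[i]] <- protein_record(id, as.character(set[[i]]), desc)
  }
  out
}

#' Write protein records to a FASTA file
#'
#' @param records list of \code{\link{protein_record}} objects.
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
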