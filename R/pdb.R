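# 3-letter -> 1-letter mapping; MSE (selenomethionine) maps to M, anything
# else outside the standard 20 maps to X.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O")

atom_columns <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                  "x", "y", "z", "o")

#' Construct a protein structure from an atom table
#'
#' A structure is a flat, ordered atom table (one row per atom, coordinates
#' in Angstrom) plus an identifier and the crystallographic resolution when
#' known.  Chains are the unique values of the \code{chain} column; residues
#' within a chain are ordered by (sequence number, insertion code).
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety} (atom name), \code{elesy}
#'   (element), \code{x}, \code{y}, \code{z}, \code{o} (occupancy).
#' @param resolution resolution in Angstrom, or \code{NA} when unknown.
#' @return object of class \code{protein_structure}.
#' @export
protein_structure <- function(id, atoms, resolution = NA_real_) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(atom_columns, names(atoms))
  if (length(missing_cols) > 0) {
    stop("protein_structure: atom table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[, atom_columns]
  if (nrow(atoms) == 0) stop("protein_structure: empty atom table")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("protein_structure: non-finite atom coordinates")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  # stable order: chains in first-appearance order, residues by number and
  # insertion code, atoms in input order within a residue
  chain_rank <- match(atoms$chain, unique(atoms$chain))
  ord <- order(chain_rank, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, resolution = resolution, atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, "\n", sep = "")
  if (!is.na(x$resolution)) {
    cat("  resolution: ", format(x$resolution), " A\n", sep = "")
  }
  for (ch in structure_chains(x)) {
    a <- x$atoms[x$atoms$chain == ch, ]
    nres <- nrow(unique(a[, c("resno", "insert")]))
    cat("  chain ", ch, ": ", nres, " residues, ", nrow(a), " atoms\n",
        sep = "")
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param structure a \code{protein_structure}.
#' @return character vector of chain ids in order of first appearance.
#' @export
structure_chains <- function(structure) {
  unique(structure$atoms$chain)
}

# atom rows of one chain, in residue order
chain_atoms <- function(structure, chain_id) {
  a <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) {
    stop("chain '", chain_id, "' not found in structure '", structure$id, "'")
  }
  a
}

#' Per-residue table for one chain
#'
#' @param structure a \code{protein_structure}.
#' @param chain_id single chain identifier.
#' @return data.frame with one row per residue (\code{resno}, \code{insert},
#'   \code{resid}), ordered by (sequence number, insertion code).
#' @export
chain_residues <- function(structure, chain_id) {
  a <- chain_atoms(structure, chain_id)
  res <- unique(a[, c("resno", "insert", "resid")])
  rownames(res) <- NULL
  res
}

#' Read a PDB coordinate file
#'
#' Keeps the first MODEL only, resolves alternate locations by highest
#' occupancy (tie broken by file order), and drops waters and HETATM records
#' that are not amino acids (MSE is retained as a residue).  Resolution is
#' taken from the \code{REMARK   2 RESOLUTION} header when present.
#'
#' @param path path to a PDB-format file.
#' @param id structure identifier; default is the file name without extension.
#' @return a \code{\link{protein_structure}}.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("read_pdb: no such file: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("read_pdb: cannot parse '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM")) {
    stop("read_pdb: no ATOM records in ", path)
  }
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% names(AA_321))
  keep <- keep & !(at$resid %in% WATER_NAMES)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("read_pdb: no polymer atoms in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  # alternate locations: keep highest occupancy; tie -> first in file
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at$elesy[is.na(at$elesy) | !nzchar(at$elesy)] <-
    substr(trimws(at$elety[is.na(at$elesy) | !nzchar(at$elesy)]), 1, 1)
  protein_structure(id,
                    at[, c("chain", "resno", "insert", "resid", "elety",
                           "elesy", "x", "y", "z", "o")],
                    resolution = parse_resolution(path))
}

# REMARK   2 RESOLUTION.    1.10 ANGSTROMS.
parse_resolution <- function(path) {
  hdr <- readLines(path, n = 500L, warn = FALSE)
  rl <- grep("^REMARK   2 RESOLUTION", hdr, value = TRUE)
  if (length(rl) == 0) return(NA_real_)
  rest <- sub("^REMARK   2 RESOLUTION\\.?", "", rl[1])
  m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

#' Write a structure as PDB-format text
#'
#' Emits ATOM records (plus a \code{REMARK   2} resolution line when known)
#' with coordinates at 0.001 Angstrom precision, so that reading the file
#' back reproduces the structure.
#'
#' @param structure a \code{\link{protein_structure}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  lines <- character(0)
  if (!is.na(structure$resolution)) {
    lines <- sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.",
                     structure$resolution)
  }
  name_field <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                       sprintf(" %-3s", at$elety))
  rec <- sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(at)) %% 100000L, name_field,
                 substr(at$resid, 1, 3), at$chain, at$resno,
                 ifelse(nzchar(at$insert), at$insert, " "),
                 at$x, at$y, at$z, at$o, 0,
                 toupper(substr(at$elesy, 1, 2)))
  writeLines(c(lines, rec, "END"), path)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Maps the chain's ordered residues to one-letter codes: the 20 standard
#' residues map normally, MSE maps to M, anything else maps to X.
#'
#' @param structure a \code{\link{protein_structure}}.
#' @param chain_id chain identifier; default is the first chain.
#' @return a \code{\link{protein_record}} whose id is
#'   \code{"<structure id>_<chain id>"}.
#' @export
chain_sequence <- function(structure, chain_id = structure_chains(structure)[1]) {
  res <- chain_residues(structure, chain_id)
  letters1 <- AA_321[res$resid]
  letters1[is.na(letters1)] <- "X"
  protein_record(paste0(structure$id, "_", chain_id),
                 paste(letters1, collapse = ""),
                 description = paste("chain", chain_id))
}
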