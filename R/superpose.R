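#' Pair C-alpha atoms of two chains through a sequence alignment
#'
#' Takes one C-alpha coordinate pair per aligned (non-gap) column in which
#' both residues actually have a CA atom; columns with a gap on either side
#' or a missing CA are skipped.
#'
#' @param alignment an \code{alignment_result} whose de-gapped sequences
#'   equal the chains' one-letter sequences.
#' @param structure_a,structure_b \code{protein_structure} objects.
#' @param chain_a,chain_b chain identifiers.
#' @return object of class \code{paired_coordinates}: list with
#'   \code{points_a}, \code{points_b} (n x 3 matrices, Angstrom) and
#'   \code{residues} (data.frame of residue provenance).
#' @export
pair_ca_atoms <- function(alignment, structure_a, structure_b,
                          chain_a = structure_chains(structure_a)[1],
                          chain_b = structure_chains(structure_b)[1]) {
  ca_table <- function(structure, chain_id) {
    at <- chain_atoms(structure, chain_id)
    res <- chain_residues(structure, chain_id)
    key_res <- paste(res$resno, res$insert)
    ca <- at[at$elety == "CA", , drop = FALSE]
    idx <- match(key_res, paste(ca$resno, ca$insert))
    list(res = res, ca = ca, idx = idx)
  }
  ta <- ca_table(structure_a, chain_a)
  tb <- ca_table(structure_b, chain_b)
  ga <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  if (sum(ga != "-") != nrow(ta$res) || sum(gb != "-") != nrow(tb$res)) {
    stop("pair_ca_atoms: alignment does not match chain residue counts")
  }
  pos_a <- cumsum(ga != "-")
  pos_b <- cumsum(gb != "-")
  use <- which(ga != "-" & gb != "-")
  ia <- ta$idx[pos_a[use]]
  ib <- tb$idx[pos_b[use]]
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]
  ib <- ib[ok]
  if (length(ia) < 3) {
    stop("pair_ca_atoms: fewer than 3 aligned residue pairs with CA atoms")
  }
  pa <- as.matrix(ta$ca[ia, c("x", "y", "z")])
  pb <- as.matrix(tb$ca[ib, c("x", "y", "z")])
  dimnames(pa) <- dimnames(pb) <- NULL
  structure(list(points_a = pa, points_b = pb,
                 residues = data.frame(
                   resno_a = ta$ca$resno[ia], resid_a = ta$ca$resid[ia],
                   resno_b = tb$ca$resno[ib], resid_b = tb$ca$resid[ib])),
            class = "paired_coordinates")
}

# bare coordinate matrices -> paired_coordinates
paired_coordinates <- function(points_a, points_b) {
  points_a <- as.matrix(points_a)
  points_b <- as.matrix(points_b)
  stopifnot(ncol(points_a) == 3, ncol(points_b) == 3,
            nrow(points_a) == nrow(points_b), nrow(points_a) >= 3)
  structure(list(points_a = points_a, points_b = points_b,
                 residues = NULL),
            class = "paired_coordinates")
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping \code{points_b} onto
#' \code{points_a} via singular value decomposition of the covariance
#' matrix; a reflection solution is corrected by flipping the sign of the
#' smallest singular direction, so the result is always a proper rotation
#' (det = +1).
#'
#' @param pairs a \code{paired_coordinates} object (or anything accepted by
#'   its constructor through \code{points_a}/\code{points_b} matrices).
#' @return object of class \code{superposition_result}: \code{rotation}
#'   (3 x 3), \code{translation} (length 3), \code{rmsd} (Angstrom),
#'   \code{n_used}, \code{n_rejected}, \code{cycles_run}.  The fitted copy
#'   of \code{points_b} is \code{points_b \%*\% t(rotation) + translation}
#'   rowwise.
#' @export
kabsch <- function(pairs) {
  pa <- pairs$points_a
  pb <- pairs$points_b
  n <- nrow(pa)
  stopifnot(n >= 3)
  ca <- colMeans(pa)
  cb <- colMeans(pb)
  qa <- sweep(pa, 2, ca)
  qb <- sweep(pb, 2, cb)
  H <- t(qb) %*% qa
  sv <- svd(H)
  if (sv$d[2] < 1e-10) {
    stop("kabsch: degenerate geometry (points collinear or coincident)")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("kabsch: degenerate geometry")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- qb %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - qa)^2)))
  translation <- as.numeric(ca - cb %*% t(R))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_used = n, n_rejected = 0L, cycles_run = 1L),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd %.3f A over %d pairs (%d rejected, %d cycle%s)\n",
              x$rmsd, x$n_used, x$n_rejected, x$cycles_run,
              if (x$cycles_run == 1) "" else "s"))
  invisible(x)
}

# per-pair distances after applying a superposition to points_b
superposition_distances <- function(fit, pairs) {
  moved <- pairs$points_b %*% t(fit$rotation) +
    matrix(fit$translation, nrow(pairs$points_b), 3, byrow = TRUE)
  sqrt(rowSums((moved - pairs$points_a)^2))
}

#' Superposition with iterative outlier rejection
#'
#' Repeats \{fit, drop pairs whose post-fit distance exceeds
#' \code{reject_cutoff}\} until no pair is rejected or \code{cycles} cycles
#' have run, then reports the final fit over the retained pairs.  With
#' \code{cycles = 0} this is a single plain Kabsch fit.
#'
#' @param pairs a \code{paired_coordinates} object.
#' @param cycles maximum number of rejection cycles (default 5).
#' @param reject_cutoff post-fit distance cutoff in Angstrom (default 2.0).
#' @return a \code{superposition_result}; \code{n_rejected} counts pairs
#'   dropped across all cycles.
#' @export
refine_superposition <- function(pairs, cycles = 5, reject_cutoff = 2.0) {
  keep <- seq_len(nrow(pairs$points_a))
  current <- pairs
  fit <- kabsch(current)
  cycles_run <- 1L
  while (cycles_run <= cycles) {
    dist <- superposition_distances(fit, current)
    bad <- dist > reject_cutoff
    if (!any(bad)) break
    if (sum(!bad) < 3) {
      stop("refine_superposition: fewer than 3 pairs left after rejection")
    }
    keep <- keep[!bad]
    current <- paired_coordinates(pairs$points_a[keep, , drop = FALSE],
                                  pairs$points_b[keep, , drop = FALSE])
    fit <- kabsch(current)
    cycles_run <- cycles_run + 1L
  }
  fit$n_used <- length(keep)
  fit$n_rejected <- nrow(pairs$points_a) - length(keep)
  fit$cycles_run <- cycles_run
  fit
}

#' Align two chains and superpose their C-alpha traces
#'
#' Convenience wrapper: global sequence alignment of the two chains'
#' ATOM-derived sequences, C-alpha pairing over identity-aligned columns,
#' then (optionally refined) Kabsch superposition.
#'
#' @param structure_a,structure_b \code{protein_structure} objects.
#' @param chain_a,chain_b chain ids (default: first chain of each).
#' @param refine logical; apply iterative outlier rejection.
#' @param cycles,reject_cutoff refinement parameters.
#' @param ... passed to \code{\link{needleman_wunsch}}.
#' @return a \code{superposition_result} with the alignment attached as
#'   attribute \code{"alignment"}.
#' @export
superpose_chains <- function(structure_a, structure_b,
                             chain_a = structure_chains(structure_a)[1],
                             chain_b = structure_chains(structure_b)[1],
                             refine = TRUE, cycles = 5, reject_cutoff = 2.0,
                             ...) {
  aln <- needleman_wunsch(chain_sequence(structure_a, chain_a),
                          chain_sequence(structure_b, chain_b), ...)
  pairs <- pair_ca_atoms(aln, structure_a, structure_b, chain_a, chain_b)
  fit <- if (refine) {
    refine_superposition(pairs, cycles = cycles,
                         reject_cutoff = reject_cutoff)
  } else {
    kabsch(pairs)
  }
  attr(fit, "alignment") <- aln
  fit
}
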