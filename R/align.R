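#' Default substitution matrix (BLOSUM62, X neutral)
#'
#' BLOSUM62 restricted to the 20 standard residues plus X, with every score
#' against X set to 0 so unknown residues neither reward nor penalize a
#' column.
#'
#' @return 21 x 21 symmetric integer matrix.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[aa_alphabet(with_x = TRUE), aa_alphabet(with_x = TRUE)]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  attr(m, "name") <- "BLOSUM62"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by BLAST/EMBOSS: \code{#}
#' comment lines, a header row of column letters, then one row per letter.
#'
#' @param path path to the matrix file.
#' @return symmetric numeric matrix with residue-letter dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2) stop("read_score_matrix: not a matrix file: ", path)
  cols <- strsplit(lines[1], "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\\s+")[[1]])
  row_letters <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(cols))))
  dimnames(vals) <- list(row_letters, cols)
  if (!isTRUE(all.equal(vals, t(vals)))) {
    stop("read_score_matrix: matrix is not symmetric")
  }
  attr(vals, "name") <- basename(path)
  vals
}

#' Global pairwise alignment with affine gap penalties
#'
#' Three-state (match / gap-in-b / gap-in-a) Needleman-Wunsch dynamic
#' programming.  A gap of length L costs
#' \code{gap_open + (L - 1) * gap_extend}; with \code{end_gaps_free = TRUE}
#' (the default, matching the common global-aligner convention) leading and
#' trailing gaps are not penalized but still appear in the alignment and
#' count toward its length.  Traceback ties are broken deterministically:
#' diagonal, then up (gap in b), then left (gap in a).
#'
#' Percent identity is identical columns over the full alignment length
#' (gap columns included); percent similarity counts columns whose
#' substitution score is positive.
#'
#' @param a,b \code{\link{protein_record}} objects.
#' @param matrix substitution matrix (default \code{\link{blosum62_matrix}}).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @param end_gaps_free logical; leave terminal gaps unpenalized.
#' @return object of class \code{alignment_result}: \code{aligned_a},
#'   \code{aligned_b}, \code{score}, \code{identity_pct},
#'   \code{similarity_pct}, \code{gaps_pct}, \code{length}, \code{id_a},
#'   \code{id_b}.
#' @examples
#' r <- needleman_wunsch(protein_record("x", "HEAGAWGHEE"),
#'                       protein_record("y", "PAWHEAE"))
#' r$identity_pct
#' @export
needleman_wunsch <- function(a, b, matrix = blosum62_matrix(),
                             gap_open = 10, gap_extend = 0.5,
                             end_gaps_free = TRUE) {
  sa <- seq_chars(a)
  sb <- seq_chars(b)
  n <- length(sa)
  m <- length(sb)
  stopifnot(n >= 1, m >= 1)
  if (!all(sa %in% rownames(matrix)) || !all(sb %in% rownames(matrix))) {
    stop("needleman_wunsch: residue letter missing from matrix")
  }
  NEG <- -1e18
  # state matrices, rows 0..n, cols 0..m
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  gp <- function(len) ifelse(len > 0, gap_open + (len - 1) * gap_extend, 0)
  X[2:(n + 1), 1] <- if (end_gaps_free) 0 else -gp(1:n)
  if (m >= 1) Y[1, 2:(m + 1)] <- if (end_gaps_free) 0 else -gp(1:m)
  smat <- matrix[sa, sb, drop = FALSE]  # n x m lookup
  for (i in 2:(n + 1)) {
    prevM <- M[i - 1, ]
    prevX <- X[i - 1, ]
    prevY <- Y[i - 1, ]
    jj <- 2:(m + 1)
    M[i, jj] <- smat[i - 1, jj - 1] +
      pmax(prevM[jj - 1], prevX[jj - 1], prevY[jj - 1])
    X[i, jj] <- pmax(prevM[jj] - gap_open, prevX[jj] - gap_extend,
                     prevY[jj] - gap_open)
    yrow <- Y[i, ]
    Mi <- M[i, ]
    Xi <- X[i, ]
    for (j in jj) {
      yrow[j] <- max(Mi[j - 1] - gap_open, Xi[j - 1] - gap_open,
                     yrow[j - 1] - gap_extend)
    }
    Y[i, ] <- yrow
  }
  best <- pmax(M, X, Y)
  if (end_gaps_free) {
    # endpoint anywhere on the last row/column; trailing gaps are free.
    # Prefer endpoints using more of both sequences, then more of a.
    cand <- rbind(cbind(i = 1:(n + 1), j = m + 1),
                  cbind(i = n + 1, j = 1:(m + 1)))
    vals <- best[cand]
    top <- which(vals >= max(vals) - 1e-9)
    ord <- top[order(-(cand[top, 1] + cand[top, 2]), -cand[top, 1])]
    ei <- cand[ord[1], 1]
    ej <- cand[ord[1], 2]
  } else {
    ei <- n + 1
    ej <- m + 1
  }
  score <- best[ei, ej]

  # traceback; states: 1 = M (diagonal), 2 = X (up, gap in b),
  # 3 = Y (left, gap in a).  Ties prefer diagonal, then up, then left.
  pick_state <- function(opts, target) {
    which(abs(opts - target) < 1e-6)[1]
  }
  out_a <- character(0)
  out_b <- character(0)
  # trailing gaps beyond the chosen endpoint (free-end-gap mode only)
  if (ei <= n) {
    out_a <- rev(sa[ei:n])
    out_b <- rep("-", n - ei + 1)
  } else if (ej <= m) {
    out_a <- rep("-", m - ej + 1)
    out_b <- rev(sb[ej:m])
  }
  i <- ei
  j <- ej
  state <- pick_state(c(M[i, j], X[i, j], Y[i, j]), score)
  repeat {
    if (i == 1 && j == 1) break
    if (j == 1) {
      # only the leading gap-in-b run reaches column 0
      out_a <- c(out_a, rev(sa[1:(i - 1)]))
      out_b <- c(out_b, rep("-", i - 1))
      break
    }
    if (i == 1) {
      out_a <- c(out_a, rep("-", j - 1))
      out_b <- c(out_b, rev(sb[1:(j - 1)]))
      break
    }
    if (state == 1) {
      out_a <- c(out_a, sa[i - 1])
      out_b <- c(out_b, sb[j - 1])
      target <- M[i, j] - smat[i - 1, j - 1]
      i <- i - 1
      j <- j - 1
      state <- pick_state(c(M[i, j], X[i, j], Y[i, j]), target)
    } else if (state == 2) {
      out_a <- c(out_a, sa[i - 1])
      out_b <- c(out_b, "-")
      target <- X[i, j]
      i <- i - 1
      state <- pick_state(c(M[i, j] - gap_open, X[i, j] - gap_extend,
                            Y[i, j] - gap_open), target)
    } else {
      out_a <- c(out_a, "-")
      out_b <- c(out_b, sb[j - 1])
      target <- Y[i, j]
      j <- j - 1
      state <- pick_state(c(M[i, j] - gap_open, X[i, j] - gap_open,
                            Y[i, j] - gap_extend), target)
    }
    if (is.na(state)) stop("needleman_wunsch: internal traceback failure")
  }
  aligned_a <- paste(rev(out_a), collapse = "")
  aligned_b <- paste(rev(out_b), collapse = "")
  alignment_stats(aligned_a, aligned_b, score, matrix, a$id, b$id)
}

alignment_stats <- function(aligned_a, aligned_b, score, matrix, id_a, id_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  len <- length(ca)
  no_gap <- ca != "-" & cb != "-"
  ident <- sum(no_gap & ca == cb)
  simil <- sum(no_gap & matrix[cbind(
    match(ifelse(no_gap, ca, "A"), rownames(matrix)),
    match(ifelse(no_gap, cb, "A"), colnames(matrix)))] > 0 & no_gap)
  gaps <- sum(!no_gap)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score,
                 identity_pct = 100 * ident / len,
                 similarity_pct = 100 * simil / len,
                 gaps_pct = 100 * gaps / len,
                 length = len, id_a = id_a, id_b = id_b),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$id_a, " vs ", x$id_b, "\n", sep = "")
  cat(sprintf("  length %d  score %.1f  identity %.1f%%  similarity %.1f%%  gaps %.1f%%\n",
              x$length, x$score, x$identity_pct, x$similarity_pct,
              x$gaps_pct))
  block <- 60
  for (k in seq(1, x$length, by = block)) {
    end <- min(k + block - 1, x$length)
    cat("  ", substr(x$aligned_a, k, end), "\n", sep = "")
    cat("  ", substr(x$aligned_b, k, end), "\n\n", sep = "")
  }
  invisible(x)
}

#' Pairwise alignment table for a collection of sequence pairs
#'
#' @param pairs list of two-element lists
#'   (\code{\link{protein_record}} pairs).
#' @param ... passed to \code{\link{needleman_wunsch}}.
#' @return data.frame with one row per pair: \code{id_a}, \code{id_b},
#'   \code{identity_pct}, \code{similarity_pct}, \code{gaps_pct},
#'   \code{score}, \code{length}.  Empty input yields an empty table.
#' @export
align_pairs <- function(pairs, ...) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      identity_pct = numeric(0), similarity_pct = numeric(0),
                      gaps_pct = numeric(0), score = numeric(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (length(pairs) == 0) return(empty)
  rows <- lapply(pairs, function(pr) {
    r <- needleman_wunsch(pr[[1]], pr[[2]], ...)
    data.frame(id_a = r$id_a, id_b = r$id_b,
               identity_pct = r$identity_pct,
               similarity_pct = r$similarity_pct,
               gaps_pct = r$gaps_pct, score = r$score,
               length = r$length, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
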