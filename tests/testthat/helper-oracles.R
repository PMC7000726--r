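# Independent oracles used to cross-check the package's implementations.
# Each one is deliberately written as a different algorithm from the code
# path it checks (enumeration, grid scan, generic numerical optimization,
# permutation resampling).

# all global alignments of two short character vectors, as op strings
# ("M" both, "X" gap in b, "Y" gap in a); exhaustive enumeration.
enumerate_alignments <- function(n, m) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(character(0)))
    out <- list()
    if (i > 0 && j > 0) {
      out <- c(out, lapply(rec(i - 1, j - 1), function(p) c(p, "M")))
    }
    if (i > 0) out <- c(out, lapply(rec(i - 1, j), function(p) c(p, "X")))
    if (j > 0) out <- c(out, lapply(rec(i, j - 1), function(p) c(p, "Y")))
    out
  }
  rec(n, m)
}

# affine-gap score of one op path: a gap run of length L costs
# open + (L-1)*ext; with end_free, runs touching either end are free
score_path <- function(ops, sa, sb, matrix, open, ext, end_free) {
  score <- 0
  i <- 0
  j <- 0
  runs <- rle(ops)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in seq_along(runs$values)) {
    op <- runs$values[r]
    len <- runs$lengths[r]
    if (op == "M") {
      for (k in seq_len(len)) {
        i <- i + 1
        j <- j + 1
        score <- score + matrix[sa[i], sb[j]]
      }
    } else {
      if (op == "X") i <- i + len else j <- j + len
      terminal <- starts[r] == 1 || ends[r] == length(ops)
      if (!(end_free && terminal)) {
        score <- score - (open + (len - 1) * ext)
      }
    }
  }
  score
}

# optimal global-alignment score by exhaustive enumeration
brute_force_align_score <- function(a, b, matrix, open, ext, end_free) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  paths <- enumerate_alignments(length(sa), length(sb))
  max(vapply(paths, score_path, numeric(1), sa = sa, sb = sb,
             matrix = matrix, open = open, ext = ext, end_free = end_free))
}

# vectorized Henderson-Hasselbalch net charge over a pH grid
grid_net_charge <- function(sequence, pH, pka = default_pka()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- c(nterm = 1, cterm = 1,
              vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(chars == a), numeric(1)))
  q <- rep(0, length(pH))
  for (g in c("nterm", "K", "R", "H")) {
    q <- q + counts[[g]] / (1 + 10^(pH - pka[[g]]))
  }
  for (g in c("cterm", "D", "E", "C", "Y")) {
    q <- q - counts[[g]] / (1 + 10^(pka[[g]] - pH))
  }
  q
}

# pI by brute-force fine-grid scan of the charge equation
grid_pi <- function(sequence, step = 1e-4, pka = default_pka()) {
  grid <- seq(0, 14, by = step)
  q <- grid_net_charge(sequence, grid, pka)
  grid[which.min(abs(q))]
}

# best-fit RMSD by generic numerical minimization over Euler angles and
# translation (multi-start BFGS), independent of the SVD solution
optim_rmsd <- function(pa, pb, n_starts = 12) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    moved <- pb %*% t(rot(par[1:3])) +
      matrix(par[4:6], nrow(pb), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - pa)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- c(stats::runif(3, -pi, pi), colMeans(pa) - colMeans(pb))
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# two-sided permutation p-value for a difference in group means
permutation_p <- function(x, y, n_perm = 4000) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), nx)
    stat <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# pooled-variance two-sample t statistic from the textbook formula
pooled_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t), nx + ny - 2)
  list(t = t, p = p, df = nx + ny - 2)
}

# random protein sequence over the 20 standard letters
random_sequence <- function(len, letters = aa_alphabet()) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
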