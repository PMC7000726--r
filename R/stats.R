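#' Two-sample t-test between descriptor groups
#'
#' Pooled-variance Student's t by default (Welch by flag), two-sided
#' p-value.  Degenerate inputs are resolved explicitly: zero variance in
#' both groups with equal means gives t = 0, p = 1; zero variance with
#' unequal means gives an infinite t (flagged) and p = 0.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @param parameter optional descriptor name carried into the result.
#' @return object of class \code{group_comparison}: list with
#'   \code{parameter}, \code{mean_a}, \code{mean_b}, \code{t}, \code{df},
#'   \code{p}, \code{infinite_t}.
#' @export
t_test <- function(x, y, variant = c("pooled", "welch"), parameter = "") {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  mean_a <- mean(x)
  mean_b <- mean(y)
  df <- if (variant == "pooled") length(x) + length(y) - 2 else NA_real_
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean_a == mean_b) {
      res <- list(t = 0, df = df, p = 1, infinite_t = FALSE)
    } else {
      res <- list(t = sign(mean_a - mean_b) * Inf, df = df, p = 0,
                  infinite_t = TRUE)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, infinite_t = FALSE)
  }
  structure(list(parameter = parameter, mean_a = mean_a, mean_b = mean_b,
                 t = res$t, df = res$df, p = res$p,
                 infinite_t = res$infinite_t),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s mean_a %.4g  mean_b %.4g  t %.4g (df %.4g)  p %.4g\n",
              if (nzchar(x$parameter)) paste0(" ", x$parameter, ":") else "",
              x$mean_a, x$mean_b, x$t, x$df, x$p))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson: zero variance, correlation undefined")
  }
  stats::cor(x, y)
}

#' Per-category correlation of alignment identity with RMSD
#'
#' One Pearson coefficient per category from a per-pair table; categories
#' with fewer than 3 complete pairs are skipped with a warning.
#'
#' @param pair_table data.frame with columns \code{category},
#'   \code{identity_pct}, \code{rmsd} (one row per ortholog pair).
#' @return data.frame with columns \code{category}, \code{n}, \code{r}.
#' @export
category_correlations <- function(pair_table) {
  stopifnot(all(c("category", "identity_pct", "rmsd") %in% names(pair_table)))
  pair_table <- pair_table[is.finite(pair_table$identity_pct) &
                           is.finite(pair_table$rmsd), , drop = FALSE]
  out <- list()
  for (cat_label in unique(pair_table$category)) {
    sub <- pair_table[pair_table$category == cat_label, , drop = FALSE]
    if (nrow(sub) < 3) {
      warning("category_correlations: category '", cat_label,
              "' has fewer than 3 pairs; skipped")
      next
    }
    out[[length(out) + 1]] <- data.frame(
      category = cat_label, n = nrow(sub),
      r = pearson(sub$identity_pct, sub$rmsd),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(category = character(0), n = integer(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
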