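#' Amino-acid composition of a protein
#'
#' Percentage of each of the 20 standard residues in a sequence.  Unknown
#' residues (\code{X}) are excluded from both numerator and denominator, so
#' the percentages always sum to 100.
#'
#' @param record a \code{\link{protein_record}}.
#' @return object of class \code{composition_profile}: list with
#'   \code{percents} (named numeric over the 20 residues, summing to 100)
#'   and \code{length} (number of non-X residues counted).
#' @examples
#' composition_percent(protein_record("p", "ACDE"))$percents[c("A", "C")]
#' @export
composition_percent <- function(record) {
  chars <- seq_chars(record)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) {
    stop("composition_percent: sequence of '", record$id,
         "' has no standard residues (all X)")
  }
  counts <- table(factor(chars, levels = aa_alphabet()))
  percents <- 100 * as.numeric(counts) / length(chars)
  names(percents) <- aa_alphabet()
  structure(list(percents = percents, length = length(chars),
                 id = record$id),
            class = "composition_profile")
}

#' Bin per-protein residue percentages into 2\%-wide occurrence bins
#'
#' Reproduces the occurrence-distribution view of group composition: for each
#' residue type, each protein falls into exactly one of the ten half-open
#' abundance bins [0,2), [2,4), ..., [18,20] (the last bin is closed).
#' Percentages above 20\% are clamped into the last bin with a warning.
#'
#' @param profiles list of \code{composition_profile} objects.
#' @return object of class \code{occurrence_distribution}: list with
#'   \code{counts} (20 x 10 integer matrix, rows = residues, columns = bins)
#'   and \code{n} (number of proteins).
#' @export
bin_occurrences <- function(profiles) {
  if (inherits(profiles, "composition_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  edges <- seq(0, 20, by = 2)
  labels <- paste0("[", edges[-11], ",", edges[-1],
                   c(rep(")", 9), "]"))
  counts <- matrix(0L, nrow = 20, ncol = 10,
                   dimnames = list(aa_alphabet(), labels))
  clamped <- 0L
  for (p in profiles) {
    v <- p$percents
    if (any(v > 20)) clamped <- clamped + sum(v > 20)
    v <- pmin(v, 20)
    bin <- pmin(floor(v / 2) + 1L, 10L)  # 20 exactly -> last bin
    for (i in seq_along(v)) {
      counts[i, bin[i]] <- counts[i, bin[i]] + 1L
    }
  }
  if (clamped > 0) {
    warning("bin_occurrences: ", clamped,
            " percentage value(s) above 20% clamped into the last bin")
  }
  structure(list(counts = counts, n = length(profiles)),
            class = "occurrence_distribution")
}

#' Per-residue composition comparison between two protein groups
#'
#' Runs a two-sample Student's t-test (pooled variance by default) on each
#' residue's percentage across the two groups.
#'
#' @param group_a,group_b lists of \code{composition_profile} objects
#'   (at least 2 proteins per group).
#' @param variant \code{"pooled"} (Student) or \code{"welch"}.
#' @return data.frame with one row per residue: \code{residue},
#'   \code{mean_a}, \code{mean_b}, \code{t}, \code{df}, \code{p}.
#' @export
compare_composition <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("compare_composition: each group needs at least 2 proteins")
  }
  mat_a <- do.call(rbind, lapply(group_a, function(p) p$percents))
  mat_b <- do.call(rbind, lapply(group_b, function(p) p$percents))
  rows <- lapply(aa_alphabet(), function(aa) {
    cmp <- t_test(mat_a[, aa], mat_b[, aa], variant = variant,
                  parameter = aa)
    data.frame(residue = aa, mean_a = cmp$mean_a, mean_b = cmp$mean_b,
               t = cmp$t, df = cmp$df, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
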