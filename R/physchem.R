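#' Default pKa table for net-charge and isoelectric-point calculations
#'
#' EMBOSS-style side-chain and terminal pKa values.  Basic groups (positive
#' when protonated): N-terminus, K, R, H.  Acidic groups (negative when
#' deprotonated): C-terminus, D, E, C, Y.  All values are swappable because
#' published pI calculators differ in their tables.
#'
#' @param ... named overrides, e.g. \code{default_pka(K = 10.5)}.
#' @return named list with elements \code{nterm}, \code{cterm} and one
#'   entry per ionizable side chain, each a single pKa in (0, 14).
#' @export
default_pka <- function(...) {
  pka <- list(nterm = 8.6, cterm = 3.6,
              K = 10.8, R = 12.5, H = 6.5,
              D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(pka)) stop("default_pka: unknown group '", nm, "'")
    pka[[nm]] <- overrides[[nm]]
  }
  stopifnot(all(unlist(pka) > 0), all(unlist(pka) < 14))
  pka
}

PKA_BASIC <- c("nterm", "K", "R", "H")
PKA_ACIDIC <- c("cterm", "D", "E", "C", "Y")

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups, termini included once:
#' \deqn{Q(pH) = \sum_{basic} \frac{1}{1+10^{pH-pK_a}} -
#'              \sum_{acidic} \frac{1}{1+10^{pK_a-pH}}}
#'
#' @param record a \code{\link{protein_record}}.
#' @param pH pH in [0, 14].
#' @param pka pKa table from \code{\link{default_pka}}.
#' @return net charge in elementary charge units.
#' @examples
#' net_charge(protein_record("g", "G"), pH = 7)  # ~ -0.024, termini only
#' @export
net_charge <- function(record, pH = 7, pka = default_pka()) {
  stopifnot(pH >= 0, pH <= 14)
  chars <- seq_chars(record)
  counts <- c(nterm = 1, cterm = 1,
              vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(chars == a), numeric(1)))
  pos <- sum(vapply(PKA_BASIC, function(g) {
    counts[[g]] / (1 + 10^(pH - pka[[g]]))
  }, numeric(1)))
  neg <- sum(vapply(PKA_ACIDIC, function(g) {
    counts[[g]] / (1 + 10^(pka[[g]] - pH))
  }, numeric(1)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which \code{\link{net_charge}} is zero.  The charge is
#' strictly decreasing in pH and every sequence carries both termini, so the
#' root exists and is unique in [0, 14].
#'
#' @param record a \code{\link{protein_record}}.
#' @param pka pKa table from \code{\link{default_pka}}.
#' @param tol convergence tolerance on |charge|, in elementary charges.
#' @return pI in pH units.
#' @examples
#' isoelectric_point(protein_record("gg", "GG"))  # 6.10: terminal midpoint
#' @export
isoelectric_point <- function(record, pka = default_pka(), tol = 1e-4) {
  lo <- 0
  hi <- 14
  # bisect to a pH interval narrow enough that the charge at the midpoint
  # is far below tol even where the titration curve is steep
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- net_charge(record, mid, pka)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  stopifnot(abs(net_charge(record, mid, pka)) < tol)
  mid
}

#' Default residue classification sets
#'
#' Polar/nonpolar sets partition the 20 residues; the hydrophobic set is an
#' independent classification.  The exact memberships behind published
#' web-calculator percentages are not recoverable, so the sets here are
#' explicit defaults and fully overridable.
#'
#' @param hydrophobic,polar character vectors of one-letter codes replacing
#'   the defaults.
#' @return list with \code{hydrophobic}, \code{polar}, \code{nonpolar}
#'   (the complement of \code{polar}).
#' @export
default_residue_classes <- function(hydrophobic = NULL, polar = NULL) {
  if (is.null(hydrophobic)) {
    hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C", "G", "P")
  }
  if (is.null(polar)) {
    polar <- c("D", "E", "H", "K", "N", "Q", "R", "S", "T")
  }
  stopifnot(all(hydrophobic %in% aa_alphabet()),
            all(polar %in% aa_alphabet()))
  list(hydrophobic = hydrophobic, polar = polar,
       nonpolar = setdiff(aa_alphabet(), polar))
}

#' Hydrophobic / polar / nonpolar residue fractions
#'
#' @param record a \code{\link{protein_record}}.
#' @param classes classification sets from
#'   \code{\link{default_residue_classes}}.
#' @return named numeric: \code{hydrophobic_pct}, \code{polar_pct},
#'   \code{nonpolar_pct} (polar + nonpolar = 100; X residues excluded).
#' @export
residue_class_fractions <- function(record, classes = default_residue_classes()) {
  chars <- seq_chars(record)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) {
    stop("residue_class_fractions: no standard residues in '", record$id, "'")
  }
  pct <- function(set) 100 * sum(chars %in% set) / length(chars)
  c(hydrophobic_pct = pct(classes$hydrophobic),
    polar_pct = pct(classes$polar),
    nonpolar_pct = pct(classes$nonpolar))
}

#' Full physicochemical descriptor profile of one protein
#'
#' @param record a \code{\link{protein_record}}.
#' @param pka pKa table.
#' @param classes residue classification sets.
#' @param report_pH pH at which the net charge is reported (default 7,
#'   neutral pH).
#' @return one-row data.frame: \code{id}, \code{length}, \code{pI},
#'   \code{net_charge}, \code{hydrophobic_pct}, \code{polar_pct},
#'   \code{nonpolar_pct}.
#' @export
physchem_profile <- function(record, pka = default_pka(),
                             classes = default_residue_classes(),
                             report_pH = 7) {
  fr <- residue_class_fractions(record, classes)
  data.frame(id = record$id,
             length = nchar(record$sequence),
             pI = isoelectric_point(record, pka),
             net_charge = net_charge(record, report_pH, pka),
             hydrophobic_pct = fr[["hydrophobic_pct"]],
             polar_pct = fr[["polar_pct"]],
             nonpolar_pct = fr[["nonpolar_pct"]],
             stringsAsFactors = FALSE)
}
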