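#' Signed torsion angle of four points
#'
#' IUPAC convention: looking down the p2-p3 axis, the angle from the
#' p1-p2 bond to the p3-p4 bond, positive clockwise, reported in
#' (-180, 180] degrees (0 = cis/eclipsed, 180 = trans).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors in Angstrom.
#' @return angle in degrees.
#' @examples
#' dihedral_angle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0))  # 180 (trans)
#' dihedral_angle(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))  # 0 (cis)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("dihedral_angle: collinear points, torsion undefined")
  }
  ang <- atan2(sum(cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) *
    180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify a peptide-bond omega angle
#'
#' A bond is trans when |omega| > 90 and cis otherwise.  Trans bonds are
#' non-planar when |omega| < 170 degrees (more than 10 degrees from the
#' planar 180); cis bonds are non-planar when |omega| > 20 degrees.  The
#' thresholds apply to |omega|, and both are configurable.
#'
#' @param omega omega angle(s) in degrees; \code{NA} allowed.
#' @param trans_thresh trans planarity threshold on |omega| (default 170).
#' @param cis_thresh cis planarity threshold on |omega| (default 20).
#' @return character vector over \{\code{trans_planar},
#'   \code{trans_nonplanar}, \code{cis_planar}, \code{cis_nonplanar},
#'   \code{undefined}\}.
#' @export
classify_omega <- function(omega, trans_thresh = 170, cis_thresh = 20) {
  out <- rep("undefined", length(omega))
  ok <- !is.na(omega)
  ao <- abs(omega[ok])
  cls <- ifelse(ao > 90,
                ifelse(ao < trans_thresh, "trans_nonplanar", "trans_planar"),
                ifelse(ao > cis_thresh, "cis_nonplanar", "cis_planar"))
  out[ok] <- cls
  out
}

# backbone atom coordinates of a chain as a list of per-residue rows
backbone_coords <- function(structure, chain_id) {
  at <- chain_atoms(structure, chain_id)
  res <- chain_residues(structure, chain_id)
  key_at <- paste(at$resno, at$insert)
  key_res <- paste(res$resno, res$insert)
  grab <- function(name) {
    rows <- at[at$elety == name, , drop = FALSE]
    idx <- match(key_res, paste(rows$resno, rows$insert))
    m <- as.matrix(rows[, c("x", "y", "z")])[idx, , drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  list(res = res, N = grab("N"), CA = grab("CA"), C = grab("C"))
}

#' Backbone phi/psi/omega torsions of a chain
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i), i.e. the torsion of the peptide
#' bond preceding residue i.  Angles are undefined (NA) at chain termini,
#' where a backbone atom is missing, and across chain breaks (peptide
#' C(i-1)-N(i) distance above \code{break_cutoff}).
#'
#' @param structure a \code{protein_structure}.
#' @param chain_id chain identifier (default: first chain).
#' @param break_cutoff C-N distance in Angstrom beyond which consecutive
#'   residues are treated as disconnected (default 2.5).
#' @param trans_thresh,cis_thresh omega planarity thresholds, see
#'   \code{\link{classify_omega}}.
#' @return data.frame with one row per residue: \code{resno},
#'   \code{insert}, \code{resid}, \code{phi}, \code{psi}, \code{omega}
#'   (degrees, NA when undefined) and \code{omega_class}.
#' @export
backbone_torsions <- function(structure, chain_id = structure_chains(structure)[1],
                              break_cutoff = 2.5,
                              trans_thresh = 170, cis_thresh = 20) {
  bc <- backbone_coords(structure, chain_id)
  n <- nrow(bc$res)
  phi <- psi <- omega <- rep(NA_real_, n)
  has <- function(m, i) i >= 1 && i <= n && !is.na(m[i, 1])
  connected <- function(i) {
    # peptide bond between residue i-1 and i
    if (!has(bc$C, i - 1) || !has(bc$N, i)) return(FALSE)
    sqrt(sum((bc$C[i - 1, ] - bc$N[i, ])^2)) <= break_cutoff
  }
  safe_dihedral <- function(p1, p2, p3, p4) {
    tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NA_real_)
  }
  for (i in seq_len(n)) {
    if (connected(i) && has(bc$CA, i) && has(bc$C, i)) {
      phi[i] <- safe_dihedral(bc$C[i - 1, ], bc$N[i, ], bc$CA[i, ], bc$C[i, ])
    }
    if (connected(i) && has(bc$CA, i - 1)) {
      omega[i] <- safe_dihedral(bc$CA[i - 1, ], bc$C[i - 1, ],
                                bc$N[i, ], bc$CA[i, ])
    }
    if (connected(i + 1) && has(bc$N, i) && has(bc$CA, i) && has(bc$C, i)) {
      psi[i] <- safe_dihedral(bc$N[i, ], bc$CA[i, ], bc$C[i, ], bc$N[i + 1, ])
    }
  }
  data.frame(resno = bc$res$resno, insert = bc$res$insert,
             resid = bc$res$resid, phi = phi, psi = psi, omega = omega,
             omega_class = classify_omega(omega, trans_thresh, cis_thresh),
             stringsAsFactors = FALSE)
}

#' Count non-planar peptide bonds in a chain
#'
#' Number of defined omega angles classified trans-non-planar or
#' cis-non-planar under the configured thresholds.
#'
#' @inheritParams backbone_torsions
#' @return integer count.
#' @export
count_nonplanar <- function(structure, chain_id = structure_chains(structure)[1],
                            trans_thresh = 170, cis_thresh = 20,
                            break_cutoff = 2.5) {
  tor <- backbone_torsions(structure, chain_id, break_cutoff = break_cutoff,
                           trans_thresh = trans_thresh,
                           cis_thresh = cis_thresh)
  sum(tor$omega_class %in% c("trans_nonplanar", "cis_nonplanar"))
}

#' Flanking-residue composition of non-planar peptide bonds
#'
#' For every non-planar peptide bond, counts the residue type on each side:
#' \code{omega_a} is the residue before the bond (contributing C=O),
#' \code{omega_b} the residue after it (contributing N).  Both flanks of an
#' internal bond always exist; the counts per flank therefore sum to the
#' number of non-planar bonds.
#'
#' @inheritParams backbone_torsions
#' @return data.frame with columns \code{resid}, \code{omega_a},
#'   \code{omega_b} (counts); empty when there is no non-planar bond.
#' @export
flank_composition <- function(structure, chain_id = structure_chains(structure)[1],
                              trans_thresh = 170, cis_thresh = 20,
                              break_cutoff = 2.5) {
  tor <- backbone_torsions(structure, chain_id, break_cutoff = break_cutoff,
                           trans_thresh = trans_thresh,
                           cis_thresh = cis_thresh)
  np <- which(tor$omega_class %in% c("trans_nonplanar", "cis_nonplanar"))
  empty <- data.frame(resid = character(0), omega_a = integer(0),
                      omega_b = integer(0), stringsAsFactors = FALSE)
  if (length(np) == 0) return(empty)
  # bond preceding residue i: omega_a = residue i-1, omega_b = residue i
  before <- tor$resid[np - 1]
  after <- tor$resid[np]
  types <- sort(unique(c(before, after)))
  data.frame(resid = types,
             omega_a = as.integer(table(factor(before, levels = types))),
             omega_b = as.integer(table(factor(after, levels = types))),
             stringsAsFactors = FALSE)
}

#' Default Ramachandran region rectangles
#'
#' Non-overlapping phi/psi rectangles for the core beta-sheet, right-handed
#' helix and left-handed helix regions; everything else is \code{other}.
#'
#' @return data.frame with columns \code{label}, \code{phi_min},
#'   \code{phi_max}, \code{psi_min}, \code{psi_max} (degrees).
#' @export
default_rama_regions <- function() {
  data.frame(
    label = c("beta", "alpha_R", "alpha_L"),
    phi_min = c(-180, -145, 35),
    phi_max = c(-45, -35, 100),
    psi_min = c(90, -70, -20),
    psi_max = c(180, -10, 90),
    stringsAsFactors = FALSE)
}

#' Assign phi/psi pairs to Ramachandran regions
#'
#' @param phi,psi angles in degrees (vectors of equal length; NA allowed).
#' @param regions region rectangles, see \code{\link{default_rama_regions}}.
#' @return character vector of region labels (\code{other} outside every
#'   rectangle, \code{NA} for undefined angles).
#' @export
ramachandran_classify <- function(phi, psi, regions = default_rama_regions()) {
  out <- rep(NA_character_, length(phi))
  for (k in seq_along(phi)) {
    if (is.na(phi[k]) || is.na(psi[k])) next
    hit <- which(phi[k] >= regions$phi_min & phi[k] <= regions$phi_max &
                 psi[k] >= regions$psi_min & psi[k] <= regions$psi_max)
    out[k] <- if (length(hit) > 0) regions$label[hit[1]] else "other"
  }
  out
}

SALT_ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SALT_BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
SALT_HIS_ATOMS <- list(HIS = c("ND1", "NE2"))

#' Detect salt bridges by side-chain oxygen-nitrogen distance
#'
#' A salt bridge is an (acidic residue, basic residue) pair with at least
#' one side-chain O-N contact at or below the cutoff: acidic oxygens are
#' Asp OD1/OD2 and Glu OE1/OE2; basic nitrogens are Lys NZ and
#' Arg NE/NH1/NH2, plus His ND1/NE2 when \code{include_his = TRUE}.  Each
#' residue pair is reported once, with its closest atom pair.
#'
#' @param structure a \code{protein_structure}.
#' @param cutoff maximum O-N distance in Angstrom (default 3.2).
#' @param include_his treat histidine as basic (default FALSE).
#' @return data.frame with one row per bridge: chain/resno/resid of the
#'   acidic and basic residues, the contact atom names and the distance.
#' @export
find_salt_bridges <- function(structure, cutoff = 3.2, include_his = FALSE) {
  at <- structure$atoms
  basic_atoms <- SALT_BASIC_ATOMS
  if (include_his) basic_atoms <- c(basic_atoms, SALT_HIS_ATOMS)
  pick <- function(spec) {
    sel <- rep(FALSE, nrow(at))
    for (resname in names(spec)) {
      sel <- sel | (at$resid == resname & at$elety %in% spec[[resname]])
    }
    at[sel, , drop = FALSE]
  }
  ox <- pick(SALT_ACIDIC_ATOMS)
  ni <- pick(basic_atoms)
  empty <- data.frame(chain_acid = character(0), resno_acid = integer(0),
                      resid_acid = character(0), chain_base = character(0),
                      resno_base = integer(0), resid_base = character(0),
                      atom_acid = character(0), atom_base = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(ox) == 0 || nrow(ni) == 0) return(empty)
  dmat <- sqrt(outer(ox$x, ni$x, "-")^2 + outer(ox$y, ni$y, "-")^2 +
               outer(ox$z, ni$z, "-")^2)
  hits <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  cand <- data.frame(
    chain_acid = ox$chain[hits[, 1]], resno_acid = ox$resno[hits[, 1]],
    insert_acid = ox$insert[hits[, 1]], resid_acid = ox$resid[hits[, 1]],
    chain_base = ni$chain[hits[, 2]], resno_base = ni$resno[hits[, 2]],
    insert_base = ni$insert[hits[, 2]], resid_base = ni$resid[hits[, 2]],
    atom_acid = ox$elety[hits[, 1]], atom_base = ni$elety[hits[, 2]],
    distance = dmat[hits], stringsAsFactors = FALSE)
  # one bridge per residue pair: keep the closest contact
  key <- paste(cand$chain_acid, cand$resno_acid, cand$insert_acid,
               cand$chain_base, cand$resno_base, cand$insert_base)
  cand <- cand[order(key, cand$distance), , drop = FALSE]
  out <- cand[!duplicated(paste(cand$chain_acid, cand$resno_acid,
                                cand$insert_acid, cand$chain_base,
                                cand$resno_base, cand$insert_base)), ,
              drop = FALSE]
  out$insert_acid <- NULL
  out$insert_base <- NULL
  rownames(out) <- NULL
  out
}
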