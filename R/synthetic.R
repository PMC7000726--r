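# Swiss-Prot-style average residue frequencies (percent), used as the
# mesophile baseline composition.
BASELINE_FREQ <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.46, C = 1.38, Q = 3.93, E = 6.72,
  G = 7.08, H = 2.27, I = 5.91, L = 9.65, K = 5.80, M = 2.41, F = 3.86,
  P = 4.74, S = 6.65, T = 5.36, W = 1.10, Y = 2.92, V = 6.86)

#' Construct a sequence-group composition profile
#'
#' A group profile is a name, a per-residue sampling probability vector and
#' a length distribution; sequences are drawn i.i.d. from the probabilities.
#'
#' @param name group label.
#' @param probs named numeric over the 20 residues; normalized to sum to 1.
#' @param mean_length,sd_length,min_length length model (residues).
#' @return object of class \code{group_profile}.
#' @export
group_profile <- function(name, probs, mean_length = 250, sd_length = 25,
                          min_length = 50) {
  stopifnot(setequal(names(probs), aa_alphabet()), all(probs >= 0),
            sum(probs) > 0)
  probs <- probs[aa_alphabet()] / sum(probs)
  structure(list(name = name, probs = probs, mean_length = mean_length,
                 sd_length = sd_length, min_length = min_length),
            class = "group_profile")
}

#' Baseline (mesophile-like) composition profile
#'
#' Average residue frequencies of well-characterized globular proteins.
#'
#' @inheritParams group_profile
#' @return a \code{\link{group_profile}}.
#' @export
mesophile_profile <- function(mean_length = 250, sd_length = 25) {
  group_profile("mesophile", BASELINE_FREQ / 100,
                mean_length = mean_length, sd_length = sd_length)
}

#' Extremophile-biased composition profile
#'
#' Shifts the baseline toward the small nonpolar residues favoured by
#' extremostable proteins: G, A, V, I are scaled up to a combined mass of
#' \code{gavi_mass} (default 0.40), Q, H, M, C are halved, and the
#' remaining residues are rescaled so the probabilities sum to 1.
#'
#' @param gavi_mass combined probability of G+A+V+I (default 0.40).
#' @inheritParams group_profile
#' @return a \code{\link{group_profile}}.
#' @export
extremophile_profile <- function(gavi_mass = 0.40, mean_length = 250,
                                 sd_length = 25) {
  p <- BASELINE_FREQ / 100
  up <- c("G", "A", "V", "I")
  down <- c("Q", "H", "M", "C")
  rest <- setdiff(names(p), c(up, down))
  p[up] <- p[up] * gavi_mass / sum(p[up])
  p[down] <- p[down] / 2
  p[rest] <- p[rest] * (1 - gavi_mass - sum(p[down])) / sum(p[rest])
  group_profile("extremophile", p, mean_length = mean_length,
                sd_length = sd_length)
}

#' Shift one residue's probability in a profile
#'
#' Adds \code{delta} (probability mass, e.g. 0.05 for +5 percentage points)
#' to one residue and rescales the others, for planting known composition
#' differences.
#'
#' @param profile a \code{\link{group_profile}}.
#' @param residue one-letter code.
#' @param delta probability mass to add (may be negative).
#' @return a new \code{\link{group_profile}}.
#' @export
shift_profile <- function(profile, residue, delta) {
  p <- profile$probs
  stopifnot(residue %in% names(p))
  target <- p[[residue]] + delta
  stopifnot(target >= 0, target <= 1)
  others <- setdiff(names(p), residue)
  p[others] <- p[others] * (1 - target) / sum(p[others])
  p[[residue]] <- target
  group_profile(paste0(profile$name, "_", residue,
                       sprintf("%+.0f%%", 100 * delta)),
                p, profile$mean_length, profile$sd_length,
                profile$min_length)
}

#' Sample synthetic protein sequences from a group profile
#'
#' Lengths are drawn from a rounded normal (truncated at
#' \code{min_length}); residues are drawn i.i.d. from the profile's
#' probabilities.  Reproducible for a fixed seed.
#'
#' @param profile a \code{\link{group_profile}}.
#' @param n number of sequences.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return list of \code{n} \code{\link{protein_record}} objects with ids
#'   \code{"<group>_<k>"}.
#' @export
sample_sequences <- function(profile, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(k) {
    len <- max(profile$min_length,
               round(stats::rnorm(1, profile$mean_length, profile$sd_length)))
    protein_record(paste0(profile$name, "_", k),
                   paste(sample(names(profile$probs), len, replace = TRUE,
                                prob = profile$probs), collapse = ""),
                   description = profile$name)
  })
}

# idealized backbone internal coordinates (Angstrom, degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

AA_123 <- c(stats::setNames(names(AA_321)[1:20], AA_321[1:20]), X = "UNK")

#' Specify a synthetic backbone by its torsion angles
#'
#' @param sequence one-letter sequence (string or character vector).
#' @param phi,psi,omega per-residue torsions in degrees, recycled to the
#'   sequence length.  \code{phi[1]} and \code{omega[1]} (no preceding
#'   residue) and \code{psi[n]} (no following residue) are ignored.
#' @return object of class \code{backbone_spec}.
#' @export
backbone_spec <- function(sequence, phi = -57, psi = -47, omega = 180) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  }
  n <- length(sequence)
  stopifnot(n >= 2, all(sequence %in% aa_alphabet(with_x = TRUE)))
  expand <- function(v, what) {
    if (length(v) == 1) v <- rep(v, n)
    if (length(v) != n) {
      stop("backbone_spec: ", what, " must have length 1 or ", n)
    }
    v
  }
  structure(list(sequence = sequence,
                 phi = expand(phi, "phi"), psi = expand(psi, "psi"),
                 omega = expand(omega, "omega")),
            class = "backbone_spec")
}

# natural-extension-reference-frame placement: position of the next atom at
# the given bond length, bond angle (with b-c) and torsion (about b-c, seen
# from a), consistent with dihedral_angle(a, b, c, new) == torsion.
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(theta), bond * sin(theta) * cos(chi),
         bond * sin(theta) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a backbone structure from torsion targets
#'
#' Places N, CA, C atoms sequentially from ideal internal coordinates
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; angles 111.2, 116.2,
#' 121.7 degrees) so that the measured phi/psi/omega torsions reproduce the
#' spec's targets to numerical precision.
#'
#' @param spec a \code{\link{backbone_spec}}.
#' @param id structure identifier.
#' @param chain_id chain identifier.
#' @return a \code{\link{protein_structure}} with three backbone atoms per
#'   residue.
#' @export
build_backbone <- function(spec, id = "synthetic", chain_id = "A") {
  n <- length(spec$sequence)
  coords <- matrix(NA_real_, 3 * n, 3)
  # residue 1 in a canonical frame
  coords[1, ] <- c(0, 0, 0)                       # N1
  coords[2, ] <- c(BOND_N_CA, 0, 0)               # CA1
  theta <- ANGLE_N_CA_C * pi / 180
  coords[3, ] <- coords[2, ] +
    BOND_CA_C * c(-cos(theta), sin(theta), 0)     # C1
  idx <- function(i, atom) 3 * (i - 1) + match(atom, c("N", "CA", "C"))
  for (i in seq_len(n - 1)) {
    coords[idx(i + 1, "N"), ] <- nerf_place(
      coords[idx(i, "N"), ], coords[idx(i, "CA"), ], coords[idx(i, "C"), ],
      BOND_C_N, ANGLE_CA_C_N, spec$psi[i])
    coords[idx(i + 1, "CA"), ] <- nerf_place(
      coords[idx(i, "CA"), ], coords[idx(i, "C"), ],
      coords[idx(i + 1, "N"), ],
      BOND_N_CA, ANGLE_C_N_CA, spec$omega[i + 1])
    coords[idx(i + 1, "C"), ] <- nerf_place(
      coords[idx(i, "C"), ], coords[idx(i + 1, "N"), ],
      coords[idx(i + 1, "CA"), ],
      BOND_CA_C, ANGLE_N_CA_C, spec$phi[i + 1])
  }
  atoms <- data.frame(
    chain = chain_id,
    resno = rep(seq_len(n), each = 3),
    insert = "",
    resid = rep(unname(AA_123[spec$sequence]), each = 3),
    elety = rep(c("N", "CA", "C"), n),
    elesy = rep(c("N", "C", "C"), n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = 1, stringsAsFactors = FALSE)
  protein_structure(id, atoms)
}

#' Plant a pseudo salt bridge into a structure
#'
#' Renames the two residues to Asp and Lys and adds a side-chain OD1/NZ
#' atom pair at exactly the requested separation, on the line between the
#' two CA atoms, for testing salt-bridge detection.
#'
#' @param structure a \code{\link{protein_structure}}.
#' @param acidic_at,basic_at residue sequence numbers (resno) in
#'   \code{chain_id}.
#' @param distance O-N separation in Angstrom (> 0).
#' @param chain_id chain holding both residues.
#' @return a new \code{\link{protein_structure}}.
#' @export
plant_salt_bridge <- function(structure, acidic_at, basic_at, distance = 3.0,
                              chain_id = structure_chains(structure)[1]) {
  stopifnot(distance > 0)
  at <- structure$atoms
  sel_a <- at$chain == chain_id & at$resno == acidic_at
  sel_b <- at$chain == chain_id & at$resno == basic_at
  if (!any(sel_a) || !any(sel_b)) {
    stop("plant_salt_bridge: residue not found in chain ", chain_id)
  }
  ca_a <- unlist(at[sel_a & at$elety == "CA", c("x", "y", "z")])
  ca_b <- unlist(at[sel_b & at$elety == "CA", c("x", "y", "z")])
  u <- ca_b - ca_a
  len <- sqrt(sum(u^2))
  if (len < 1e-6) stop("plant_salt_bridge: CA atoms coincide, cannot place")
  u <- u / len
  o_pos <- ca_a + 1.5 * u
  n_pos <- o_pos + distance * u
  at$resid[sel_a] <- "ASP"
  at$resid[sel_b] <- "LYS"
  extra <- data.frame(
    chain = chain_id, resno = c(acidic_at, basic_at), insert = "",
    resid = c("ASP", "LYS"), elety = c("OD1", "NZ"), elesy = c("O", "N"),
    x = c(o_pos[1], n_pos[1]), y = c(o_pos[2], n_pos[2]),
    z = c(o_pos[3], n_pos[3]), o = 1, stringsAsFactors = FALSE)
  protein_structure(structure$id, rbind(at, extra), structure$resolution)
}

# random proper rotation from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a rigid transform to every atom of a structure
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
  at$x <- xyz[, 1] + translation[1]
  at$y <- xyz[, 2] + translation[2]
  at$z <- xyz[, 3] + translation[3]
  protein_structure(structure$id, at, structure$resolution)
}

#' Generate a benchmark structure pair with a known expected RMSD
#'
#' Builds a helical backbone from a random sequence, then creates a second
#' copy under a random rigid transform with isotropic Gaussian coordinate
#' noise of standard deviation \code{rmsd_target / sqrt(3)} per axis, so
#' the expected RMSD after optimal superposition is approximately
#' \code{rmsd_target}.
#'
#' @param seed integer seed.
#' @param rmsd_target expected post-fit RMSD in Angstrom (>= 0).
#' @param n_residues backbone length.
#' @return list with \code{a} and \code{b} (\code{protein_structure}) and
#'   \code{record} (the shared \code{\link{protein_record}}).
#' @export
make_benchmark_pair <- function(seed, rmsd_target = 1.0, n_residues = 200) {
  stopifnot(rmsd_target >= 0)
  set.seed(seed)
  rec <- sample_sequences(group_profile("bench", BASELINE_FREQ / 100,
                                        mean_length = n_residues,
                                        sd_length = 0,
                                        min_length = n_residues),
                          1)[[1]]
  # helix with mild torsion jitter so the trace is well conditioned
  n <- nchar(rec$sequence)
  spec <- backbone_spec(rec$sequence,
                        phi = -57 + stats::rnorm(n, 0, 5),
                        psi = -47 + stats::rnorm(n, 0, 5),
                        omega = 180)
  a <- build_backbone(spec, id = "bench_a")
  b <- a
  b$id <- "bench_b"
  sigma <- rmsd_target / sqrt(3)
  if (sigma > 0) {
    nat <- nrow(b$atoms)
    b$atoms$x <- b$atoms$x + stats::rnorm(nat, 0, sigma)
    b$atoms$y <- b$atoms$y + stats::rnorm(nat, 0, sigma)
    b$atoms$z <- b$atoms$z + stats::rnorm(nat, 0, sigma)
  }
  b <- transform_structure(b, random_rotation(), stats::rnorm(3, 0, 20))
  list(a = a, b = b, record = rec)
}

#' Generate a synthetic ortholog pair with planted identity and RMSD
#'
#' Sequence B is a point-mutated copy of sequence A (substitution rate
#' \code{mutation_rate}); both structures share the same backbone torsions,
#' with coordinate noise planting the requested superposition RMSD.
#' Useful for planting known identity-versus-RMSD trends.
#'
#' @param seed integer seed.
#' @param mutation_rate expected fraction of substituted positions.
#' @param rmsd_target expected post-fit RMSD in Angstrom.
#' @param n_residues sequence/backbone length.
#' @return list with \code{record_a}, \code{record_b},
#'   \code{structure_a}, \code{structure_b}.
#' @export
make_ortholog_pair <- function(seed, mutation_rate = 0.3, rmsd_target = 1.0,
                               n_residues = 120) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  bench <- make_benchmark_pair(seed, rmsd_target, n_residues)
  chars <- seq_chars(bench$record)
  mutate <- which(stats::runif(length(chars)) < mutation_rate)
  for (i in mutate) {
    chars[i] <- sample(setdiff(aa_alphabet(), chars[i]), 1)
  }
  rec_b <- protein_record("ortho_b", paste(chars, collapse = ""))
  rec_a <- protein_record("ortho_a", bench$record$sequence)
  swap_sequence <- function(structure, chars1) {
    at <- structure$atoms
    at$resid <- rep(unname(AA_123[chars1]), each = 3)
    protein_structure(structure$id, at, structure$resolution)
  }
  list(record_a = rec_a, record_b = rec_b,
       structure_a = swap_sequence(bench$a, seq_chars(rec_a)),
       structure_b = swap_sequence(bench$b, seq_chars(rec_b)))
}
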