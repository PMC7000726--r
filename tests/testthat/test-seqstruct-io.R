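make_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("FASTA reading uppercases, keeps file order and rejects bad letters", {
  one <- read_fasta(make_fasta(c(">p1", "acde")))
  expect_length(one, 1)
  expect_equal(one[[1]]$sequence, "ACDE")
  expect_equal(nchar(one[[1]]$sequence), 4)

  two <- read_fasta(make_fasta(c(">b first", "AAAA", ">a second", "CCDD")))
  expect_equal(vapply(two, function(r) r$id, character(1)), c("b", "a"))
  expect_equal(two[[2]]$description, "second")

  expect_error(read_fasta(make_fasta(c(">p1", "AC1E"))), "disallowed")
  empty <- make_fasta(character(0))
  expect_equal(read_fasta(empty), list())
  expect_error(read_fasta(make_fasta(c("ACDE"))), "header")
})

test_that("FASTA round trip preserves records", {
  recs <- list(protein_record("a", "ACDEFGHIKLMNPQRSTVWY", "desc one"),
               protein_record("b", strrep("GAVI", 40)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(vapply(back, function(r) r$id, character(1)), c("a", "b"))
  expect_equal(back[[1]]$sequence, recs[[1]]$sequence)
  expect_equal(back[[2]]$sequence, recs[[2]]$sequence)
})

minimal_pdb <- function() {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(c(
    "REMARK   2 RESOLUTION.    1.10 ANGSTROMS.",
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       2.500   2.200   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.900   2.500   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       4.500   3.900   0.100  1.00  0.00           C",
    "HETATM    8 SE   MSE A   3       5.000   5.000   0.000  1.00  0.00          SE",
    "HETATM    9  O   HOH A  99       9.000   9.000   9.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM     10  N   ALA A   1       7.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL",
    "END"), path)
  path
}

test_that("PDB reading keeps first model, best altLoc and drops waters", {
  st <- read_pdb(minimal_pdb())
  expect_equal(structure_chains(st), "A")
  res <- chain_residues(st, "A")
  expect_equal(nrow(res), 3)
  expect_equal(res$resid, c("ALA", "GLY", "MSE"))
  # altLoc B (occupancy 0.6) wins over A (0.4)
  ca1 <- st$atoms[st$atoms$resno == 1 & st$atoms$elety == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 1.5)
  # second MODEL dropped: residue 1 N comes from model 1
  n1 <- st$atoms[st$atoms$resno == 1 & st$atoms$elety == "N", ]
  expect_equal(n1$x, 0)
  expect_false(any(st$atoms$resid == "HOH"))
  expect_equal(st$resolution, 1.1)
})

test_that("PDB reading fails cleanly without ATOM records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), path)
  expect_error(read_pdb(path), "ATOM")
})

test_that("chain_sequence maps three-letter codes, MSE and unknowns", {
  st <- read_pdb(minimal_pdb())
  rec <- chain_sequence(st, "A")
  expect_equal(rec$sequence, "AGM")
  expect_equal(nchar(rec$sequence), nrow(chain_residues(st, "A")))
  expect_error(chain_sequence(st, "Z"), "not found")

  # unknown residue inside a chain becomes X
  at <- st$atoms
  at$resid[at$resno == 2] <- "LIG"
  st2 <- protein_structure("mod", at)
  expect_equal(chain_sequence(st2, "A")$sequence, "AXM")
})

test_that("structures survive a PDB write/read round trip to 1e-3 A", {
  set.seed(7)
  spec <- backbone_spec(random_sequence(25),
                        phi = runif(25, -170, -40),
                        psi = runif(25, -60, 170),
                        omega = sample(c(180, 175, -170, 160), 25, TRUE))
  st <- build_backbone(spec, id = "rt")
  st <- plant_salt_bridge(st, 3, 20, 3.0)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(back$atoms$resid, st$atoms$resid)
  expect_equal(back$atoms$elety, st$atoms$elety)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(st$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  expect_equal(chain_sequence(back)$sequence, chain_sequence(st)$sequence)
})
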