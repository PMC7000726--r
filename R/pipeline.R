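#' Pipeline configuration with documented defaults
#'
#' Single container for every tunable threshold of the comparison pipeline.
#'
#' @param gap_open,gap_extend,end_gaps_free alignment parameters
#'   (see \code{\link{needleman_wunsch}}).
#' @param refine,cycles,reject_cutoff superposition parameters
#'   (see \code{\link{refine_superposition}}).
#' @param salt_cutoff,include_his salt-bridge parameters
#'   (see \code{\link{find_salt_bridges}}).
#' @param trans_thresh,cis_thresh omega planarity thresholds
#'   (see \code{\link{classify_omega}}).
#' @param resolution_max structural stages run only for structures at or
#'   below this resolution in Angstrom (\code{NA} = no filter).
#' @param report_pH pH for the reported net charge.
#' @param pka,classes physicochemical tables (see \code{\link{default_pka}},
#'   \code{\link{default_residue_classes}}).
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(gap_open = 10, gap_extend = 0.5,
                            end_gaps_free = TRUE,
                            refine = TRUE, cycles = 5, reject_cutoff = 2.0,
                            salt_cutoff = 3.2, include_his = FALSE,
                            trans_thresh = 170, cis_thresh = 20,
                            resolution_max = NA_real_, report_pH = 7,
                            pka = default_pka(),
                            classes = default_residue_classes()) {
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 end_gaps_free = end_gaps_free, refine = refine,
                 cycles = cycles, reject_cutoff = reject_cutoff,
                 salt_cutoff = salt_cutoff, include_his = include_his,
                 trans_thresh = trans_thresh, cis_thresh = cis_thresh,
                 resolution_max = resolution_max, report_pH = report_pH,
                 pka = pka, classes = classes),
            class = "pipeline_config")
}

MANIFEST_OPTIONAL <- c("fasta_a", "fasta_b", "pdb_a", "pdb_b",
                       "chain_a", "chain_b")

#' Read a tab-separated ortholog-pair manifest
#'
#' Required columns: \code{category}, \code{id_a}, \code{id_b}.  Optional
#' columns (\code{fasta_a/b}, \code{pdb_a/b}, \code{chain_a/b}) are filled
#' with \code{NA} when absent.
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame with one row per ortholog pair.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("category", "id_a", "id_b")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("read_manifest: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in MANIFEST_OPTIONAL) {
    if (!col %in% names(m)) m[[col]] <- NA_character_
    m[[col]][!is.na(m[[col]]) & !nzchar(m[[col]])] <- NA_character_
  }
  m
}

# load the analyzed record and (optionally) structure for one side of a
# manifest row; ATOM-derived sequence is the alignment source whenever a
# structure is present
load_side <- function(id, fasta_path, pdb_path, chain_id) {
  st <- NULL
  if (!is.na(pdb_path)) {
    st <- read_pdb(pdb_path, id = id)
    if (is.na(chain_id)) chain_id <- structure_chains(st)[1]
    rec <- chain_sequence(st, chain_id)
    rec$id <- id
  } else if (!is.na(fasta_path)) {
    recs <- read_fasta(fasta_path)
    if (length(recs) == 0) stop("empty FASTA: ", fasta_path)
    rec <- recs[[1]]
    rec$id <- id
    chain_id <- NA_character_
  } else {
    stop("no sequence input for ", id)
  }
  list(record = rec, structure = st, chain = chain_id)
}

#' Run the full comparison for one ortholog pair
#'
#' Always computes composition, physicochemical descriptors and the global
#' alignment; when both sides have structures (and pass the resolution
#' filter), also the refined superposition RMSD, per-side salt-bridge
#' counts and non-planar peptide-bond counts.
#'
#' @param row one manifest row (list or one-row data.frame) with the
#'   columns of \code{\link{read_manifest}}; alternatively pre-loaded
#'   objects can be supplied via \code{side_a}/\code{side_b}.
#' @param config a \code{\link{pipeline_config}}.
#' @param side_a,side_b optional pre-loaded sides, each a list with
#'   \code{record} (\code{protein_record}), \code{structure}
#'   (\code{protein_structure} or \code{NULL}) and \code{chain}.
#' @return one-row data.frame; structural fields are \code{NA} with
#'   \code{structural_stage} saying why when structures are absent or
#'   filtered out.
#' @export
run_pair <- function(row, config = pipeline_config(),
                     side_a = NULL, side_b = NULL) {
  row <- as.list(row)
  if (is.null(side_a)) {
    side_a <- load_side(row$id_a, row$fasta_a, row$pdb_a, row$chain_a)
  }
  if (is.null(side_b)) {
    side_b <- load_side(row$id_b, row$fasta_b, row$pdb_b, row$chain_b)
  }
  pa <- physchem_profile(side_a$record, config$pka, config$classes,
                         config$report_pH)
  pb <- physchem_profile(side_b$record, config$pka, config$classes,
                         config$report_pH)
  aln <- needleman_wunsch(side_a$record, side_b$record,
                          gap_open = config$gap_open,
                          gap_extend = config$gap_extend,
                          end_gaps_free = config$end_gaps_free)
  out <- data.frame(
    category = row$category, id_a = row$id_a, id_b = row$id_b,
    length_a = pa$length, length_b = pb$length,
    pI_a = pa$pI, pI_b = pb$pI,
    net_charge_a = pa$net_charge, net_charge_b = pb$net_charge,
    hydrophobic_pct_a = pa$hydrophobic_pct,
    hydrophobic_pct_b = pb$hydrophobic_pct,
    polar_pct_a = pa$polar_pct, polar_pct_b = pb$polar_pct,
    identity_pct = aln$identity_pct, similarity_pct = aln$similarity_pct,
    gaps_pct = aln$gaps_pct, score = aln$score,
    rmsd = NA_real_, n_used = NA_integer_, n_rejected = NA_integer_,
    salt_bridges_a = NA_integer_, salt_bridges_b = NA_integer_,
    nonplanar_a = NA_integer_, nonplanar_b = NA_integer_,
    structural_stage = "absent", stringsAsFactors = FALSE)
  both <- !is.null(side_a$structure) && !is.null(side_b$structure)
  if (both && !is.na(config$resolution_max)) {
    res <- c(side_a$structure$resolution, side_b$structure$resolution)
    if (any(is.na(res)) || any(res > config$resolution_max)) {
      out$structural_stage <- "resolution_filtered"
      both <- FALSE
    }
  }
  if (both) {
    pairs <- pair_ca_atoms(aln, side_a$structure, side_b$structure,
                           side_a$chain, side_b$chain)
    fit <- if (config$refine) {
      refine_superposition(pairs, config$cycles, config$reject_cutoff)
    } else {
      kabsch(pairs)
    }
    out$rmsd <- fit$rmsd
    out$n_used <- fit$n_used
    out$n_rejected <- fit$n_rejected
    out$salt_bridges_a <- nrow(find_salt_bridges(
      side_a$structure, config$salt_cutoff, config$include_his))
    out$salt_bridges_b <- nrow(find_salt_bridges(
      side_b$structure, config$salt_cutoff, config$include_his))
    out$nonplanar_a <- count_nonplanar(
      side_a$structure, side_a$chain,
      config$trans_thresh, config$cis_thresh)
    out$nonplanar_b <- count_nonplanar(
      side_b$structure, side_b$chain,
      config$trans_thresh, config$cis_thresh)
    out$structural_stage <- "done"
  }
  out
}

#' Run the group-level comparison over a whole manifest
#'
#' Processes every manifest row (unreadable rows are skipped with a logged
#' reason), then aggregates: per-category and overall descriptor t-tests
#' between the extremostable (a) and counterpart (b) sides, per-category
#' Pearson correlation of alignment identity with RMSD, and the binned
#' occurrence distributions of both sides.
#'
#' @param manifest data.frame from \code{\link{read_manifest}} (or rows in
#'   the same shape).
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{comparison_report}: list with
#'   \code{pairs}, \code{skipped}, \code{descriptor_tests},
#'   \code{correlations}, \code{occurrence_a}, \code{occurrence_b}.
#' @export
run_group_analysis <- function(manifest, config = pipeline_config()) {
  stopifnot(nrow(manifest) >= 1)
  records <- list()
  comps_a <- list()
  comps_b <- list()
  skipped <- data.frame(id_a = character(0), id_b = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    rec <- tryCatch({
      side_a <- load_side(row$id_a, row$fasta_a, row$pdb_a, row$chain_a)
      side_b <- load_side(row$id_b, row$fasta_b, row$pdb_b, row$chain_b)
      comps_a[[length(comps_a) + 1]] <- composition_percent(side_a$record)
      comps_b[[length(comps_b) + 1]] <- composition_percent(side_b$record)
      run_pair(row, config, side_a, side_b)
    }, error = function(e) {
      skipped[nrow(skipped) + 1, ] <<- list(row$id_a, row$id_b,
                                            conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1]] <- rec
  }
  if (length(records) == 0) {
    stop("run_group_analysis: no valid manifest rows")
  }
  pairs <- do.call(rbind, records)
  rownames(pairs) <- NULL

  descriptors <- c("pI", "net_charge", "hydrophobic_pct", "polar_pct")
  test_block <- function(sub, label) {
    if (nrow(sub) < 2) return(NULL)
    do.call(rbind, lapply(descriptors, function(d) {
      cmp <- t_test(sub[[paste0(d, "_a")]], sub[[paste0(d, "_b")]],
                    parameter = d)
      data.frame(category = label, parameter = d, mean_a = cmp$mean_a,
                 mean_b = cmp$mean_b, t = cmp$t, df = cmp$df, p = cmp$p,
                 stringsAsFactors = FALSE)
    }))
  }
  blocks <- c(lapply(unique(pairs$category),
                     function(cc) test_block(pairs[pairs$category == cc, ], cc)),
              list(test_block(pairs, "all")))
  descriptor_tests <- do.call(rbind, blocks[!vapply(blocks, is.null, TRUE)])
  if (!is.null(descriptor_tests)) rownames(descriptor_tests) <- NULL

  correlations <- suppressWarnings(category_correlations(pairs))

  structure(list(pairs = pairs, skipped = skipped,
                 descriptor_tests = descriptor_tests,
                 correlations = correlations,
                 occurrence_a = bin_occurrences(comps_a),
                 occurrence_b = bin_occurrences(comps_b)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", nrow(x$pairs), " pair(s), ",
      nrow(x$skipped), " skipped\n", sep = "")
  if (nrow(x$correlations) > 0) {
    cat("  identity-RMSD correlations:\n")
    for (k in seq_len(nrow(x$correlations))) {
      cat(sprintf("    %-14s n=%-3d r=%+.3f\n", x$correlations$category[k],
                  x$correlations$n[k], x$correlations$r[k]))
    }
  }
  invisible(x)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as JSON
#'
#' Serializes the per-pair table, skip log, descriptor tests, correlations
#' and occurrence-distribution counts.  Byte-identical for identical inputs.
#'
#' @param report a \code{comparison_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    pairs = report$pairs,
    skipped = report$skipped,
    descriptor_tests = report$descriptor_tests,
    correlations = report$correlations,
    occurrence_a = report$occurrence_a$counts,
    occurrence_b = report$occurrence_b$counts)
  jsonlite::write_json(payload, path, digits = 10, auto_unbox = TRUE)
  invisible(path)
}
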