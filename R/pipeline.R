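#' Build and validate a pipeline run configuration
#'
#' Collects every knob of the analysis in one validated list. Unknown
#' arguments are rejected. Inputs can be file paths (`fasta_a`/`fasta_b`) or
#' in-memory `coev_msa` objects (`msa_a`/`msa_b`, e.g. from
#' [simulate_paired_msa()]).
#'
#' @param ... configuration entries; see Details.
#' @details Recognised keys (defaults in parentheses):
#' `fasta_a`, `fasta_b`, `msa_a`, `msa_b`, `header_rule` ("ox"),
#' `anchor_a`, `anchor_b` ([anchor_rule()] or NULL),
#' `pairing` ("cross_product"), `theta` (0.8), `lambda` (NULL = 0.5 m_eff),
#' `methods` (c("mfdca", "sparse_l1", "mutual_information")),
#' `rho` (NULL = 0.01 mean|C|), `mi_lambda` (0),
#' `threshold_k_all` (7), `threshold_k_inter` (6), `min_sep` (5),
#' `top_n_consensus` (10), `pdb_path`/`z_table`/`chain_map`/`offsets`
#' (NULL), `max_dz` (15), `subset_k` (NULL = skip subsetting),
#' `subset_region` (NULL = full chain A), `restraint_top_n` (10),
#' `restraint_format` ("casp_rr"), `seed` (1), `out_dir` (NULL = no files).
#' @return a validated `run_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(fasta_a = NULL, fasta_b = NULL, msa_a = NULL, msa_b = NULL,
                   header_rule = "ox", anchor_a = NULL, anchor_b = NULL,
                   pairing = "cross_product", theta = 0.8, lambda = NULL,
                   methods = c("mfdca", "sparse_l1", "mutual_information"),
                   rho = NULL, mi_lambda = 0,
                   threshold_k_all = 7, threshold_k_inter = 6, min_sep = 5L,
                   top_n_consensus = 10L,
                   pdb_path = NULL, z_table = NULL, chain_map = NULL,
                   offsets = NULL, max_dz = 15,
                   subset_k = NULL, subset_region = NULL,
                   restraint_top_n = 10L, restraint_format = "casp_rr",
                   seed = 1L, out_dir = NULL)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  has_a <- !is.null(cfg$fasta_a) || !is.null(cfg$msa_a)
  has_b <- !is.null(cfg$fasta_b) || !is.null(cfg$msa_b)
  if (!has_a || !has_b)
    stop("both families must be supplied (fasta_a/msa_a and fasta_b/msa_b)",
         call. = FALSE)
  stopifnot(cfg$theta > 0, cfg$theta <= 1,
            all(cfg$methods %in% c("mfdca", "sparse_l1",
                                   "mutual_information")))
  structure(cfg, class = "run_config")
}

#' Run the full coevolution analysis
#'
#' Executes the stages in order: read/parse, anchor filter, pair, weight,
#' score (each selected method), precision, thresholds, contact
#' partitioning, membrane-topology filter and structural classification
#' (skipped without geometry), phylogenetic subsets and logos (skipped
#' unless `subset_k` is set), consensus, and restraint export. All
#' intermediates are written under `out_dir` when given; a machine-readable
#' run report is returned (and written as JSON).
#'
#' @param cfg a `run_config` from [pipeline_config()].
#' @return a `run_report` list: per-stage counts, thresholds, consensus
#'   size, stage status, and the config echo; the scored objects are
#'   attached in `$objects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  out <- !is.null(cfg$out_dir)
  if (out) dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), config = echo_config(cfg))
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           "\nstages completed: ",
           paste(names(report$stages), collapse = ", "), call. = FALSE)
    })
  }

  msa_a <- run_stage("read_a", {
    m <- if (!is.null(cfg$msa_a)) cfg$msa_a
         else read_alignment(cfg$fasta_a, "familyA")
    if (anyNA(m$organism_id)) m <- parse_organism_ids(m, cfg$header_rule)
    m
  })
  msa_b <- run_stage("read_b", {
    m <- if (!is.null(cfg$msa_b)) cfg$msa_b
         else read_alignment(cfg$fasta_b, "familyB")
    if (anyNA(m$organism_id)) m <- parse_organism_ids(m, cfg$header_rule)
    m
  })
  note("read", rows_a = length(msa_a$seq_id), rows_b = length(msa_b$seq_id))

  if (!is.null(cfg$anchor_a))
    msa_a <- run_stage("anchor_a", filter_by_anchor(msa_a, cfg$anchor_a))
  if (!is.null(cfg$anchor_b))
    msa_b <- run_stage("anchor_b", filter_by_anchor(msa_b, cfg$anchor_b))
  note("anchor_filter",
       dropped_a = sum(msa_a$provenance$dropped[
         msa_a$provenance$stage == "filter_by_anchor"]),
       dropped_b = sum(msa_b$provenance$dropped[
         msa_b$provenance$stage == "filter_by_anchor"]))

  paired <- run_stage("pair", pair_alignments(msa_a, msa_b,
                                              pairing = cfg$pairing))
  prov <- paired$provenance
  note("pair", rows = length(paired$residues),
       unpaired_a = prov$dropped[prov$stage == "pair_unpaired_a"],
       unpaired_b = prov$dropped[prov$stage == "pair_unpaired_b"],
       duplicates = prov$dropped[prov$stage == "pair_duplicates"])
  if (out) write_paired_msa(paired, file.path(cfg$out_dir, "paired.fasta"),
                            file.path(cfg$out_dir, "provenance.tsv"))

  wmsa <- run_stage("weight", compute_weights(paired, theta = cfg$theta))
  note("weight", m_eff = wmsa$m_eff, theta = cfg$theta)

  lambda <- if (is.null(cfg$lambda)) 0.5 * wmsa$m_eff else cfg$lambda
  freq <- run_stage("frequencies", compute_frequencies(wmsa, lambda = lambda))

  results <- list()
  for (m in cfg$methods) {
    results[[m]] <- run_stage(paste0("score_", m), switch(m,
      mfdca = score_mfdca(freq),
      sparse_l1 = score_sparse_l1(freq, rho = cfg$rho),
      mutual_information = score_mutual_information(wmsa,
                                                    lambda = cfg$mi_lambda)))
    results[[m]] <- estimate_precision(results[[m]])
  }
  note("score", methods = cfg$methods)

  thresholds <- lapply(results, function(r) {
    list(all = sd_threshold(r, cfg$threshold_k_all, "all_pairs"),
         inter = sd_threshold(r, cfg$threshold_k_inter,
                              "inter_subunit_only"))
  })
  note("threshold",
       values = lapply(thresholds, function(t)
         c(all = t$all$value, inter = t$inter$value)))

  contacts <- lapply(results, partition_contacts, min_sep = cfg$min_sep)
  note("partition",
       n_inter = vapply(contacts, function(x) nrow(x$inter), integer(1)),
       n_intra = vapply(contacts, function(x) nrow(x$intra), integer(1)))
  if (out) {
    for (m in names(results))
      write_contact_table(results[[m]],
                          file.path(cfg$out_dir,
                                    paste0("contacts_", m, ".tsv")),
                          threshold = thresholds[[m]]$inter,
                          min_sep = cfg$min_sep)
  }

  geom <- NULL
  if (!is.null(cfg$pdb_path) || !is.null(cfg$z_table)) {
    geom <- run_stage("geometry",
                      load_geometry(cfg$pdb_path, cfg$z_table,
                                    cfg$chain_map, cfg$offsets))
    filtered <- lapply(contacts, function(x)
      filter_membrane_normal(x$inter, geom, max_dz = cfg$max_dz))
    classified <- lapply(contacts, function(x)
      classify_structural_contacts(rbind(x$inter, x$intra), geom))
    note("topology",
         kept = vapply(filtered, function(f) sum(f$topology == "kept"),
                       integer(1)),
         removed = vapply(filtered,
                          function(f) sum(f$topology == "removed_topology"),
                          integer(1)))
    note("classify", labels = lapply(classified,
                                     function(cl) table(cl$label)))
    if (out) {
      for (m in names(classified))
        write.table(classified[[m]],
                    file.path(cfg$out_dir, paste0("classified_", m, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    filtered <- NULL; classified <- NULL
    note("topology", skipped = TRUE)
    note("classify", skipped = TRUE)
  }

  subsets <- NULL; logos <- NULL
  if (!is.null(cfg$subset_k)) {
    subsets <- run_stage("subsets", {
      region <- if (is.null(cfg$subset_region)) c(1L, msa_a$n_columns)
                else cfg$subset_region
      dm <- pairwise_distance_matrix(msa_a, region = region)
      tree <- build_tree(dm, "nj")
      partition_subsets(tree, "k_groups", k = cfg$subset_k,
                        organism_ids = setNames(msa_a$organism_id,
                                                msa_a$seq_id))
    })
    logos <- lapply(subsets$subsets, function(s)
      logo_matrix(msa_a, subset = s$seq_id))
    note("subsets",
         sizes = vapply(subsets$subsets, nrow, integer(1)))
    if (out) {
      for (nm in names(logos))
        write_logo_matrix(logos[[nm]],
                          file.path(cfg$out_dir, paste0("logo_", nm, ".tsv")))
    }
  } else {
    note("subsets", skipped = TRUE)
  }

  consensus <- if (length(results) >= 2L)
    consensus_contacts(results, top_n = cfg$top_n_consensus,
                       min_sep = cfg$min_sep) else NULL
  note("consensus",
       size = if (is.null(consensus)) NA_integer_ else nrow(consensus))

  if (out && length(results)) {
    first <- coupling_pairs(results[[1]], min_sep = cfg$min_sep)
    export_restraints(first[first$inter, , drop = FALSE],
                      file.path(cfg$out_dir, "restraints.rr"),
                      format = cfg$restraint_format,
                      top_n = min(cfg$restraint_top_n,
                                  sum(first$inter)))
  }

  report$objects <- list(paired = paired, weighted = wmsa,
                         results = results, thresholds = thresholds,
                         contacts = contacts, filtered = filtered,
                         classified = classified, geom = geom,
                         subsets = subsets, logos = logos,
                         consensus = consensus)
  class(report) <- "run_report"
  if (out) {
    slim <- report[c("stages", "config")]
    jsonlite::write_json(slim, file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  report
}

echo_config <- function(cfg) {
  e <- unclass(cfg)
  e$msa_a <- if (is.null(e$msa_a)) NULL else "<in-memory MSA>"
  e$msa_b <- if (is.null(e$msa_b)) NULL else "<in-memory MSA>"
  e$anchor_a <- if (is.null(e$anchor_a)) NULL else unclass(e$anchor_a)
  e$anchor_b <- if (is.null(e$anchor_b)) NULL else unclass(e$anchor_b)
  e
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    if (isTRUE(st$skipped)) {
      cat("  ", nm, ": skipped\n", sep = "")
    } else {
      vals <- vapply(st, function(v)
        paste(format(unlist(v), digits = 4, trim = TRUE), collapse = "/"),
        character(1))
      cat("  ", nm, ": ", paste(names(vals), vals, sep = "=",
                                collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Score predictions against synthetic ground truth
#'
#' Positive predictive value at the top `top_k` predicted contacts and the
#' rank of every planted pair, per scoring method and for the consensus.
#' Ranking and truth matching use concatenated column coordinates; by
#' default only inter-chain predictions are ranked (the planted pairs of
#' interest are inter-chain contacts).
#'
#' @param results list of `coupling_result` objects (or a `run_report`).
#' @param truth a `synthetic_truth`.
#' @param top_k number of top predictions scored (default: number of
#'   planted pairs).
#' @param subset `"inter"` (default) or `"all"`: which predictions to rank.
#' @param min_sep intra-chain separation filter (see [coupling_pairs()]).
#' @return list with `ppv` (named per method), `ranks` (data frame: method,
#'   col_i, col_j, rank), and `top_k`.
#' @export
evaluate_against_truth <- function(results, truth, top_k = NULL,
                                   subset = c("inter", "all"),
                                   min_sep = 5L) {
  subset <- match.arg(subset)
  if (inherits(results, "run_report")) results <- results$objects$results
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- truth$planted_pairs
  if (is.null(planted) || !nrow(planted))
    stop("truth object has no planted pairs", call. = FALSE)
  if (is.null(top_k)) top_k <- nrow(planted)
  truth_keys <- paste(pmin(planted$col_i, planted$col_j),
                      pmax(planted$col_i, planted$col_j))
  L <- truth$config$len_a + truth$config$len_b
  ppv <- numeric(0)
  ranks <- NULL
  for (m in names(results)) {
    r <- results[[m]]
    if (nrow(r$raw) != L)
      stop("dimension mismatch: coupling result has ", nrow(r$raw),
           " columns, truth expects ", L, call. = FALSE)
    cp <- coupling_pairs(r, min_sep = min_sep)
    if (subset == "inter") cp <- cp[cp$inter, , drop = FALSE]
    keys <- paste(cp$i, cp$j)
    hit <- keys[seq_len(min(top_k, length(keys)))] %in% truth_keys
    ppv[m] <- sum(hit) / top_k
    ranks <- rbind(ranks,
                   data.frame(method = m,
                              col_i = pmin(planted$col_i, planted$col_j),
                              col_j = pmax(planted$col_i, planted$col_j),
                              rank = match(truth_keys, keys),
                              stringsAsFactors = FALSE))
  }
  list(ppv = ppv, ranks = ranks, top_k = top_k)
}
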