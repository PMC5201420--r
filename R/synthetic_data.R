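#' Sample a random species tree
#'
#' Deterministic given `seed`. `"yule"` draws a pure-birth tree
#' (birth rate 1); `"star"` returns a star phylogeny with unit branch
#' lengths.
#'
#' @param n number of organisms (leaves), >= 2.
#' @param shape `"yule"` or `"star"`.
#' @param seed integer RNG seed.
#' @return an `ape::phylo` tree with `n` leaves and positive branch lengths.
#' @export
sample_species_tree <- function(n, shape = c("yule", "star"), seed = 1L) {
  shape <- match.arg(shape)
  if (n < 2L) stop("size error: need at least 2 organisms", call. = FALSE)
  set.seed(seed)
  tree <- switch(shape,
                 yule = ape::rphylo(n, birth = 1, death = 0),
                 star = {
                   t <- ape::stree(n, type = "star")
                   t$edge.length <- rep(1, nrow(t$edge))
                   t
                 })
  tree$tip.label <- paste0("org", seq_len(n))
  tree
}

#' Simulation configuration for the paired-MSA generator
#'
#' Defines the study conditions the generator emulates: a shared species
#' tree, two gapless protein chains evolving along it, planted compensatory
#' couplings, invariant anchor columns, optional paralogous subfamilies with
#' motif signatures, and contamination (verbatim duplicates, unpaired rows,
#' anchor violations).
#'
#' @param n_organisms number of organisms.
#' @param len_a,len_b chain lengths (family A, family B).
#' @param planted_pairs data frame with columns `chain_i`, `pos_i`,
#'   `chain_j`, `pos_j`, `strength` (s in [0,1]); positions are 1-based
#'   within each chain. NULL for none.
#' @param mutation_rate substitutions per column per unit branch length.
#' @param tree_shape `"yule"` or `"star"`.
#' @param n_subfamilies number of paralogous subfamilies of family A (1 =
#'   none). Subfamilies are deep clades: independent subtrees joined by long
#'   stems of length `subfamily_sep`.
#' @param motif_columns chain-A columns carrying the subfamily motif
#'   (each subfamily gets a distinct residue at each motif column).
#' @param subfamily_sep stem length separating subfamilies.
#' @param anchor_col_a,anchor_res_a invariant anchor in chain A (a hinge-
#'   glycine analogue); the column never mutates.
#' @param anchor_col_b,anchor_res_b invariant anchor in chain B.
#' @param dup_rate,unpaired_rate,anchor_violation_rate contamination rates
#'   in [0,1]; counts are deterministic (`round(rate * n)`), applied to
#'   disjoint organisms.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_organisms = 500L, len_a = 30L, len_b = 60L,
                              planted_pairs = NULL, mutation_rate = 0.05,
                              tree_shape = c("yule", "star"),
                              n_subfamilies = 1L, motif_columns = integer(),
                              subfamily_sep = 3,
                              anchor_col_a = 2L, anchor_res_a = "G",
                              anchor_col_b = 2L, anchor_res_b = "E",
                              dup_rate = 0, unpaired_rate = 0,
                              anchor_violation_rate = 0, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_organisms >= 2L, len_a >= 1L, len_b >= 1L,
            dup_rate >= 0, dup_rate <= 1, unpaired_rate >= 0,
            unpaired_rate <= 1, anchor_violation_rate >= 0,
            anchor_violation_rate <= 1, mutation_rate > 0,
            n_subfamilies >= 1L)
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("chain_i", "pos_i", "chain_j", "pos_j", "strength") %in%
                    names(planted_pairs)),
              all(planted_pairs$strength >= 0),
              all(planted_pairs$strength <= 1))
    lims <- c(A = len_a, B = len_b)
    ok <- planted_pairs$pos_i >= 1 &
      planted_pairs$pos_i <= lims[planted_pairs$chain_i] &
      planted_pairs$pos_j >= 1 &
      planted_pairs$pos_j <= lims[planted_pairs$chain_j]
    if (!all(ok)) stop("planted pair positions outside their chains",
                       call. = FALSE)
  }
  fixed_a <- c(anchor_col_a, motif_columns)
  if (!is.null(planted_pairs)) {
    pa <- c(planted_pairs$pos_i[planted_pairs$chain_i == "A"],
            planted_pairs$pos_j[planted_pairs$chain_j == "A"])
    pb <- c(planted_pairs$pos_i[planted_pairs$chain_i == "B"],
            planted_pairs$pos_j[planted_pairs$chain_j == "B"])
    if (any(pa %in% fixed_a) || any(pb %in% anchor_col_b))
      stop("configuration error: planted pair collides with a motif or ",
           "anchor column", call. = FALSE)
  }
  if (anchor_col_a %in% motif_columns)
    stop("configuration error: anchor column cannot carry a motif",
         call. = FALSE)
  structure(list(n_organisms = as.integer(n_organisms),
                 len_a = as.integer(len_a), len_b = as.integer(len_b),
                 planted_pairs = planted_pairs,
                 mutation_rate = mutation_rate, tree_shape = tree_shape,
                 n_subfamilies = as.integer(n_subfamilies),
                 motif_columns = as.integer(motif_columns),
                 subfamily_sep = subfamily_sep,
                 anchor_col_a = as.integer(anchor_col_a),
                 anchor_res_a = anchor_res_a,
                 anchor_col_b = as.integer(anchor_col_b),
                 anchor_res_b = anchor_res_b,
                 dup_rate = dup_rate, unpaired_rate = unpaired_rate,
                 anchor_violation_rate = anchor_violation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Convenience set of inter-chain planted pairs
#'
#' `k` pairs at evenly spaced chain-A and chain-B positions (skipping the
#' default anchor columns), all at coupling strength `strength`.
#'
#' @param k number of pairs.
#' @param len_a,len_b chain lengths.
#' @param strength coupling strength in [0, 1].
#' @return data frame usable as `planted_pairs` in [simulation_config()].
#' @export
planted_pairs_inter <- function(k, len_a = 30L, len_b = 60L, strength = 0.9) {
  pos_a <- round(seq(4, len_a - 1, length.out = k))
  pos_b <- round(seq(4, len_b - 1, length.out = k))
  data.frame(chain_i = "A", pos_i = as.integer(pos_a),
             chain_j = "B", pos_j = as.integer(pos_b),
             strength = strength, stringsAsFactors = FALSE)
}

# fixed compensatory bijection on the 20 residues (shift by 7, coprime to 20)
compensatory_partner <- function(code) ((code + 6L) %% 20L) + 1L

#' Simulate a pair of organism-matched family alignments
#'
#' An ancestral concatenated sequence is evolved down a species tree. At
#' ordinary columns substitutions are independent draws at
#' `mutation_rate` per unit branch length. At a planted pair with strength
#' `s`, a substitution at one member is accompanied with probability `s` by
#' a deterministic compensatory substitution at its partner (a fixed
#' bijection on the 20 residues), producing genuine direct covariation.
#' Anchor columns are invariant; subfamily motifs overwrite their columns
#' after evolution; contamination (verbatim duplicates, unpaired rows,
#' anchor violations) is applied last and applied to disjoint organisms so
#' that every contamination event is individually recoverable. Headers carry
#' organism IDs in the UniProt `OX=` convention.
#'
#' @param cfg a [simulation_config()].
#' @return list with `msa_a`, `msa_b` (class `coev_msa`, organism IDs
#'   populated), `tree` (the species tree), and `truth`, a
#'   `synthetic_truth` object recording planted pairs (also in concatenated
#'   coordinates), subfamily membership, the organism roster, per-row
#'   contamination flags, and the full config echo.
#' @export
simulate_paired_msa <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_organisms
  L <- cfg$len_a + cfg$len_b

  # species tree (subfamilies are deep clades joined by long stems)
  if (cfg$n_subfamilies > 1L) {
    sizes <- diff(round(seq(0, n, length.out = cfg$n_subfamilies + 1L)))
    parts <- vapply(seq_len(cfg$n_subfamilies), function(s) {
      if (sizes[s] == 1L) {
        nwk <- paste0("s", s, "x1")
      } else {
        sub <- ape::rphylo(sizes[s], birth = 1, death = 0)
        # normalise the subtree to unit height so the joining stems
        # (subfamily_sep) dominate: subfamilies are deep, well-separated
        # clades, as in a paralog family tree
        h <- max(ape::node.depth.edgelength(sub))
        sub$edge.length <- sub$edge.length / h
        sub$tip.label <- paste0("s", s, "x", seq_len(sizes[s]))
        nwk <- sub(";$", "", ape::write.tree(sub))
      }
      paste0(nwk, ":", format(cfg$subfamily_sep, scientific = FALSE))
    }, character(1))
    tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","),
                                         ");"))
    subfam_of_tip <- as.integer(sub("^s([0-9]+)x.*$", "\\1", tree$tip.label))
    tree$tip.label <- paste0("org", seq_len(n))
    subfam <- setNames(subfam_of_tip, tree$tip.label)
  } else {
    tree <- switch(cfg$tree_shape,
                   yule = ape::rphylo(n, birth = 1, death = 0),
                   star = {
                     t <- ape::stree(n, type = "star")
                     t$edge.length <- rep(1, nrow(t$edge))
                     t
                   })
    tree$tip.label <- paste0("org", seq_len(n))
    subfam <- setNames(rep(1L, n), tree$tip.label)
  }

  # planted pairs in concatenated coordinates
  planted <- cfg$planted_pairs
  if (!is.null(planted) && nrow(planted)) {
    planted$col_i <- ifelse(planted$chain_i == "A", planted$pos_i,
                            cfg$len_a + planted$pos_i)
    planted$col_j <- ifelse(planted$chain_j == "A", planted$pos_j,
                            cfg$len_a + planted$pos_j)
  }
  anchor_cols <- c(cfg$anchor_col_a, cfg$len_a + cfg$anchor_col_b)
  anchor_codes <- match(c(cfg$anchor_res_a, cfg$anchor_res_b), AA20)
  motif_cols_cat <- cfg$motif_columns  # chain A columns == concatenated

  # ancestral sequence
  root <- sample.int(20L, L, replace = TRUE)
  root[anchor_cols] <- anchor_codes
  if (!is.null(planted) && nrow(planted))
    root[planted$col_j] <- compensatory_partner(root[planted$col_i])

  mutable <- setdiff(seq_len(L), anchor_cols)
  planted_cols <- if (!is.null(planted)) c(planted$col_i, planted$col_j)
                  else integer()

  # evolve down the tree, preorder over edges
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  seqs <- matrix(0L, ntip, L)
  node_seq <- vector("list", ntip + tr$Nnode)
  root_node <- ntip + 1L
  node_seq[[root_node]] <- root
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    s <- node_seq[[parent]]
    p_mut <- 1 - exp(-cfg$mutation_rate * tr$edge.length[e])
    hit <- mutable[runif(length(mutable)) < p_mut]
    if (length(hit)) {
      # independent substitutions (draw from the 19 other residues)
      s[hit] <- (s[hit] - 1L + sample.int(19L, length(hit),
                                          replace = TRUE)) %% 20L + 1L
      # compensatory follow-up at planted partners
      if (!is.null(planted) && nrow(planted)) {
        for (p in seq_len(nrow(planted))) {
          ci <- planted$col_i[p]; cj <- planted$col_j[p]
          s_p <- planted$strength[p]
          if (ci %in% hit && runif(1) < s_p)
            s[cj] <- compensatory_partner(s[ci])
          if (cj %in% hit && runif(1) < s_p)
            s[ci] <- match(s[cj], compensatory_partner(seq_len(20L)))
        }
      }
    }
    node_seq[[child]] <- s
    if (child <= ntip) seqs[child, ] <- s
  }
  rownames(seqs) <- tr$tip.label
  seqs <- seqs[paste0("org", seq_len(n)), , drop = FALSE]

  # subfamily motifs overwrite their columns after evolution
  if (cfg$n_subfamilies > 1L && length(motif_cols_cat)) {
    for (s in seq_len(cfg$n_subfamilies)) {
      rows <- which(subfam[rownames(seqs)] == s)
      for (ci in seq_along(motif_cols_cat)) {
        res <- ((s - 1L + (ci - 1L) * cfg$n_subfamilies) %% 20L) + 1L
        seqs[rows, motif_cols_cat[ci]] <- res
      }
    }
  }

  # resolve accidental verbatim duplicates deterministically so that truth
  # flags and pipeline provenance can match exactly
  free_cols <- setdiff(mutable, c(planted_cols, motif_cols_cat))
  key <- apply(seqs, 1, paste, collapse = ",")
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    col <- free_cols[1 + (d %% length(free_cols))]
    seqs[d, col] <- (seqs[d, col] %% 20L) + 1L
    key <- apply(seqs, 1, paste, collapse = ",")
  }

  org_ids <- as.character(1000L + seq_len(n))
  rows_a <- data.frame(seq_id = paste0("A", org_ids), organism = org_ids,
                       row = seq_len(n), flag = "clean",
                       stringsAsFactors = FALSE)
  rows_b <- data.frame(seq_id = paste0("B", org_ids), organism = org_ids,
                       row = seq_len(n), flag = "clean",
                       stringsAsFactors = FALSE)
  mat_a <- seqs[, seq_len(cfg$len_a), drop = FALSE]
  mat_b <- seqs[, cfg$len_a + seq_len(cfg$len_b), drop = FALSE]

  # contamination on disjoint organisms, deterministic counts
  n_dup <- as.integer(round(cfg$dup_rate * n))
  n_unp <- as.integer(round(cfg$unpaired_rate * n))
  n_anc <- as.integer(round(cfg$anchor_violation_rate * n))
  if (n_dup + n_unp + n_anc > n)
    stop("contamination rates exceed the organism count", call. = FALSE)
  picks <- sample.int(n, n_dup + n_unp + n_anc)
  dup_rows <- picks[seq_len(n_dup)]
  unp_rows <- picks[n_dup + seq_len(n_unp)]
  anc_rows <- picks[n_dup + n_unp + seq_len(n_anc)]

  if (n_anc > 0L) {
    bad <- match("P", AA20)  # any residue outside the allowed anchor set
    if (cfg$anchor_res_a == "P") bad <- match("G", AA20)
    mat_a[anc_rows, cfg$anchor_col_a] <- bad
    rows_a$flag[anc_rows] <- "anchor_violation"
  }
  if (n_unp > 0L) rows_a$flag[unp_rows] <- "unpaired"

  # duplicates: verbatim copies of family-A rows, same organism
  if (n_dup > 0L) {
    dup_a <- data.frame(seq_id = paste0("A", org_ids[dup_rows], "dup"),
                        organism = org_ids[dup_rows], row = dup_rows,
                        flag = "duplicate", stringsAsFactors = FALSE)
    rows_a <- rbind(rows_a, dup_a)
    mat_a <- rbind(mat_a, mat_a[dup_rows, , drop = FALSE])
  }

  # unpaired: delete the family-B record of the chosen organisms
  keep_b <- !(rows_b$row %in% unp_rows)
  rows_b <- rows_b[keep_b, , drop = FALSE]
  mat_b <- mat_b[keep_b, , drop = FALSE]

  to_string <- function(m) apply(m, 1, function(r) paste(AA20[r],
                                                         collapse = ""))
  header_a <- paste0(rows_a$seq_id, " synthetic family A OX=", rows_a$organism)
  header_b <- paste0(rows_b$seq_id, " synthetic family B OX=", rows_b$organism)

  msa_a <- new_msa(rows_a$seq_id, header_a, rows_a$organism,
                   unname(to_string(mat_a)), "familyA")
  msa_b <- new_msa(rows_b$seq_id, header_b, rows_b$organism,
                   unname(to_string(mat_b)), "familyB")

  truth <- structure(list(
    planted_pairs = planted,
    subfamily = data.frame(seq_id = paste0("A", org_ids),
                           organism_id = org_ids,
                           subfamily = unname(subfam[paste0("org",
                                                            seq_len(n))]),
                           stringsAsFactors = FALSE),
    organisms = org_ids,
    flags_a = rows_a[, c("seq_id", "organism", "flag")],
    flags_b = rows_b[, c("seq_id", "organism", "flag")],
    n_duplicate = n_dup, n_unpaired = n_unp, n_anchor_violation = n_anc,
    config = cfg), class = "synthetic_truth")

  list(msa_a = msa_a, msa_b = msa_b, tree = tree, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth: ", length(x$organisms), " organisms, ",
      if (is.null(x$planted_pairs)) 0L else nrow(x$planted_pairs),
      " planted pairs, contamination (dup/unpaired/anchor) = ",
      x$n_duplicate, "/", x$n_unpaired, "/", x$n_anchor_violation, "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the two aligned FASTA files, truth tables (TSV), and a JSON config
#' echo. Deterministic: identical configs give byte-identical files.
#'
#' @param sim output of [simulate_paired_msa()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fam in c("msa_a", "msa_b")) {
    msa <- sim[[fam]]
    f <- file.path(dir, paste0(msa$family_label, ".fasta"))
    writeLines(paste0(">", msa$header, "\n", msa$residues), f)
  }
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  truth <- sim$truth
  write.table(truth$flags_a, file.path(dir, "truth_flags_a.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$flags_b, file.path(dir, "truth_flags_b.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$subfamily, file.path(dir, "truth_subfamily.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$planted_pairs))
    write.table(truth$planted_pairs, file.path(dir, "truth_planted.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Toy membrane geometry with planted contacts
#'
#' Builds a helical Calpha trace per chain spanning z in [-20, 20] Angstrom
#' (the membrane normal along z). Chain-B residues of each planted pair are
#' repositioned next to their chain-A partner (d3d <= 8, dz < 15); decoy
#' pairs are repositioned to dz > 15. Optionally writes a PDB file readable
#' by [load_geometry()].
#'
#' @param len_a,len_b chain lengths.
#' @param planted_pairs as in [simulation_config()] (inter-chain rows used).
#' @param decoy_pairs optional data frame (pos_i chain A, pos_j chain B)
#'   forced to dz > 15.
#' @param seed RNG seed (used only for small xy jitter of decoys).
#' @param pdb_path optional path; if given, a CA-only PDB file is written.
#' @return a `residue_geometry` data frame (chain, pos, x, y, z).
#' @export
make_toy_geometry <- function(len_a, len_b, planted_pairs = NULL,
                              decoy_pairs = NULL, seed = 1L,
                              pdb_path = NULL) {
  stopifnot(len_a >= 1L, len_b >= 1L)
  set.seed(seed)
  helix <- function(len, x0) {
    k <- seq_len(len)
    data.frame(x = x0 + 2.3 * cos(2 * pi * k / 3.6),
               y = 2.3 * sin(2 * pi * k / 3.6),
               z = if (len == 1L) 0 else seq(-20, 20, length.out = len))
  }
  ga <- cbind(chain = "A", pos = seq_len(len_a), helix(len_a, 0))
  gb <- cbind(chain = "B", pos = seq_len(len_b), helix(len_b, 10))
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    pp <- planted_pairs[planted_pairs$chain_i == "A" &
                          planted_pairs$chain_j == "B", , drop = FALSE]
    for (p in seq_len(nrow(pp))) {
      a <- ga[ga$pos == pp$pos_i[p], c("x", "y", "z")]
      gb[gb$pos == pp$pos_j[p], c("x", "y", "z")] <-
        a + c(4, 0, 2)  # d3d = sqrt(20) ~ 4.47 A, dz = 2 A
    }
  }
  if (!is.null(decoy_pairs) && nrow(decoy_pairs)) {
    for (p in seq_len(nrow(decoy_pairs))) {
      a <- ga[ga$pos == decoy_pairs$pos_i[p], c("x", "y", "z")]
      gb[gb$pos == decoy_pairs$pos_j[p], c("x", "y", "z")] <-
        a + c(runif(1, -2, 2), runif(1, -2, 2), 18)  # dz = 18 A > 15
    }
  }
  geom <- rbind(ga, gb)
  geom$pos <- as.integer(geom$pos)
  class(geom) <- c("residue_geometry", "data.frame")
  if (!is.null(pdb_path)) write_ca_pdb(geom, pdb_path)
  geom
}

# minimal CA-only PDB writer (fixed-column format)
write_ca_pdb <- function(geom, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(geom)), geom$chain, geom$pos, geom$x, geom$y, geom$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
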