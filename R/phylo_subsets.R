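#' Pairwise identity distance matrix over a column region
#'
#' `d(i,j) = 1 - (matching non-gap columns) / (columns where either sequence
#' has a residue)` over the chosen region (e.g. the TMH+APH helices of a
#' TatA-family alignment). Both-gap columns are unscored; a pair sharing no
#' scored column gets distance 1 with a warning.
#'
#' @param msa a `coev_msa`.
#' @param region length-2 integer vector, 1-based inclusive column interval;
#'   default the whole alignment.
#' @return an object of class `identity_dist`: list with `taxa` (seq IDs),
#'   `organism_id`, `d` (symmetric matrix, zero diagonal) and `region`.
#' @export
pairwise_distance_matrix <- function(msa, region = c(1L, msa$n_columns)) {
  stopifnot(inherits(msa, "coev_msa"), length(region) == 2L,
            region[1] >= 1L, region[2] <= msa$n_columns,
            region[1] <= region[2])
  sub <- substr(msa$residues, region[1], region[2])
  codes <- encode_residues(sub)
  res <- cpp_identity_distance(codes, GAP_CODE)
  if (res$n_no_overlap > 0)
    warning(res$n_no_overlap, " sequence pair(s) share no scored column; ",
            "their distance is set to 1", call. = FALSE)
  d <- res$d
  dimnames(d) <- list(msa$seq_id, msa$seq_id)
  structure(list(taxa = msa$seq_id, organism_id = msa$organism_id, d = d,
                 region = as.integer(region)),
            class = "identity_dist")
}

#' Build a tree from an identity distance matrix
#'
#' Neighbour joining (`"nj"`, via ape; negative branch lengths are clamped
#' to zero with a message) or UPGMA (`"upgma"`, average-linkage
#' agglomeration, giving an ultrametric rooted tree).
#'
#' @param dm an `identity_dist`.
#' @param method `"nj"` or `"upgma"`.
#' @return an `ape::phylo` tree over all taxa.
#' @export
build_tree <- function(dm, method = c("nj", "upgma")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "identity_dist"))
  n <- length(dm$taxa)
  if (n < 2L) stop("size error: need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    half <- dm$d[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         dm$taxa[1], half, dm$taxa[2], half)))
  }
  if (method == "nj") {
    tree <- ape::nj(as.dist(dm$d))
    if (any(tree$edge.length < 0)) {
      message(sum(tree$edge.length < 0),
              " negative NJ branch length(s) clamped to 0")
      tree$edge.length[tree$edge.length < 0] <- 0
    }
    tree
  } else {
    hc <- hclust(as.dist(dm$d), method = "average")
    ape::as.phylo(hc)
  }
}

#' Partition taxa into phylogenetic subsets
#'
#' `"k_groups"` removes the k-1 longest internal edges of the tree and takes
#' the connected components (a reproducible surrogate for assigning subsets
#' by visual inspection of a cladogram); if the tree has fewer than k-1
#' internal edges the longest terminal edges are cut as well.
#' `"height_cut"` cuts an ultrametric (UPGMA) tree at a height above the
#' tips, taking each hanging clade as a subset.
#'
#' @param tree an `ape::phylo` tree (or Newick text).
#' @param rule `"k_groups"` or `"height_cut"`.
#' @param k number of groups (k_groups).
#' @param height cut height above the tips (height_cut).
#' @param organism_ids optional character vector named by taxon giving each
#'   taxon's organism, carried into the partition for co-occurrence
#'   bookkeeping.
#' @return an object of class `subset_partition`: `subsets` is a named list
#'   of data frames (seq_id, organism_id), plus `method` and the `tree` as
#'   Newick text.
#' @export
partition_subsets <- function(tree, rule = c("k_groups", "height_cut"),
                              k = 3L, height = NULL, organism_ids = NULL) {
  rule <- match.arg(rule)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  if (ntip == 1L || (rule == "k_groups" && k == 1L)) {
    groups <- setNames(rep(1L, ntip), tree$tip.label)
  } else if (rule == "k_groups") {
    if (k > ntip) stop("size error: k = ", k, " exceeds ", ntip, " taxa",
                       call. = FALSE)
    edge <- tree$edge
    len <- tree$edge.length
    internal <- edge[, 2] > ntip
    ord <- order(!internal, -len)  # internal edges first, longest first
    drop <- ord[seq_len(k - 1L)]
    groups <- components_after_cut(tree, drop)
  } else {
    if (is.null(height)) stop("height_cut requires a height", call. = FALSE)
    depth <- ape::node.depth.edgelength(tree)  # distance from the root
    H <- max(depth[seq_len(ntip)])
    # cut edges crossing the height: parent above the cut, child at/below
    hn <- H - depth  # height above the tips
    edge <- tree$edge
    crossing <- which(hn[edge[, 1]] > height & hn[edge[, 2]] <= height)
    groups <- components_after_cut(tree, crossing)
  }
  ids <- split(names(groups), groups)
  names(ids) <- paste0("subset", seq_along(ids))
  subsets <- lapply(ids, function(s) {
    data.frame(seq_id = s,
               organism_id = if (is.null(organism_ids)) NA_character_
                             else unname(organism_ids[s]),
               stringsAsFactors = FALSE)
  })
  structure(list(subsets = subsets,
                 method = if (rule == "k_groups") "k_groups" else "height_cut",
                 tree = ape::write.tree(tree)),
            class = "subset_partition")
}

# connected components of the tree after deleting the given edge rows;
# returns an integer group id per tip, named by tip label
components_after_cut <- function(tree, drop_edges) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- seq_len(nnode)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- setdiff(seq_len(nrow(tree$edge)), drop_edges)
  for (e in keep) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(ntip), find, integer(1))
  setNames(match(roots, unique(roots)), tree$tip.label)
}

#' @export
print.subset_partition <- function(x, ...) {
  sizes <- vapply(x$subsets, nrow, integer(1))
  cat("Subset partition (", x$method, "): ",
      paste(names(sizes), "=", sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter one subset by organism co-occurrence with another
#'
#' Retains the members of `subset_a` whose organism also has a member in
#' `subset_b` (e.g. keeping only TatA proteins from organisms that also have
#' a TatB protein, so that only genuine three-component systems remain).
#'
#' @param subset_a,subset_b subset members: data frames with `seq_id` and
#'   `organism_id` columns (as stored in a `subset_partition`).
#' @return the filtered `subset_a`; a warning is raised if it empties.
#' @export
filter_subset_by_cooccurrence <- function(subset_a, subset_b) {
  stopifnot(is.data.frame(subset_a), is.data.frame(subset_b))
  keep <- subset_a$organism_id %in% unique(subset_b$organism_id)
  out <- subset_a[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("co-occurrence filter removed every member of the subset",
            call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-column residue frequencies and information content
#'
#' Sequence-logo statistics for a subset of an alignment: per-column
#' frequencies over the 20 amino acids (gaps excluded from the numerator;
#' per-column coverage reported) and information content
#' `IC = log2(20) - H` in bits, where `H` is the Shannon entropy of the
#' non-gap frequencies. Columns that are 100% gaps get `IC = NA` (undefined).
#' A small-sample correction is available but off by default.
#'
#' @param msa a `coev_msa`.
#' @param subset optional character vector of seq IDs (default: all rows).
#' @param weights optional per-sequence weights (aligned with `subset`).
#' @param small_sample_correction subtract the Miller-Madow bias term
#'   `(q - 1) / (2 ln(2) n)` from IC (default FALSE).
#' @return an object of class `logo_matrix`: data frame with `column`, one
#'   frequency column per residue, `coverage` and `ic_bits`.
#' @export
logo_matrix <- function(msa, subset = NULL, weights = NULL,
                        small_sample_correction = FALSE) {
  stopifnot(inherits(msa, "coev_msa"))
  rows <- if (is.null(subset)) seq_along(msa$seq_id)
          else match(subset, msa$seq_id)
  if (anyNA(rows)) stop("subset contains unknown sequence IDs", call. = FALSE)
  if (length(rows) == 0L) stop("empty subset", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(rows))
  stopifnot(length(weights) == length(rows), all(weights > 0))
  codes <- encode_residues(msa$residues[rows])
  L <- ncol(codes)
  q_logo <- 20L
  freq <- matrix(0, L, q_logo, dimnames = list(NULL, AA20))
  coverage <- numeric(L)
  ic <- numeric(L)
  wtot <- sum(weights)
  for (col in seq_len(L)) {
    cnt <- vapply(seq_len(q_logo),
                  function(a) sum(weights[codes[, col] == a]), numeric(1))
    nongap <- sum(cnt)
    coverage[col] <- nongap / wtot
    if (nongap == 0) {
      ic[col] <- NA_real_
      next
    }
    f <- cnt / nongap
    freq[col, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    ic[col] <- log2(q_logo) - h
    if (small_sample_correction) {
      n_eff <- sum(weights[codes[, col] != GAP_CODE])
      ic[col] <- ic[col] - (q_logo - 1) / (2 * log(2) * n_eff)
    }
  }
  out <- data.frame(column = seq_len(L), freq, coverage = coverage,
                    ic_bits = ic, check.names = FALSE)
  class(out) <- c("logo_matrix", "data.frame")
  out
}

#' Write a logo matrix as TSV
#'
#' @param logo a `logo_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(logo, path) {
  write.table(logo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (grouped together
#' in both, or separated in both). Used to compare a recovered subset
#' partition with planted subfamily membership.
#'
#' @param labels_a,labels_b vectors of group labels over the same elements.
#' @return the Rand index in [0, 1].
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2L) return(1)
  same_a <- outer(labels_a, labels_a, "==")
  same_b <- outer(labels_b, labels_b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}
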