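#' Read an aligned FASTA file as an MSA object
#'
#' Sequences are upper-cased, '.' gaps are normalised to '-', and any
#' character outside the 20 amino acids, '-' and 'X' is mapped to 'X' (a
#' warning reports how many characters were remapped). All sequences must
#' have the same length.
#'
#' @param path path to an aligned FASTA file (.fasta/.fa/.afa).
#' @param family_label label for the protein family (e.g. "TatA", "TatC").
#' @return an object of class `coev_msa`: a list with elements
#'   `seq_id`, `header`, `organism_id` (NA until parsed), `residues`,
#'   `n_columns`, `family_label` and a `provenance` data frame.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 OX=1", "AG-X", ">s2 OX=2", "AGGX"), f)
#' msa <- read_alignment(f, "demo")
#' msa$n_columns
read_alignment <- function(path, family_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  headers <- names(set)
  residues <- toupper(as.character(set))
  widths <- nchar(residues)
  if (length(unique(widths)) != 1L) {
    stop("alignment-shape error: sequences have unequal lengths (",
         paste(unique(widths), collapse = ", "), ") in ", path,
         call. = FALSE)
  }
  residues <- gsub(".", "-", residues, fixed = TRUE)
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X-]"), "", residues)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0L) {
    residues <- vapply(residues, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      chars[!chars %in% ALPHABET] <- "X"
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    warning(n_bad, " non-standard character(s) mapped to 'X' in ", path,
            call. = FALSE)
  }
  seq_id <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1L)
  new_msa(seq_id = seq_id, header = headers, organism_id = rep(NA_character_,
          length(seq_id)), residues = unname(residues),
          family_label = family_label)
}

new_msa <- function(seq_id, header, organism_id, residues, family_label,
                    provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(stage = character(), dropped = integer(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  structure(list(seq_id = seq_id, header = header,
                 organism_id = organism_id, residues = residues,
                 n_columns = if (length(residues)) nchar(residues[1]) else 0L,
                 family_label = family_label, provenance = provenance),
            class = "coev_msa")
}

#' @export
print.coev_msa <- function(x, ...) {
  cat("MSA <", x$family_label, ">: ", length(x$residues), " sequences x ",
      x$n_columns, " columns\n", sep = "")
  if (nrow(x$provenance)) {
    cat("filters applied:\n")
    print(x$provenance, row.names = FALSE)
  }
  invisible(x)
}

add_provenance <- function(msa, stage, dropped, reason) {
  msa$provenance <- rbind(msa$provenance,
                          data.frame(stage = stage, dropped = as.integer(dropped),
                                     reason = reason, stringsAsFactors = FALSE))
  msa
}

subset_msa <- function(msa, keep) {
  msa$seq_id <- msa$seq_id[keep]
  msa$header <- msa$header[keep]
  msa$organism_id <- msa$organism_id[keep]
  msa$residues <- msa$residues[keep]
  msa
}

#' Parse organism identifiers from FASTA headers
#'
#' Populates `organism_id` for every record. `header_rule` is either a named
#' convention — `"ox"` (UniProt `OX=<taxid>`) or `"os"` (UniProt
#' `OS=<name>`) — or a custom regular expression whose first capture group
#' yields the organism ID. Records whose header yields no ID are dropped and
#' counted in the provenance table.
#'
#' @param msa a `coev_msa`.
#' @param header_rule `"ox"`, `"os"`, or a regex with one capture group.
#' @return the MSA with `organism_id` populated and droppings recorded.
#' @export
parse_organism_ids <- function(msa, header_rule = "ox") {
  stopifnot(inherits(msa, "coev_msa"))
  pattern <- switch(header_rule,
                    ox = "OX=([0-9]+)",
                    os = "OS=(.+?)(?:\\s+[A-Z]{2}=|$)",
                    header_rule)
  m <- regmatches(msa$header, regexec(pattern, msa$header))
  ids <- vapply(m, function(g) if (length(g) >= 2L) g[2] else NA_character_,
                character(1))
  ids[!is.na(ids) & ids == ""] <- NA_character_
  if (all(is.na(ids))) {
    stop("configuration error: header rule '", header_rule,
         "' matched no header in MSA '", msa$family_label,
         "' - check the pattern (a sparse-metadata file would still match ",
         "some headers)", call. = FALSE)
  }
  n_drop <- sum(is.na(ids))
  msa$organism_id <- ids
  msa <- subset_msa(msa, !is.na(ids))
  add_provenance(msa, "parse_organism_ids", n_drop, "no organism ID in header")
}

#' Define an anchor-residue rule
#'
#' An anchor rule retains only sequences carrying one of `allowed_residues`
#' at a given alignment column — e.g. the invariant TatA-family inter-helix
#' hinge glycine, or the TatC signal-peptide-binding glutamate. A gap at the
#' anchor column counts as lacking the residue.
#'
#' @param column_index 1-based alignment column.
#' @param allowed_residues character vector of allowed residues.
#' @param description free-text label (e.g. "G21 hinge").
#' @export
anchor_rule <- function(column_index, allowed_residues, description = "") {
  stopifnot(length(column_index) == 1L, column_index >= 1L,
            length(allowed_residues) >= 1L)
  structure(list(column_index = as.integer(column_index),
                 allowed_residues = toupper(allowed_residues),
                 description = description),
            class = "anchor_rule")
}

#' Map an ungapped reference-sequence position to its alignment column
#'
#' Anchor residues are usually named in reference-sequence numbering (e.g.
#' E. coli TatA G21). Given the reference row of the alignment, this maps a
#' 1-based ungapped position in that sequence to the 1-based alignment
#' column it occupies.
#'
#' @param msa a `coev_msa`.
#' @param ref_seq_id sequence ID of the reference row.
#' @param position 1-based ungapped residue position in the reference.
#' @return 1-based alignment column index.
#' @export
reference_column <- function(msa, ref_seq_id, position) {
  idx <- match(ref_seq_id, msa$seq_id)
  if (is.na(idx)) stop("reference sequence '", ref_seq_id, "' not in MSA",
                       call. = FALSE)
  chars <- strsplit(msa$residues[idx], "", fixed = TRUE)[[1]]
  ungapped <- cumsum(chars != GAP_CHAR)
  col <- which(ungapped == position & chars != GAP_CHAR)
  if (length(col) != 1L)
    stop("position ", position, " beyond the reference sequence length",
         call. = FALSE)
  col
}

#' Filter an MSA on an anchor residue
#'
#' Retains exactly the records whose residue at the rule's column is in the
#' allowed set; gaps (and 'X') fail. The drop count is recorded in the
#' provenance table.
#'
#' @param msa a `coev_msa`.
#' @param rule an [anchor_rule()].
#' @return the filtered MSA.
#' @export
filter_by_anchor <- function(msa, rule) {
  stopifnot(inherits(msa, "coev_msa"), inherits(rule, "anchor_rule"))
  if (rule$column_index > msa$n_columns) {
    stop("configuration error: anchor column ", rule$column_index,
         " exceeds alignment width ", msa$n_columns, call. = FALSE)
  }
  at <- substr(msa$residues, rule$column_index, rule$column_index)
  keep <- at %in% setdiff(rule$allowed_residues, c(GAP_CHAR, "X"))
  n_drop <- sum(!keep)
  msa <- subset_msa(msa, keep)
  add_provenance(msa, "filter_by_anchor", n_drop,
                 paste0("anchor ", rule$description, " [col ",
                        rule$column_index, " not in {",
                        paste(rule$allowed_residues, collapse = ""), "}]"))
}

#' Pair two family alignments by organism and concatenate
#'
#' For each organism present in both families, all cross-product pairs of
#' its family-A and family-B entries are concatenated (A then B). Rows with
#' identical concatenated residue strings are collapsed to one (the first in
#' order is kept); records with no same-organism partner are dropped. With
#' `pairing = "best_one"` each organism instead contributes the single pair
#' whose members are most similar to their family consensus (1:1 pairing).
#'
#' @param msa_a,msa_b `coev_msa` objects with organism IDs populated.
#' @param pairing `"cross_product"` (default) or `"best_one"`.
#' @return an object of class `paired_msa`: organism/sequence IDs,
#'   concatenated `residues`, `len_a`, `len_b`, `boundary` (= `len_a`; a
#'   1-based position p belongs to chain A iff p <= boundary) and a
#'   provenance table covering both inputs plus the pairing stage.
#' @export
pair_alignments <- function(msa_a, msa_b,
                            pairing = c("cross_product", "best_one")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(msa_a, "coev_msa"), inherits(msa_b, "coev_msa"))
  if (anyNA(msa_a$organism_id) || anyNA(msa_b$organism_id))
    stop("organism IDs must be populated on both MSAs before pairing",
         call. = FALSE)
  shared <- intersect(msa_a$organism_id, msa_b$organism_id)
  unpaired_a <- sum(!msa_a$organism_id %in% shared)
  unpaired_b <- sum(!msa_b$organism_id %in% shared)
  if (length(shared) == 0L)
    stop("empty-pairing error: no organism occurs in both families",
         call. = FALSE)

  if (pairing == "best_one") {
    ia <- best_per_organism(msa_a, shared)
    ib <- best_per_organism(msa_b, shared)
    idx_a <- ia[shared]; idx_b <- ib[shared]
    org <- shared
  } else {
    pieces <- lapply(shared, function(o) {
      a <- which(msa_a$organism_id == o)
      b <- which(msa_b$organism_id == o)
      cbind(rep(a, each = length(b)), rep(b, times = length(a)))
    })
    allp <- do.call(rbind, pieces)
    idx_a <- allp[, 1]; idx_b <- allp[, 2]
    org <- msa_a$organism_id[idx_a]
  }

  concat <- paste0(msa_a$residues[idx_a], msa_b$residues[idx_b])
  dup <- duplicated(concat)
  n_dup <- sum(dup)
  keep <- !dup
  if (!any(keep)) stop("empty-pairing error: no rows survive pairing",
                       call. = FALSE)

  prov <- rbind(
    tag_provenance(msa_a$provenance, msa_a$family_label),
    tag_provenance(msa_b$provenance, msa_b$family_label),
    data.frame(stage = c("pair_unpaired_a", "pair_unpaired_b",
                         "pair_duplicates"),
               dropped = c(unpaired_a, unpaired_b, n_dup),
               reason = c(paste0("no same-organism partner (",
                                 msa_a$family_label, ")"),
                          paste0("no same-organism partner (",
                                 msa_b$family_label, ")"),
                          "identical concatenated sequence"),
               stringsAsFactors = FALSE))

  structure(list(organism_id = org[keep],
                 seq_id_a = msa_a$seq_id[idx_a][keep],
                 seq_id_b = msa_b$seq_id[idx_b][keep],
                 residues = concat[keep],
                 len_a = msa_a$n_columns, len_b = msa_b$n_columns,
                 boundary = msa_a$n_columns,
                 family_a = msa_a$family_label, family_b = msa_b$family_label,
                 provenance = prov),
            class = "paired_msa")
}

tag_provenance <- function(prov, label) {
  if (!nrow(prov)) return(prov)
  prov$stage <- paste0(label, ":", prov$stage)
  prov
}

# index of the entry most similar to the family consensus, per organism
best_per_organism <- function(msa, organisms) {
  codes <- encode_residues(msa$residues)
  cons <- apply(codes, 2, function(col) {
    tab <- tabulate(col, nbins = Q_STATES)
    which.max(tab)
  })
  sim <- rowMeans(codes == matrix(cons, nrow(codes), ncol(codes), byrow = TRUE))
  out <- setNames(integer(length(organisms)), organisms)
  for (o in organisms) {
    cand <- which(msa$organism_id == o)
    out[o] <- cand[which.max(sim[cand])]
  }
  out
}

#' @export
print.paired_msa <- function(x, ...) {
  cat("Paired MSA <", x$family_a, "+", x$family_b, ">: ",
      length(x$residues), " rows, ", x$len_a, "+", x$len_b,
      " columns (boundary after column ", x$boundary, ")\n", sep = "")
  invisible(x)
}

#' Write a paired alignment and its provenance table
#'
#' The alignment is written as aligned FASTA with headers
#' `<organism_id>|<idA>+<idB>`; the provenance table as TSV
#' (stage, dropped, reason).
#'
#' @param paired a `paired_msa`.
#' @param fasta_path output FASTA path.
#' @param provenance_path optional TSV path for the provenance table.
#' @return `fasta_path`, invisibly.
#' @export
write_paired_msa <- function(paired, fasta_path, provenance_path = NULL) {
  stopifnot(inherits(paired, "paired_msa"))
  headers <- paste0(paired$organism_id, "|", paired$seq_id_a, "+",
                    paired$seq_id_b)
  set <- Biostrings::BStringSet(setNames(paired$residues, headers))
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(provenance_path)) {
    write.table(paired$provenance, provenance_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
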