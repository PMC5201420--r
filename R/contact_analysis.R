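#' Partition predicted contacts by chain
#'
#' Splits the ranked pair table of a coupling result into intra-subunit and
#' inter-subunit contacts. A pair is inter-subunit iff exactly one of its
#' positions lies in chain A (positions <= boundary). Both tables are sorted
#' by APC score descending.
#'
#' @param result a `coupling_result`.
#' @param min_sep intra-chain separation filter (see [coupling_pairs()]).
#' @return list with elements `intra` and `inter` (data frames).
#' @export
partition_contacts <- function(result, min_sep = 5L) {
  cp <- coupling_pairs(result, min_sep = min_sep)
  list(intra = cp[!cp$inter, , drop = FALSE],
       inter = cp[cp$inter, , drop = FALSE])
}

#' Load residue geometry from a PDB file and/or a z-coordinate table
#'
#' Accepts a membrane-oriented PDB (normal along the z-axis; only Calpha
#' records are used) and/or a 3-column table (chain, position, z). When both
#' are given, table z values override the PDB (the number of overrides is
#' reported in a message). Chain IDs can be remapped (e.g. PDB chain "C" to
#' analysis chain "B") and per-chain residue-numbering offsets applied so
#' that positions match the alignment's 1-based within-chain coordinates.
#'
#' @param pdb_path optional PDB file path.
#' @param z_table optional path to a TSV with columns chain, position, z, or
#'   a data frame with those columns.
#' @param chain_map optional named character vector mapping source chain IDs
#'   to analysis chains, e.g. `c(A = "A", C = "B")`.
#' @param offsets optional named numeric vector; `position_analysis =
#'   position_source - offset[chain]`.
#' @return a `residue_geometry` data frame (chain, pos, x, y, z; x/y/z NA
#'   where unknown).
#' @export
load_geometry <- function(pdb_path = NULL, z_table = NULL, chain_map = NULL,
                          offsets = NULL) {
  geom <- NULL
  if (!is.null(pdb_path)) {
    pdb <- bio3d::read.pdb(pdb_path)
    ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
    geom <- data.frame(chain = ca$chain, pos = as.integer(ca$resno),
                       x = ca$x, y = ca$y, z = ca$z,
                       stringsAsFactors = FALSE)
  }
  tab <- NULL
  if (!is.null(z_table)) {
    tab <- if (is.data.frame(z_table)) z_table else
      read.delim(z_table, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    req <- c("chain", "position", "z")
    if (!all(req %in% names(tab)))
      stop("format error: z-table needs columns chain, position, z",
           call. = FALSE)
    if (anyDuplicated(tab[, c("chain", "position")]))
      stop("format error: duplicate (chain, position) in z-table",
           call. = FALSE)
  }
  if (is.null(geom) && is.null(tab))
    stop("provide a PDB file and/or a z-table", call. = FALSE)
  if (is.null(geom)) {
    geom <- data.frame(chain = as.character(tab$chain),
                       pos = as.integer(tab$position),
                       x = NA_real_, y = NA_real_, z = tab$z,
                       stringsAsFactors = FALSE)
  } else if (!is.null(tab)) {
    key_g <- paste(geom$chain, geom$pos)
    key_t <- paste(tab$chain, tab$position)
    hit <- match(key_g, key_t)
    n_over <- sum(!is.na(hit))
    geom$z[!is.na(hit)] <- tab$z[hit[!is.na(hit)]]
    new <- !(key_t %in% key_g)
    if (any(new)) {
      geom <- rbind(geom,
                    data.frame(chain = as.character(tab$chain[new]),
                               pos = as.integer(tab$position[new]),
                               x = NA_real_, y = NA_real_, z = tab$z[new],
                               stringsAsFactors = FALSE))
    }
    message(n_over, " z value(s) overridden by the z-table")
  }
  if (!is.null(chain_map)) {
    mapped <- chain_map[geom$chain]
    geom$chain <- ifelse(is.na(mapped), geom$chain, mapped)
  }
  if (!is.null(offsets)) {
    off <- offsets[geom$chain]
    off[is.na(off)] <- 0
    geom$pos <- as.integer(geom$pos - off)
  }
  if (anyDuplicated(geom[, c("chain", "pos")]))
    stop("format error: duplicate (chain, position) after mapping",
         call. = FALSE)
  class(geom) <- c("residue_geometry", "data.frame")
  geom
}

# attach d3d and dz columns to a contact table; residues absent from the
# geometry get NA and are listed in attr(, "missing_residues")
annotate_geometry <- function(contacts, geom) {
  key <- paste(geom$chain, geom$pos)
  ki <- match(paste(contacts$chain_i, contacts$pos_i), key)
  kj <- match(paste(contacts$chain_j, contacts$pos_j), key)
  zi <- geom$z[ki]; zj <- geom$z[kj]
  contacts$dz <- abs(zi - zj)
  dx <- geom$x[ki] - geom$x[kj]
  dy <- geom$y[ki] - geom$y[kj]
  dzc <- geom$z[ki] - geom$z[kj]
  contacts$d3d <- sqrt(dx^2 + dy^2 + dzc^2)
  miss <- unique(c(paste(contacts$chain_i, contacts$pos_i)[is.na(ki)],
                   paste(contacts$chain_j, contacts$pos_j)[is.na(kj)]))
  attr(contacts, "missing_residues") <- miss
  contacts
}

#' Filter contacts by separation along the membrane normal
#'
#' A contact is kept iff the two residues are strictly less than `max_dz`
#' Angstrom apart along the membrane normal (z). Removed contacts are
#' retained in the output with `topology = "removed_topology"`; contacts
#' referencing residues missing from the geometry are left unfiltered and
#' flagged `"missing_geometry"`.
#'
#' @param contacts contact data frame with chain_i/pos_i/chain_j/pos_j
#'   columns (e.g. from [coupling_pairs()] or [partition_contacts()]).
#' @param geom a `residue_geometry`.
#' @param max_dz cutoff in Angstrom (default 15; kept iff dz < max_dz).
#' @return the contact table with `dz` and `topology` (`"kept"`,
#'   `"removed_topology"` or `"missing_geometry"`) columns.
#' @export
filter_membrane_normal <- function(contacts, geom, max_dz = 15) {
  contacts <- annotate_geometry(contacts, geom)
  contacts$topology <- ifelse(is.na(contacts$dz), "missing_geometry",
                              ifelse(contacts$dz < max_dz, "kept",
                                     "removed_topology"))
  miss <- attr(contacts, "missing_residues")
  if (length(miss))
    warning(length(miss), " residue(s) missing from geometry; affected ",
            "contacts left unfiltered", call. = FALSE)
  contacts
}

#' Classify contacts against a reference structure
#'
#' Four-way classification of each contact from its Calpha-Calpha distance
#' `d3d` and membrane-normal separation `dz`:
#' \itemize{
#'   \item `spurious` if dz > 15 (impossible across the membrane under any
#'     model; takes precedence over the distance bins),
#'   \item `consistent` if d3d <= 12 (agrees with the reference structure),
#'   \item `alternative_conformer` if 12 < d3d <= 20,
#'   \item `inter_subunit_candidate` if d3d > 20.
#' }
#' Contacts with missing geometry are labelled `unclassified`.
#'
#' @param contacts contact data frame (see [filter_membrane_normal()]).
#' @param geom a `residue_geometry` with Calpha coordinates.
#' @return the contact table with `d3d`, `dz` and `label` columns.
#' @export
classify_structural_contacts <- function(contacts, geom) {
  contacts <- annotate_geometry(contacts, geom)
  contacts$label <- classify_d3d_dz(contacts$d3d, contacts$dz)
  contacts
}

# vectorised classification rule; exported for grid checks
#' Classification rule on (d3d, dz)
#'
#' @param d3d Calpha-Calpha distances (Angstrom).
#' @param dz membrane-normal separations (Angstrom).
#' @return character vector of labels (see
#'   [classify_structural_contacts()]).
#' @export
classify_d3d_dz <- function(d3d, dz) {
  ifelse(is.na(d3d) | is.na(dz), "unclassified",
  ifelse(dz > 15, "spurious",
  ifelse(d3d <= 12, "consistent",
  ifelse(d3d <= 20, "alternative_conformer", "inter_subunit_candidate"))))
}

#' Organism co-occurrence percentages between subsets
#'
#' For each ordered subset pair (S, T): the percentage of organisms having a
#' member of S that also have a member of T (e.g. "94% of organisms with a
#' TatB protein also have a TatA protein"). Empty source subsets yield NA
#' (undefined), not 0.
#'
#' @param subsets a `subset_partition` (see [partition_subsets()]) or a
#'   named list of organism-ID character vectors.
#' @return data frame: subset_a, subset_b, n_a (organisms in S),
#'   pct (percentage of them also in T).
#' @export
cooccurrence_stats <- function(subsets) {
  orgs <- if (inherits(subsets, "subset_partition")) {
    lapply(subsets$subsets, function(s) unique(s$organism_id))
  } else {
    lapply(subsets, unique)
  }
  nm <- names(orgs)
  if (is.null(nm)) nm <- paste0("subset", seq_along(orgs))
  grid <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  pct <- mapply(function(a, b) {
    na <- length(orgs[[a]])
    if (na == 0L) return(NA_real_)
    100 * sum(orgs[[a]] %in% orgs[[b]]) / na
  }, grid$a, grid$b)
  data.frame(subset_a = grid$a, subset_b = grid$b,
             n_a = vapply(orgs[grid$a], length, integer(1)),
             pct = as.numeric(pct), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export contacts as docking restraints
#'
#' Writes the top `top_n` contacts by APC score. `"casp_rr"` emits the CASP
#' residue-residue contact dialect (`i j d_low d_high confidence` on
#' concatenated 1-based positions, preceded by a `PFRMAT RR` record);
#' `"distance_table"` emits chain-qualified TSV rows suitable for manual
#' conversion to unambiguous docking restraints. Rows are sorted by
#' confidence (precision if calibrated, otherwise APC) descending.
#'
#' @param contacts contact data frame (needs i, j, chain/pos columns, apc,
#'   optionally precision).
#' @param path output file path.
#' @param format `"casp_rr"` or `"distance_table"`.
#' @param top_n number of contacts to write; if more than available, all are
#'   written with a warning.
#' @param d_low,d_high distance bounds in Angstrom (defaults 0 and 8).
#' @return `path`, invisibly.
#' @export
export_restraints <- function(contacts, path,
                              format = c("casp_rr", "distance_table"),
                              top_n = nrow(contacts), d_low = 0, d_high = 8) {
  format <- match.arg(format)
  conf <- if (!is.null(contacts$precision) && !all(is.na(contacts$precision)))
    contacts$precision else contacts$apc
  ord <- order(-conf)
  if (top_n > nrow(contacts)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(contacts),
            " available contacts; writing all", call. = FALSE)
    top_n <- nrow(contacts)
  }
  sel <- ord[seq_len(top_n)]
  cc <- contacts[sel, , drop = FALSE]
  conf <- conf[sel]
  if (format == "casp_rr") {
    lines <- c("PFRMAT RR",
               sprintf("%d %d %g %g %.17g", cc$i, cc$j, d_low, d_high, conf),
               "END")
    writeLines(lines, path)
  } else {
    out <- data.frame(chain_i = cc$chain_i, pos_i = cc$pos_i,
                      chain_j = cc$chain_j, pos_j = cc$pos_j,
                      d_low = d_low, d_high = d_high,
                      confidence = conf, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (top_n == 0L) warning("no contacts to export; header-only file written",
                           call. = FALSE)
  invisible(path)
}

#' Read a CASP RR restraint file written by [export_restraints()]
#'
#' @param path file path.
#' @return data frame: i, j, d_low, d_high, confidence.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(PFRMAT|TARGET|MODEL|END|REMARK)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(i = integer(), j = integer(), d_low = numeric(),
                      d_high = numeric(), confidence = numeric()))
  parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
             d_low = as.numeric(parts[, 3]), d_high = as.numeric(parts[, 4]),
             confidence = as.numeric(parts[, 5]))
}
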