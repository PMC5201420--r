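# Small fixtures built in code.

write_fasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# bare MSA object without going through a file
make_msa <- function(residues, organism_id = NULL, seq_id = NULL,
                     family = "test") {
  n <- length(residues)
  if (is.null(seq_id)) seq_id <- paste0("s", seq_len(n))
  if (is.null(organism_id)) organism_id <- as.character(seq_len(n))
  paircoev:::new_msa(seq_id = seq_id, header = seq_id,
                     organism_id = organism_id, residues = residues,
                     family_label = family)
}

# paired MSA straight from concatenated rows (for scorer unit tests)
make_paired <- function(residues, len_a, organism_id = NULL) {
  n <- length(residues)
  if (is.null(organism_id)) organism_id <- as.character(seq_len(n))
  structure(list(organism_id = organism_id,
                 seq_id_a = paste0("a", seq_len(n)),
                 seq_id_b = paste0("b", seq_len(n)),
                 residues = residues,
                 len_a = len_a, len_b = nchar(residues[1]) - len_a,
                 boundary = len_a, family_a = "A", family_b = "B",
                 provenance = data.frame(stage = character(),
                                         dropped = integer(),
                                         reason = character())),
            class = "paired_msa")
}

# i.i.d. random paired alignment (no tree structure)
random_paired <- function(n, len_a, len_b, seed) {
  set.seed(seed)
  aa <- paircoev:::AA20
  rows <- replicate(n, paste(sample(aa, len_a + len_b, replace = TRUE),
                             collapse = ""))
  make_paired(rows, len_a)
}

# coupling result with a given score matrix (for threshold/consensus tests)
make_result <- function(raw, boundary, method = "mfdca") {
  paircoev:::new_coupling_result(method, raw, boundary, list())
}

# standard planted-coupling study conditions
standard_sim <- function(seed, strength = 0.9, n = 500) {
  simulation_config(n_organisms = n, len_a = 30, len_b = 60,
                    planted_pairs = planted_pairs_inter(5, 30, 60, strength),
                    seed = seed)
}

planted_keys <- function(truth) {
  tp <- truth$planted_pairs
  paste(pmin(tp$col_i, tp$col_j), pmax(tp$col_i, tp$col_j))
}
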