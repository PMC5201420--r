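# Amino-acid alphabet used throughout: 20 residues in a fixed order, the
# alignment gap '-', and 'X' for unknowns. For all statistics the alphabet
# has q = 21 states with the gap as the 21st; 'X' is pooled with the gap
# (it carries no residue identity).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
ALPHABET <- c(AA20, GAP_CHAR, "X")
Q_STATES <- 21L
GAP_CODE <- 21L  # 1-based state index of the gap (and of 'X')

#' Encode aligned sequences as an integer matrix
#'
#' Rows are sequences, columns alignment positions; values are 1..21 with
#' 21 = gap (unknown 'X' is pooled with the gap state).
#'
#' @param residues character vector of equal-length aligned sequences.
#' @return integer matrix of dimension `length(residues)` x nchar.
#' @keywords internal
encode_residues <- function(residues) {
  if (length(residues) == 0L) stop("no sequences to encode", call. = FALSE)
  L <- nchar(residues[1])
  m <- matrix(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE),
              nrow = length(residues), ncol = L, byrow = TRUE)
  codes <- match(m, AA20)
  codes[is.na(codes)] <- GAP_CODE
  matrix(as.integer(codes), nrow = length(residues), ncol = L)
}

# Canonical pair index for column pairs i < j of an L-column alignment,
# matching the layout of cpp_weighted_counts: pairs ordered (1,2), (1,3),
# ..., (1,L), (2,3), ... Returns a 2-column matrix (i, j) for all pairs.
pair_index_table <- function(L) {
  i <- rep.int(seq_len(L - 1L), times = (L - 1L):1L)
  j <- unlist(lapply(seq_len(L - 1L), function(a) (a + 1L):L),
              use.names = FALSE)
  cbind(i = i, j = j)
}
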