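#' Redundancy-weight the rows of a paired alignment
#'
#' Each row receives weight 1 / (number of rows, itself included, with
#' fractional identity >= `theta` to it). Identity is computed over all
#' columns of the concatenated row with the gap compared as a 21st symbol.
#' The effective sequence count `m_eff` is the sum of weights.
#'
#' @param paired a `paired_msa`.
#' @param theta identity threshold in (0, 1]; default 0.8.
#' @return an object of class `weighted_msa` wrapping the paired alignment
#'   with `weights`, `theta`, `m_eff` and the encoded residue matrix.
#' @export
compute_weights <- function(paired, theta = 0.8) {
  stopifnot(inherits(paired, "paired_msa"), theta > 0, theta <= 1)
  if (length(paired$residues) == 0L) stop("empty paired alignment",
                                          call. = FALSE)
  codes <- encode_residues(paired$residues)
  w <- cpp_identity_weights(codes, theta)
  structure(list(paired = paired, codes = codes, weights = w, theta = theta,
                 m_eff = sum(w)),
            class = "weighted_msa")
}

#' @export
print.weighted_msa <- function(x, ...) {
  cat("Weighted paired MSA: ", nrow(x$codes), " rows, m_eff = ",
      format(x$m_eff, digits = 6), " at theta = ", x$theta, "\n", sep = "")
  invisible(x)
}

#' Weighted single- and pair-column frequencies with pseudocount
#'
#' Frequencies over the 21-state alphabet (20 residues + gap):
#' `f_i(a) = (lambda/q + sum_r w_r [x_ri = a]) / (lambda + m_eff)` and
#' `f_ij(a,b)` analogously with `lambda/q^2`. Same-column pair frequencies
#' are defined as `f_ii(a,b) = f_i(a) [a = b]`.
#'
#' @param wmsa a `weighted_msa`.
#' @param lambda pseudocount, >= 0. Default `0.5 * m_eff`.
#' @return an object of class `freq_model` with `fi` (q x L), `fij`
#'   (q^2 x L(L-1)/2, pairs i<j in row-wise upper-triangle order),
#'   `lambda`, `q`, `m_eff`, `L` and the chain `boundary`.
#' @export
compute_frequencies <- function(wmsa, lambda = 0.5 * wmsa$m_eff) {
  stopifnot(inherits(wmsa, "weighted_msa"), lambda >= 0)
  q <- Q_STATES
  counts <- cpp_weighted_counts(wmsa$codes, wmsa$weights, q)
  denom <- lambda + wmsa$m_eff
  fi <- (lambda / q + counts$fi) / denom
  fij <- (lambda / q^2 + counts$fij) / denom
  structure(list(fi = fi, fij = fij, lambda = lambda, q = q,
                 m_eff = wmsa$m_eff, L = ncol(fi),
                 boundary = wmsa$paired$boundary),
            class = "freq_model")
}

new_coupling_result <- function(method, raw, boundary, params,
                                precision = NULL) {
  diag(raw) <- NA_real_
  apc <- apc_correct(raw)
  structure(list(method = method, raw = raw, apc = apc,
                 precision = precision, boundary = boundary,
                 params = params),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Coupling result <", x$method, ">: ", nrow(x$raw), " columns, boundary ",
      x$boundary, if (!is.null(x$precision)) ", precision calibrated" else "",
      "\n", sep = "")
  invisible(x)
}

# Covariance matrix over q-1 = 20 states per column (the gap state is the
# dropped reference), dimension 20L x 20L.
build_covariance <- function(freq) {
  qr <- freq$q - 1L
  L <- freq$L
  fi <- freq$fi[seq_len(qr), , drop = FALSE]
  C <- matrix(0, qr * L, qr * L)
  pt <- pair_index_table(L)
  for (p in seq_len(nrow(pt))) {
    i <- pt[p, 1]; j <- pt[p, 2]
    blk <- matrix(freq$fij[, p], freq$q, freq$q)[seq_len(qr), seq_len(qr)] -
      tcrossprod(fi[, i], fi[, j])
    ri <- (i - 1L) * qr + seq_len(qr)
    rj <- (j - 1L) * qr + seq_len(qr)
    C[ri, rj] <- blk
    C[rj, ri] <- t(blk)
  }
  for (i in seq_len(L)) {
    ri <- (i - 1L) * qr + seq_len(qr)
    C[ri, ri] <- diag(fi[, i], qr) - tcrossprod(fi[, i])
  }
  C
}

# Frobenius norm of each off-diagonal block of a coupling (precision-like)
# matrix after shifting the block to zero-sum gauge.
block_frobenius <- function(J, L, qr) {
  raw <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * qr + seq_len(qr)
    for (j in (i + 1L):L) {
      rj <- (j - 1L) * qr + seq_len(qr)
      K <- J[ri, rj]
      K <- K - outer(rowMeans(K), rep(1, qr)) -
        outer(rep(1, qr), colMeans(K)) + mean(K)
      raw[i, j] <- raw[j, i] <- sqrt(sum(K^2))
    }
  }
  raw
}

#' Mean-field direct coupling analysis
#'
#' Builds the 20-state covariance matrix (gap dropped as the reference
#' state), inverts it, and scores each column pair by the Frobenius norm of
#' the corresponding block of the negated inverse after a zero-sum gauge
#' shift, followed by the average product correction. The pseudocount in the
#' frequency model regularises the covariance.
#'
#' @param freq a `freq_model`.
#' @param ridge additional diagonal regularisation added before inversion
#'   (default 0; the pseudocount normally suffices).
#' @return a `coupling_result` with `method = "mfdca"`.
#' @export
score_mfdca <- function(freq, ridge = 0) {
  stopifnot(inherits(freq, "freq_model"))
  qr <- freq$q - 1L
  C <- build_covariance(freq)
  if (ridge > 0) diag(C) <- diag(C) + ridge
  J <- tryCatch(-solve(C), error = function(e) {
    stop("numerical-regularization error: covariance inversion failed (",
         conditionMessage(e),
         "); increase the pseudocount lambda or the ridge", call. = FALSE)
  })
  raw <- block_frobenius(J, freq$L, qr)
  new_coupling_result("mfdca", raw, freq$boundary,
                      list(lambda = freq$lambda, ridge = ridge, q = freq$q))
}

#' Sparse inverse covariance coupling analysis
#'
#' As [score_mfdca()], but the inverse covariance is estimated under an L1
#' sparsity penalty by graphical-lasso block coordinate descent (the
#' approach of sparse-inverse-covariance contact predictors). Scoring
#' (zero-sum gauge, block Frobenius norm, APC) is shared with the mean-field
#' scorer.
#'
#' @param freq a `freq_model`.
#' @param rho L1 penalty, > 0. Default `mean(|C|)` over the off-diagonal
#'   entries of the covariance — the scale at which soft-thresholding
#'   actually sparsifies the couplings (matching the flat ~1e-3 penalty of
#'   the established sparse-inverse-covariance contact predictors on
#'   amino-acid indicator covariances).
#' @param max_sweeps,tol,inner_max coordinate-descent controls; convergence
#'   is declared when the mean absolute change of the working covariance in
#'   a sweep drops below `tol * mean(|C_offdiag|)`.
#' @return a `coupling_result` with `method = "sparse_l1"`.
#' @export
score_sparse_l1 <- function(freq, rho = NULL, max_sweeps = 12L, tol = 3e-2,
                            inner_max = 8L) {
  stopifnot(inherits(freq, "freq_model"))
  qr <- freq$q - 1L
  C <- build_covariance(freq)
  if (is.null(rho)) {
    off <- abs(C); diag(off) <- NA
    rho <- mean(off, na.rm = TRUE)
  }
  stopifnot(rho > 0)
  fit <- cpp_glasso(C, rho, as.integer(max_sweeps), tol, as.integer(inner_max))
  if (!fit$converged) {
    stop("convergence error: graphical lasso did not converge in ",
         fit$sweeps, " sweeps (last max column change ",
         format(fit$last_delta, digits = 4), ", tolerance ",
         format(fit$tol_used, digits = 4),
         "); raise max_sweeps or the penalty rho", call. = FALSE)
  }
  raw <- block_frobenius(-fit$theta, freq$L, qr)
  new_coupling_result("sparse_l1", raw, freq$boundary,
                      list(lambda = freq$lambda, rho = rho,
                           sweeps = fit$sweeps, q = freq$q))
}

#' Mutual information coupling scores
#'
#' Scores each column pair by the weighted mutual information
#' `sum_ab f_ij(a,b) log2(f_ij(a,b) / (f_i(a) f_j(b)))` in bits, followed by
#' the average product correction. Serves both as the third, methodologically
#' distinct scorer of the consensus and as a brute-force oracle for the
#' model-based scorers.
#'
#' @param wmsa a `weighted_msa`.
#' @param lambda pseudocount passed to [compute_frequencies()]; default 0
#'   (plain empirical weighted frequencies).
#' @return a `coupling_result` with `method = "mutual_information"`.
#' @export
score_mutual_information <- function(wmsa, lambda = 0) {
  stopifnot(inherits(wmsa, "weighted_msa"))
  freq <- compute_frequencies(wmsa, lambda = lambda)
  q <- freq$q
  pt <- pair_index_table(freq$L)
  a_idx <- rep(seq_len(q), times = q)
  b_idx <- rep(seq_len(q), each = q)
  fprod <- freq$fi[a_idx, pt[, 1], drop = FALSE] *
    freq$fi[b_idx, pt[, 2], drop = FALSE]
  term <- freq$fij * log2(freq$fij / fprod)
  term[freq$fij == 0] <- 0
  mi <- colSums(term)
  raw <- matrix(0, freq$L, freq$L)
  raw[cbind(pt[, 1], pt[, 2])] <- mi
  raw[cbind(pt[, 2], pt[, 1])] <- mi
  new_coupling_result("mutual_information", raw, freq$boundary,
                      list(lambda = lambda, q = q))
}

#' Average product correction
#'
#' `apc(i,j) = raw(i,j) - mean_i * mean_j / grand_mean`, where the means are
#' taken over all finite entries of the matrix. Coupling matrices produced
#' by the scorers carry an `NA` diagonal, so for them the means run over the
#' off-diagonal entries; a full matrix (diagonal present, e.g. a rank-one
#' `s %o% s`) cancels exactly to zero.
#'
#' @param raw square symmetric numeric matrix; `NA` entries are ignored in
#'   the means and preserved in the output.
#' @return the corrected matrix, same shape as `raw`.
#' @export
apc_correct <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  grand <- mean(raw, na.rm = TRUE)
  if (!is.finite(grand) || grand == 0) {
    warning("grand mean of the score matrix is zero; returning raw scores",
            call. = FALSE)
    return(raw)
  }
  rmean <- rowMeans(raw, na.rm = TRUE)
  cmean <- colMeans(raw, na.rm = TRUE)
  raw - outer(rmean, cmean) / grand
}

#' Map APC scores to a pseudo-precision in [0, 1]
#'
#' A strictly monotone logistic map of the z-score of each APC value over
#' all scored pairs: `precision = plogis((z - center) / scale)`. This is an
#' explicit pseudo-precision — a calibrated probability would require
#' labelled training contacts — so raw and APC scores are always carried
#' alongside.
#'
#' @param result a `coupling_result`.
#' @param calibration list with elements `center` (z-score at which
#'   precision = 0.5; default 3) and `scale` (logistic scale in z units;
#'   default 1).
#' @return the `coupling_result` with `precision` populated.
#' @export
estimate_precision <- function(result, calibration = list(center = 3,
                                                          scale = 1)) {
  stopifnot(inherits(result, "coupling_result"))
  apc <- result$apc
  vals <- apc[upper.tri(apc)]
  mu <- mean(vals, na.rm = TRUE)
  s <- stats::sd(vals, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) apc * 0 else (apc - mu) / s
  result$precision <- stats::plogis((z - calibration$center) /
                                      calibration$scale)
  result$params$calibration <- calibration
  result
}

#' Significance threshold at k standard deviations above the mean
#'
#' `value = mean + k * SD` (population SD) over the selected score
#' population; pairs at or above the value are flagged significant. The
#' population is all column pairs (i < j), restricted to inter- or
#' intra-chain pairs on request.
#'
#' @param result a `coupling_result`.
#' @param k SD multiplier (e.g. 7 for a whole-dataset threshold, 6 for an
#'   inter-subunit threshold).
#' @param subset `"all_pairs"`, `"inter_subunit_only"` or
#'   `"intra_subunit_only"`.
#' @param score which matrix to threshold: `"apc"` (default), `"raw"`, or
#'   `"precision"` (requires [estimate_precision()]).
#' @return an object of class `threshold_spec`: list with `k`, `subset`,
#'   `score`, `value`, and `n` (population size).
#' @export
sd_threshold <- function(result, k,
                         subset = c("all_pairs", "inter_subunit_only",
                                    "intra_subunit_only"),
                         score = c("apc", "raw", "precision")) {
  subset <- match.arg(subset)
  score <- match.arg(score)
  stopifnot(inherits(result, "coupling_result"))
  m <- result[[score]]
  if (is.null(m)) stop("score '", score, "' not available; run ",
                       "estimate_precision() first", call. = FALSE)
  L <- nrow(m)
  pt <- pair_index_table(L)
  keep <- switch(subset,
                 all_pairs = rep(TRUE, nrow(pt)),
                 inter_subunit_only =
                   (pt[, 1] <= result$boundary) != (pt[, 2] <= result$boundary),
                 intra_subunit_only =
                   (pt[, 1] <= result$boundary) == (pt[, 2] <= result$boundary))
  vals <- m[cbind(pt[keep, 1], pt[keep, 2])]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty-subset error: no scored pairs in '",
                               subset, "'", call. = FALSE)
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))  # population SD
  structure(list(k = k, subset = subset, score = score,
                 value = mu + k * sdev, mean = mu, sd = sdev,
                 n = length(vals)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("Threshold: mean + ", x$k, "SD over ", x$subset, " (", x$score, ") = ",
      format(x$value, digits = 6), " [n = ", x$n, "]\n", sep = "")
  invisible(x)
}

#' Ranked pair table of a coupling result
#'
#' All scored column pairs sorted by APC score descending. Intra-chain pairs
#' closer than `min_sep` positions are excluded by default (trivial backbone
#' correlations); inter-chain pairs have no separation filter. Positions are
#' reported both in concatenated coordinates (`i`, `j`) and per chain
#' (`pos_i`, `pos_j`, 1-based within chain).
#'
#' @param result a `coupling_result`.
#' @param min_sep minimum intra-chain separation |i - j| kept (default 5).
#' @return a data frame: i, j, chain_i, chain_j, pos_i, pos_j, raw, apc,
#'   precision (NA unless calibrated), inter.
#' @export
coupling_pairs <- function(result, min_sep = 5L) {
  stopifnot(inherits(result, "coupling_result"))
  L <- nrow(result$raw)
  b <- result$boundary
  pt <- pair_index_table(L)
  chain_i <- ifelse(pt[, 1] <= b, "A", "B")
  chain_j <- ifelse(pt[, 2] <= b, "A", "B")
  inter <- chain_i != chain_j
  keep <- inter | (abs(pt[, 1] - pt[, 2]) >= min_sep)
  pt <- pt[keep, , drop = FALSE]
  chain_i <- chain_i[keep]; chain_j <- chain_j[keep]; inter <- inter[keep]
  idx <- cbind(pt[, 1], pt[, 2])
  prec <- if (is.null(result$precision)) rep(NA_real_, nrow(pt))
          else result$precision[idx]
  out <- data.frame(i = pt[, 1], j = pt[, 2],
                    chain_i = chain_i, chain_j = chain_j,
                    pos_i = ifelse(pt[, 1] <= b, pt[, 1], pt[, 1] - b),
                    pos_j = ifelse(pt[, 2] <= b, pt[, 2], pt[, 2] - b),
                    raw = result$raw[idx], apc = result$apc[idx],
                    precision = prec, inter = inter,
                    stringsAsFactors = FALSE)
  out[order(-out$apc, out$i, out$j), , drop = FALSE]
}

#' Consensus contacts across scoring methods
#'
#' The set of column pairs present in the top `top_n` (by APC) of every
#' supplied coupling result, annotated with the per-method rank of each
#' pair.
#'
#' @param results list of >= 2 `coupling_result` objects over the same
#'   paired alignment.
#' @param top_n number of top-ranked pairs taken per method.
#' @param min_sep intra-chain separation filter applied to each ranking
#'   (see [coupling_pairs()]).
#' @return data frame of consensus pairs (i, j, chain_i, chain_j, inter, one
#'   `rank_<method>` column per method), sorted by mean rank.
#' @export
consensus_contacts <- function(results, top_n, min_sep = 5L) {
  stopifnot(is.list(results), length(results) >= 2L)
  Ls <- vapply(results, function(r) nrow(r$raw), integer(1))
  bs <- vapply(results, function(r) r$boundary, numeric(1))
  if (length(unique(Ls)) != 1L || length(unique(bs)) != 1L)
    stop("incompatible-results error: coupling results differ in dimension ",
         "or boundary", call. = FALSE)
  methods <- vapply(results, function(r) r$method, character(1))
  ranked <- lapply(results, function(r) {
    cp <- coupling_pairs(r, min_sep = min_sep)
    cp$rank <- seq_len(nrow(cp))
    cp
  })
  keys <- lapply(ranked, function(cp) paste(cp$i, cp$j)[seq_len(min(top_n,
                                                                   nrow(cp)))])
  common <- Reduce(intersect, keys)
  base <- ranked[[1]]
  base_key <- paste(base$i, base$j)
  out <- base[match(common, base_key),
              c("i", "j", "chain_i", "chain_j", "pos_i", "pos_j", "inter"),
              drop = FALSE]
  for (m in seq_along(results)) {
    rk <- ranked[[m]]$rank[match(common, paste(ranked[[m]]$i, ranked[[m]]$j))]
    out[[paste0("rank_", methods[m])]] <- rk
  }
  if (nrow(out)) {
    mean_rank <- rowMeans(out[, grepl("^rank_", names(out)), drop = FALSE])
    out <- out[order(mean_rank), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write per-method contact tables
#'
#' Tab-separated table (i, j, chain_i, chain_j, pos_i, pos_j, method, raw,
#' apc, precision, flagged) for one coupling result; `flagged` marks pairs
#' at or above the supplied threshold.
#'
#' @param result a `coupling_result`.
#' @param path output TSV path.
#' @param threshold optional `threshold_spec` used for the `flagged` column.
#' @param min_sep see [coupling_pairs()].
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(result, path, threshold = NULL,
                                min_sep = 5L) {
  cp <- coupling_pairs(result, min_sep = min_sep)
  cp$method <- result$method
  cp$flagged <- if (is.null(threshold)) NA else
    cp[[threshold$score]] >= threshold$value
  write.table(cp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
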