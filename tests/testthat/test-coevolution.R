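test_that("identity weights match the definition and a brute-force oracle", {
  # three identical rows form one cluster of three
  w3 <- compute_weights(make_paired(rep("AGAGAG", 3), 3), theta = 0.8)
  expect_equal(w3$weights, rep(1 / 3, 3))
  expect_equal(w3$m_eff, 1)

  # 50% identity is below theta = 0.8: both rows keep weight 1
  w2 <- compute_weights(make_paired(c("AGAG", "AGCC"), 2), theta = 0.8)
  expect_equal(w2$weights, c(1, 1))
  expect_equal(w2$m_eff, 2)

  # brute-force oracle on a random alignment
  paired <- random_paired(30, 4, 5, seed = 5)
  wm <- compute_weights(paired, theta = 0.5)
  codes <- paircoev:::encode_residues(paired$residues)
  L <- ncol(codes)
  oracle <- vapply(seq_len(nrow(codes)), function(r) {
    idents <- rowMeans(codes == matrix(codes[r, ], nrow(codes), L,
                                       byrow = TRUE))
    1 / sum(idents >= 0.5)
  }, numeric(1))
  expect_equal(wm$weights, oracle)
})

test_that("i.i.d. rows are effectively independent: m_eff = N", {
  paired <- random_paired(200, 25, 25, seed = 9)
  wm <- compute_weights(paired, theta = 0.8)
  expect_equal(wm$m_eff, 200)
})

test_that("m_eff decreases (or stays equal) as theta decreases", {
  sim <- simulate_paired_msa(simulation_config(n_organisms = 60, len_a = 10,
                                               len_b = 12, seed = 2))
  paired <- pair_alignments(sim$msa_a, sim$msa_b)
  meffs <- vapply(c(1, 0.8, 0.5, 0.2),
                  function(th) compute_weights(paired, th)$m_eff, numeric(1))
  expect_true(all(diff(meffs) <= 1e-12))
})

test_that("frequencies: pseudocount limits, empirical counts, marginals", {
  paired <- make_paired("AG", 1)
  wm <- compute_weights(paired, theta = 1)

  # lambda = 0 reproduces plain empirical frequencies
  f0 <- compute_frequencies(wm, lambda = 0)
  expect_equal(f0$fi[match("A", paircoev:::AA20), 1], 1)
  expect_equal(f0$fi[match("G", paircoev:::AA20), 2], 1)

  # lambda >> m_eff: all frequencies tend to 1/q
  finf <- compute_frequencies(wm, lambda = 1e9 * wm$m_eff)
  expect_true(max(abs(finf$fi - 1 / 21)) < 1e-6)

  # pair marginals are consistent with singles on a random alignment
  paired2 <- random_paired(40, 4, 4, seed = 1)
  wm2 <- compute_weights(paired2, theta = 0.8)
  fr <- compute_frequencies(wm2)
  pt <- paircoev:::pair_index_table(fr$L)
  worst <- 0
  for (p in seq_len(nrow(pt))) {
    blk <- matrix(fr$fij[, p], fr$q, fr$q)
    worst <- max(worst,
                 max(abs(rowSums(blk) - fr$fi[, pt[p, 1]])),
                 max(abs(colSums(blk) - fr$fi[, pt[p, 2]])))
  }
  expect_lt(worst, 1e-12)
  # columns sum to one
  expect_true(max(abs(colSums(fr$fi) - 1)) < 1e-12)

  # lambda = 0 with unit weights equals direct counting (oracle)
  codes <- paircoev:::encode_residues(paired2$residues)
  f_direct <- vapply(seq_len(ncol(codes)), function(col)
    tabulate(codes[, col], 21), numeric(21)) / nrow(codes)
  wm_unit <- compute_weights(paired2, theta = 1)
  expect_equal(unname(compute_frequencies(wm_unit, 0)$fi), f_direct)
})

test_that("mutual information: closed forms and null behaviour", {
  # identical columns, each uniform over two letters: exactly 1 bit
  paired <- make_paired(c("AA", "GG"), 1)
  wm <- compute_weights(paired, theta = 1)
  mi <- score_mutual_information(wm, lambda = 0)
  expect_equal(mi$raw[1, 2], 1, tolerance = 1e-12)

  # independent two-letter columns at large N: raw MI is bias-only, < 0.02
  set.seed(4)
  rows <- paste0(sample(c("A", "G"), 2000, TRUE),
                 sample(c("L", "P"), 2000, TRUE))
  wm2 <- compute_weights(make_paired(rows, 1), theta = 1)
  mi2 <- score_mutual_information(wm2, lambda = 0)
  expect_lt(mi2$raw[1, 2], 0.02)

  # non-negativity at lambda = 0 and symmetry
  paired3 <- random_paired(50, 3, 3, seed = 7)
  mi3 <- score_mutual_information(compute_weights(paired3), lambda = 0)
  off <- mi3$raw[upper.tri(mi3$raw)]
  expect_true(all(off >= -1e-12))
  expect_equal(mi3$raw, t(mi3$raw))
})

test_that("apc_correct: analytic cancellations and hand-checked example", {
  # constant matrix (diagonal present) -> exactly zero
  m <- matrix(3, 5, 5)
  expect_equal(apc_correct(m), matrix(0, 5, 5))

  # rank-one s %o% s -> exactly zero
  s <- c(1, 2, 3, 4.5)
  expect_equal(apc_correct(s %o% s), matrix(0, 4, 4), tolerance = 1e-12)

  # NA-diagonal 3x3: compare with the off-diagonal means formula by hand
  raw <- matrix(c(NA, 2, 1, 2, NA, 1, 1, 1, NA), 3, 3)
  rm <- c(mean(c(2, 1)), mean(c(2, 1)), mean(c(1, 1)))
  g <- mean(c(2, 1, 2, 1, 1, 1))
  expected <- raw - outer(rm, rm) / g
  expect_equal(apc_correct(raw), expected, tolerance = 1e-12)

  # zero grand mean returns the input with a warning
  z <- matrix(0, 3, 3)
  expect_warning(out <- apc_correct(z), "grand mean")
  expect_equal(out, z)
})

test_that("mfdca is symmetric, null-calibrated, and finds a planted pair", {
  # null: independent i.i.d. columns, no pair crosses a 6 SD threshold
  exceed <- vapply(1:3, function(seed) {
    paired <- random_paired(500, 5, 5, seed = seed)
    fr <- compute_frequencies(compute_weights(paired))
    r <- score_mfdca(fr)
    expect_equal(r$raw, t(r$raw))
    expect_true(all(is.na(diag(r$raw))))
    vals <- r$apc[upper.tri(r$apc)]
    th <- mean(vals) + 6 * sqrt(mean((vals - mean(vals))^2))
    # true-zero couplings scatter around zero
    expect_lt(abs(mean(vals)), 3 * sd(vals))
    sum(vals >= th)
  }, numeric(1))
  expect_gte(sum(exceed == 0), 2)

  # planted signal: a column copied with 5% noise among 8 decoys ranks first
  set.seed(10)
  n <- 500
  c1 <- sample(c("A", "G"), n, TRUE)
  c2 <- ifelse(runif(n) < 0.05, sample(c("A", "G"), n, TRUE), c1)
  decoys <- replicate(8, sample(paircoev:::AA20, n, TRUE))
  rows <- apply(cbind(c1, c2, decoys), 1, paste, collapse = "")
  fr <- compute_frequencies(compute_weights(make_paired(rows, 5)))
  r <- score_mfdca(fr)
  cp <- coupling_pairs(r, min_sep = 0)
  expect_equal(c(cp$i[1], cp$j[1]), c(1, 2))
})

test_that("sparse_l1: penalty-dominated limit, planted pair, mfdca overlap", {
  set.seed(11)
  n <- 500
  c1 <- sample(c("A", "G"), n, TRUE)
  c2 <- ifelse(runif(n) < 0.05, sample(c("A", "G"), n, TRUE), c1)
  decoys <- replicate(8, sample(paircoev:::AA20, n, TRUE))
  rows <- apply(cbind(c1, c2, decoys), 1, paste, collapse = "")
  fr <- compute_frequencies(compute_weights(make_paired(rows, 5)))

  # a huge penalty kills every coupling (all-zero scores also trip the
  # grand-mean warning in the APC step)
  expect_warning(r_big <- score_sparse_l1(fr, rho = 100), "grand mean")
  expect_true(all(r_big$raw[upper.tri(r_big$raw)] == 0))

  # default penalty: the copied pair ranks first
  r <- score_sparse_l1(fr)
  cp <- coupling_pairs(r, min_sep = 0)
  expect_equal(c(cp$i[1], cp$j[1]), c(1, 2))

  # cross-method consistency with mfdca on the same data: top pair agrees
  r_mf <- score_mfdca(fr)
  cp_mf <- coupling_pairs(r_mf, min_sep = 0)
  expect_equal(cp$i[1:2] + 1i * cp$j[1:2], cp_mf$i[1:2] + 1i * cp_mf$j[1:2])
})

test_that("estimate_precision is monotone and bounded", {
  raw <- matrix(runif(64), 8, 8); raw <- raw + t(raw)
  r <- make_result(raw, 4)
  r <- estimate_precision(r)
  u <- upper.tri(raw)
  expect_true(all(r$precision[u] >= 0 & r$precision[u] <= 1))
  ord <- order(r$apc[u])
  expect_true(all(diff(r$precision[u][ord]) >= -1e-12))

  # constant scores map to a constant precision
  rc <- estimate_precision(make_result(matrix(1, 4, 4), 2))
  expect_equal(length(unique(rc$precision[upper.tri(rc$precision)])), 1L)
})

test_that("sd_threshold closed forms, subsets and monotonicity in k", {
  m <- matrix(0.1, 6, 6)
  r <- make_result(m, 3)
  r$apc <- m; diag(r$apc) <- NA  # bypass APC for the closed-form check
  th <- sd_threshold(r, 7)
  expect_equal(th$value, 0.1)

  # {0, 1} population: mean .5, population SD .5, k=1 -> 1.0
  m2 <- matrix(0, 4, 4); m2[1, 2] <- m2[2, 1] <- 1
  r2 <- make_result(m2, 2); r2$apc <- m2; diag(r2$apc) <- NA
  # 6 upper pairs: one 1, five 0 -> mean 1/6; use a 2-value matrix instead
  vals <- c(0, 1, 0, 1, 0, 1)
  m3 <- matrix(0, 4, 4); m3[upper.tri(m3)] <- vals; m3 <- m3 + t(m3)
  r3 <- make_result(m3, 2); r3$apc <- m3; diag(r3$apc) <- NA
  th3 <- sd_threshold(r3, 1)
  expect_equal(th3$value, 0.5 + 0.5)

  ks <- c(0, 1, 2, 6, 7)
  vs <- vapply(ks, function(k) sd_threshold(r3, k)$value, numeric(1))
  expect_true(all(diff(vs) >= 0))

  # subset selectors partition the pair population
  th_all <- sd_threshold(r3, 1, "all_pairs")
  th_int <- sd_threshold(r3, 1, "inter_subunit_only")
  th_intra <- sd_threshold(r3, 1, "intra_subunit_only")
  expect_equal(th_int$n + th_intra$n, th_all$n)
})

test_that("consensus_contacts: identity, disjoint and rank annotation", {
  L <- 10; b <- 5
  base <- matrix(0, L, L)
  vals <- seq(0.9, 0.1, length.out = 4)
  pairs <- list(c(1, 6), c(2, 7), c(3, 8), c(4, 9))
  for (k in seq_along(pairs)) {
    base[pairs[[k]][1], pairs[[k]][2]] <- vals[k]
    base[pairs[[k]][2], pairs[[k]][1]] <- vals[k]
  }
  r1 <- make_result(base, b, "mfdca"); r1$apc <- base; diag(r1$apc) <- NA
  r2 <- r1; r2$method <- "mutual_information"
  cons <- consensus_contacts(list(r1, r2), top_n = 3)
  expect_equal(nrow(cons), 3L)
  expect_equal(cons$rank_mfdca, cons$rank_mutual_information)

  # disjoint rankings intersect to nothing
  flip <- base[L:1, L:1]
  r3 <- make_result(flip, b, "sparse_l1"); r3$apc <- flip; diag(r3$apc) <- NA
  cons2 <- consensus_contacts(list(r1, r3), top_n = 2)
  expect_equal(nrow(cons2), 0L)

  r_dim <- suppressWarnings(make_result(matrix(0, 4, 4), 2))
  expect_error(consensus_contacts(list(r1, r_dim), 3),
               "incompatible-results")
})

test_that("scores are invariant to row order and equivariant to columns", {
  sim <- simulate_paired_msa(standard_sim(6, n = 80))
  paired <- pair_alignments(sim$msa_a, sim$msa_b)
  small <- make_paired(substr(paired$residues, 1, 20)[1:60], 8)
  wm <- compute_weights(small)
  mi <- score_mutual_information(wm)

  # permute rows: identical matrices
  perm <- sample(seq_along(small$residues))
  small_p <- make_paired(small$residues[perm], 8)
  mi_p <- score_mutual_information(compute_weights(small_p))
  expect_equal(mi$raw, mi_p$raw)

  # permute columns within each chain: scores permute identically
  cols <- c(sample(1:8), 8 + sample(1:12))
  rows_c <- vapply(strsplit(small$residues, ""),
                   function(ch) paste(ch[cols], collapse = ""), character(1))
  mi_c <- score_mutual_information(compute_weights(make_paired(rows_c, 8)))
  expect_equal(mi_c$raw, mi$raw[cols, cols], tolerance = 1e-12)
})

test_that("write_contact_table emits flagged TSV", {
  sim <- simulate_paired_msa(standard_sim(8, n = 60))
  paired <- pair_alignments(sim$msa_a, sim$msa_b)
  wm <- compute_weights(paired)
  mi <- estimate_precision(score_mutual_information(wm))
  th <- sd_threshold(mi, 2)
  f <- tempfile(fileext = ".tsv")
  write_contact_table(mi, f, threshold = th)
  tab <- read.delim(f)
  expect_true(all(c("i", "j", "apc", "precision", "flagged") %in% names(tab)))
  expect_equal(sum(tab$flagged), sum(tab$apc >= th$value))
})
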