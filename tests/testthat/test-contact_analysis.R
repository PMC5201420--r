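test_that("partition_contacts splits by the chain boundary, half-open", {
  L <- 60; b <- 30
  raw <- matrix(0, L, L)
  set.seed(1)
  raw[upper.tri(raw)] <- runif(sum(upper.tri(raw)))
  raw <- raw + t(raw)
  r <- make_result(raw, b)
  parts <- partition_contacts(r, min_sep = 0)
  expect_true(all((parts$inter$i <= b) != (parts$inter$j <= b)))
  expect_true(all((parts$intra$i <= b) == (parts$intra$j <= b)))
  # edge: (30, 31) straddles the boundary, (30, 29) does not
  expect_true(any(parts$inter$i == 30 & parts$inter$j == 31))
  # sorted by APC descending
  expect_true(all(diff(parts$inter$apc) <= 1e-12))
  # nothing lost
  expect_equal(nrow(parts$inter) + nrow(parts$intra), L * (L - 1) / 2)
})

test_that("load_geometry reads CA records, z-tables, and precedence", {
  geom0 <- data.frame(chain = c("A", "A", "A"), pos = 1:3,
                      x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 10, 20))
  pdb <- tempfile(fileext = ".pdb")
  paircoev:::write_ca_pdb(geom0, pdb)
  g <- load_geometry(pdb_path = pdb)
  expect_equal(g$z, c(0, 10, 20))
  expect_equal(g$pos, 1:3)

  # duplicate (chain, position) rows in a z-table are a format error
  ztab <- data.frame(chain = c("A", "A"), position = c(1, 1), z = c(0, 5))
  expect_error(load_geometry(z_table = ztab), "format error")

  # table overrides PDB z values
  zt <- data.frame(chain = "A", position = 2, z = 99)
  expect_message(g2 <- load_geometry(pdb_path = pdb, z_table = zt),
                 "overridden")
  expect_equal(g2$z[g2$pos == 2], 99)

  # chain remapping and numbering offsets
  g3 <- load_geometry(pdb_path = pdb, chain_map = c(A = "B"),
                      offsets = c(B = -10))
  expect_equal(unique(g3$chain), "B")
  expect_equal(g3$pos, 11:13)
})

test_that("filter_membrane_normal keeps dz < 15 strictly, loses nothing", {
  geom <- data.frame(chain = rep(c("A", "B"), each = 3), pos = rep(1:3, 2),
                     x = 0, y = 0,
                     z = c(0, 0, 0, 0, 15, 20))
  contacts <- data.frame(i = c(1, 2, 3), j = c(4, 5, 6),
                         chain_i = "A", pos_i = 1:3,
                         chain_j = "B", pos_j = 1:3,
                         apc = c(0.3, 0.2, 0.1))
  out <- filter_membrane_normal(contacts, geom)
  expect_equal(out$topology, c("kept", "removed_topology",
                               "removed_topology"))  # dz = 0, 15, 20
  expect_equal(nrow(out), nrow(contacts))

  # max_dz = Inf keeps everything
  out_inf <- filter_membrane_normal(contacts, geom, max_dz = Inf)
  expect_true(all(out_inf$topology == "kept"))

  # a residue missing from the geometry leaves the contact unfiltered
  contacts2 <- rbind(contacts,
                     data.frame(i = 1, j = 7, chain_i = "A", pos_i = 1,
                                chain_j = "B", pos_j = 9, apc = 0.05))
  expect_warning(out2 <- filter_membrane_normal(contacts2, geom), "missing")
  expect_equal(out2$topology[4], "missing_geometry")
})

test_that("structural classification honours the 12/20/15 boundaries", {
  expect_equal(classify_d3d_dz(10, 5), "consistent")
  expect_equal(classify_d3d_dz(12, 5), "consistent")        # inclusive
  expect_equal(classify_d3d_dz(14, 5), "alternative_conformer")
  expect_equal(classify_d3d_dz(20, 5), "alternative_conformer")  # inclusive
  expect_equal(classify_d3d_dz(25, 5), "inter_subunit_candidate")
  expect_equal(classify_d3d_dz(14, 16), "spurious")  # z-rule precedence
  expect_equal(classify_d3d_dz(5, 15), "consistent") # dz = 15 not spurious
  expect_equal(classify_d3d_dz(NA, 5), "unclassified")

  # end-to-end through geometry
  geom <- data.frame(chain = c("A", "B", "B"), pos = c(1, 1, 2),
                     x = c(0, 10, 0), y = 0, z = c(0, 0, 18))
  contacts <- data.frame(i = c(1, 1), j = c(31, 32),
                         chain_i = "A", pos_i = 1,
                         chain_j = "B", pos_j = c(1, 2), apc = 0.1)
  cl <- classify_structural_contacts(contacts, geom)
  expect_equal(cl$label, c("consistent", "spurious"))
  expect_equal(cl$d3d[1], 10)
  expect_equal(cl$dz[2], 18)
})

test_that("cooccurrence_stats computes directed percentages", {
  co <- cooccurrence_stats(list(S = c("X", "Y"), T = c("X", "Y")))
  expect_equal(co$pct, c(100, 100))
  co2 <- cooccurrence_stats(list(S = c("X", "Y"), T = "X"))
  expect_equal(co2$pct[co2$subset_a == "S"], 50)
  expect_equal(co2$pct[co2$subset_a == "T"], 100)
  # empty source subset is undefined, not zero
  co3 <- cooccurrence_stats(list(S = character(), T = "X"))
  expect_true(is.na(co3$pct[co3$subset_a == "S"]))
})

test_that("restraint export sorts, truncates, round-trips and warns", {
  contacts <- data.frame(i = 1:5, j = 31:35, chain_i = "A", pos_i = 1:5,
                         chain_j = "B", pos_j = 1:5,
                         apc = c(0.5, 0.9, 0.1, 0.7, 0.3),
                         precision = NA_real_)
  f <- tempfile(fileext = ".rr")
  export_restraints(contacts, f, "casp_rr", top_n = 3)
  back <- read_restraints(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$confidence, sort(contacts$apc, decreasing = TRUE)[1:3])
  expect_equal(back$i, c(2, 4, 1))
  expect_equal(back$d_low, rep(0, 3))
  expect_equal(back$d_high, rep(8, 3))

  # full-precision round trip
  expect_identical(back$confidence, c(0.9, 0.7, 0.5))

  # top_n beyond availability writes all with a warning
  expect_warning(export_restraints(contacts, f, "casp_rr", top_n = 10),
                 "exceeds")
  expect_equal(nrow(read_restraints(f)), 5L)

  # empty input: header-only file plus warning
  expect_warning(export_restraints(contacts[0, ], f, "casp_rr", top_n = 0),
                 "no contacts")
  expect_equal(nrow(read_restraints(f)), 0L)

  # chain-qualified distance table
  f2 <- tempfile(fileext = ".tsv")
  export_restraints(contacts, f2, "distance_table", top_n = 2)
  tab <- read.delim(f2)
  expect_equal(names(tab), c("chain_i", "pos_i", "chain_j", "pos_j",
                             "d_low", "d_high", "confidence"))
  expect_equal(tab$confidence, c(0.9, 0.7))
})

test_that("toy geometry honours planted and decoy constraints, PDB round-trip", {
  pp <- planted_pairs_inter(4, 30, 60, 0.9)
  decoys <- data.frame(pos_i = c(2, 3), pos_j = c(50, 55))
  pdb <- tempfile(fileext = ".pdb")
  geom <- make_toy_geometry(30, 60, pp, decoy_pairs = decoys, seed = 1,
                            pdb_path = pdb)
  key <- paste(geom$chain, geom$pos)
  for (p in seq_len(nrow(pp))) {
    za <- geom$z[key == paste("A", pp$pos_i[p])]
    ra <- geom[key == paste("A", pp$pos_i[p]), c("x", "y", "z")]
    rb <- geom[key == paste("B", pp$pos_j[p]), c("x", "y", "z")]
    expect_lt(abs(ra$z - rb$z), 15)
    expect_lte(sqrt(sum((ra - rb)^2)), 8)
  }
  for (p in seq_len(nrow(decoys))) {
    za <- geom$z[key == paste("A", decoys$pos_i[p])]
    zb <- geom$z[key == paste("B", decoys$pos_j[p])]
    expect_gt(abs(za - zb), 15)
  }
  expect_true(all(geom$z >= -21 & geom$z <= 21))

  g2 <- load_geometry(pdb_path = pdb)
  m <- merge(geom, g2, by = c("chain", "pos"))
  expect_lt(max(abs(m$z.x - m$z.y)), 1e-3)
  expect_lt(max(abs(m$x.x - m$x.y)), 1e-3)
})
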