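test_that("side-chain extraction skips residues lacking the reference atom", {
  f <- write_pdb_text(c(
    atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0),
    atom_line(2, "NZ", "LYS", "A", 1, 0, 0, 1),
    atom_line(3, "CA", "LYS", "A", 5, 9, 9, 9)   # truncated side chain
  ))
  st <- read_pdb(f)
  pts <- extract_side_chain_points(st, "LYS")
  expect_equal(nrow(pts), 1)
  expect_equal(attr(pts, "n_skipped"), 1)
  expect_equal(nrow(extract_side_chain_points(st, "CYS")), 0)
})

test_that("nearest-cysteine distance is the Euclidean minimum with index ties low", {
  res <- kc_distance_for_lysine(c(0, 0, 0), data.frame(
    chain = "A", resno = 2L, x = 3, y = 4, z = 0))
  expect_equal(res$distance, 5)
  expect_equal(res$nearest_resno, 2L)

  cys <- data.frame(chain = "A", resno = c(10L, 20L),
                    x = c(6, 2), y = 0, z = 0)
  res <- kc_distance_for_lysine(c(0, 0, 0), cys)
  expect_equal(res$distance, 2)
  expect_equal(res$nearest_resno, 20L)

  # exact tie: lower residue index wins
  tie <- data.frame(chain = "A", resno = c(30L, 4L), x = c(0, 0),
                    y = c(5, -5), z = 0)
  expect_equal(kc_distance_for_lysine(c(0, 0, 0), tie)$nearest_resno, 4L)

  empty <- data.frame(chain = character(), resno = integer(),
                      x = numeric(), y = numeric(), z = numeric())
  expect_true(is.na(kc_distance_for_lysine(c(0, 0, 0), empty)$distance))
})

test_that("compute_kc_table equals the brute-force all-pairs oracle", {
  for (seed in c(101, 202, 303)) {
    g <- generate_proteome(sim_config(seed = seed, n_proteins = 4,
                                      length_range = c(40, 120),
                                      geometry = "packed"))
    for (st in g$structures) {
      kc <- compute_kc_table(st)
      oracle <- brute_force_kc(st)
      expect_equal(kc$lys_position, oracle$lys_position)
      expect_equal(kc$nearest_cys_position, oracle$nearest_cys_position)
      expect_equal(kc$kc_distance, oracle$kc_distance, tolerance = 1e-12)
    }
  }
})

test_that("KC distances are invariant under rigid-body transforms", {
  g <- generate_proteome(sim_config(seed = 77, n_proteins = 2,
                                    length_range = c(50, 80),
                                    geometry = "packed"))
  st <- g$structures[[1]]
  base <- compute_kc_table(st)
  # random rotation (QR of a random matrix) plus translation
  set.seed(7)
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_r) < 0) qr_r[, 1] <- -qr_r[, 1]
  shift <- c(100, -50, 3)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(qr_r)
  st2 <- st
  st2$atoms$x <- xyz[, 1] + shift[1]
  st2$atoms$y <- xyz[, 2] + shift[2]
  st2$atoms$z <- xyz[, 3] + shift[3]
  moved <- compute_kc_table(st2)
  expect_equal(moved$kc_distance, base$kc_distance, tolerance = 1e-6)
  expect_equal(moved$nearest_cys_position, base$nearest_cys_position)
})

test_that("adding a cysteine never increases any KC distance", {
  g <- generate_proteome(sim_config(seed = 88, n_proteins = 3,
                                    length_range = c(40, 90),
                                    geometry = "packed"))
  for (st in g$structures) {
    base <- compute_kc_table(st)
    extra <- data.frame(chain = "A", resno = max(st$atoms$resno) + 1L,
                        resname = "CYS", atom = "SG",
                        x = mean(st$atoms$x), y = mean(st$atoms$y),
                        z = mean(st$atoms$z))
    st2 <- pdb_structure(st$source_id, rbind(
      st$atoms[, c("chain", "resno", "resname", "atom", "x", "y", "z")],
      extra))
    aug <- compute_kc_table(st2)
    both <- is.finite(base$kc_distance)
    expect_true(all(aug$kc_distance[both] <= base$kc_distance[both] + 1e-12))
    expect_true(all(is.finite(aug$kc_distance)))
  }
})

test_that("cysteine-free structures yield only missing distances", {
  f <- write_pdb_text(c(
    atom_line(1, "NZ", "LYS", "A", 1, 0, 0, 0),
    atom_line(2, "NZ", "LYS", "A", 8, 5, 5, 5)
  ))
  kc <- compute_kc_table(read_pdb(f))
  expect_equal(nrow(kc), 2)
  expect_true(all(is.na(kc$kc_distance)))
})

test_that("chain scope separates within-chain and cross-chain searches", {
  f <- write_pdb_text(c(
    atom_line(1, "NZ", "LYS", "A", 1, 0, 0, 0),
    atom_line(2, "SG", "CYS", "A", 9, 12, 0, 0),
    atom_line(3, "SG", "CYS", "B", 5, 2, 0, 0)
  ))
  st <- read_pdb(f)
  within <- compute_kc_table(st)
  expect_equal(within$kc_distance[within$chain == "A"], 12)
  crossed <- compute_kc_table(st, cross_chain = TRUE)
  expect_equal(crossed$kc_distance[crossed$chain == "A"], 2)
  expect_equal(crossed$nearest_cys_chain[crossed$chain == "A"], "B")
})

test_that("site annotation joins, counts misses and rejects ambiguous tables", {
  kc <- data.frame(protein_id = c("P1", "P1", "P2"), chain = "A",
                   lys_position = c(5L, 9L, 2L),
                   nearest_cys_position = c(7L, 7L, 4L),
                   kc_distance = c(7.2, 11.0, 3.3))
  sites <- data.frame(protein_id = c("P1", "P3"), position = c(5L, 1L))
  ann <- annotate_sites_with_kc(sites, kc)
  expect_equal(ann$kc_distance, c(7.2, NA))
  expect_equal(attr(ann, "n_unmatched"), 1)

  dup <- rbind(kc, data.frame(protein_id = "P1", chain = "B",
                              lys_position = 5L, nearest_cys_position = 1L,
                              kc_distance = 1))
  expect_error(annotate_sites_with_kc(sites, dup), "duplicate")
})

test_that("KC distances agree with an independent bio3d-based computation", {
  library(bio3d)
  f <- system.file("extdata", "stat1_1yvl_standin_synthetic.pdb",
                   package = "lactylKC")
  ours <- compute_kc_table(read_pdb(f))

  ref <- bio3d::read.pdb(f)
  at <- ref$atom
  nzr <- at[at$resid == "LYS" & at$elety == "NZ", ]
  sgr <- at[at$resid == "CYS" & at$elety == "SG", ]
  for (i in seq_len(nrow(nzr))) {
    sg_same <- sgr[sgr$chain == nzr$chain[i], ]
    d <- sqrt((sg_same$x - nzr$x[i])^2 + (sg_same$y - nzr$y[i])^2 +
                (sg_same$z - nzr$z[i])^2)
    row <- ours[ours$chain == nzr$chain[i] & ours$lys_position == nzr$resno[i], ]
    expect_equal(row$kc_distance, min(d), tolerance = 1e-9)
    expect_equal(row$nearest_cys_position, sg_same$resno[which.min(d)])
  }
})
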