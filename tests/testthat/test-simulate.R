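test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 99, n_proteins = 6, motif_fraction = 0.5)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$truth, b2$truth)
  for (id in names(b1$proteome$structures)) {
    expect_identical(write_pdb(b1$proteome$structures[[id]]),
                     write_pdb(b2$proteome$structures[[id]]))
  }
})

test_that("a requested KC distance is realised to PDB precision", {
  cfg <- sim_config(seed = 12, n_proteins = 1)
  g <- generate_structure("AKAAACAA", cfg, protein_id = "one",
                          kc_targets = c("2" = 5.0))
  expect_equal(g$truth$kc_distance, 5.0, tolerance = 1e-9)
  f <- tempfile(fileext = ".pdb")
  write_pdb(g$structure, f)
  kc <- compute_kc_table(read_pdb(f))
  expect_equal(kc$kc_distance, 5.0, tolerance = 5e-3)
  expect_equal(kc$nearest_cys_position, 6L)
})

test_that("planted targets are realised exactly across a proteome", {
  prot <- generate_proteome(sim_config(seed = 21, n_proteins = 20))
  m <- prot$manifest[!is.na(prot$manifest$kc_target), ]
  expect_gt(nrow(m), 50)
  expect_equal(m$kc_distance, m$kc_target, tolerance = 1e-9)
})

test_that("the logistic planting rule degenerates to a step function", {
  manifest <- data.frame(protein_id = "P1", lys_position = c(1L, 2L),
                         kc_distance = c(5, 15))
  cfg <- sim_config(seed = 1, s = 1e-9)
  set.seed(1)
  sites <- plant_modification_sites(manifest, cfg)
  expect_equal(sites$position, 1L)    # 5 A planted, 15 A never
})

test_that("uniform planting matches the binomial expectation", {
  manifest <- data.frame(protein_id = "P", lys_position = seq_len(10000),
                         kc_distance = runif(10000, 2, 25))
  cfg <- sim_config(seed = 3, plant_rule = "uniform", p_uniform = 0.1)
  set.seed(3)
  sites <- plant_modification_sites(manifest, cfg)
  expect_gte(nrow(sites), 850)   # binomial 99% interval at n = 10000, p = 0.1
  expect_lte(nrow(sites), 1150)
})

test_that("logistic planting frequencies track the logistic curve per KC bin", {
  n <- 40000
  manifest <- data.frame(protein_id = "P", lys_position = seq_len(n),
                         kc_distance = runif(n, 2, 25))
  cfg <- sim_config(seed = 8)
  set.seed(8)
  sites <- plant_modification_sites(manifest, cfg)
  hit <- manifest$lys_position %in% sites$position
  bins <- cut(manifest$kc_distance, breaks = seq(2, 25, by = 2.3))
  obs <- tapply(hit, bins, sum)
  nn <- tapply(hit, bins, length)
  pbar <- tapply(plogis((cfg$d0 - manifest$kc_distance) / cfg$s), bins, mean)
  # goodness-of-fit against the planned probabilities, binomial variance
  keep <- nn * pbar > 1e-6 & nn * (1 - pbar) > 1e-6
  x2 <- sum(((obs - nn * pbar)^2 / (nn * pbar * (1 - pbar)))[keep])
  p <- pchisq(x2, df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("noise-free intensity simulation reproduces planted effects exactly", {
  design_fc <- function(effects, cfg) {
    si <- simulate_site_intensities(length(effects), effects, cfg)
    site_fold_change(si$matrix, si$design)
  }
  cfg0 <- sim_config(seed = 5, noise_sd = 0, missing_rate = 0)
  set.seed(5)
  fc0 <- design_fc(rep(0, 20), cfg0)
  expect_equal(fc0$fold_change, rep(1, 20))
  set.seed(5)
  fc2 <- design_fc(rep(2, 20), cfg0)
  expect_equal(fc2$fold_change, rep(4, 20))
})

test_that("noisy replicate estimates concentrate around the planted effect", {
  cfg <- sim_config(seed = 6, noise_sd = 0.3, missing_rate = 0)
  set.seed(6)
  si <- simulate_site_intensities(500, rep(2, 500), cfg)
  fc <- site_fold_change(si$matrix, si$design)
  # mean log2 of the ratio-of-means estimator at n = 3, sd = 0.3
  expect_lt(abs(mean(log2(fc$mean_treated / fc$mean_control)) - 2), 0.1)
})

test_that("dropout never removes a site completely", {
  cfg <- sim_config(seed = 7, missing_rate = 0.45)
  set.seed(7)
  si <- simulate_site_intensities(400, rep(0, 400), cfg)
  expect_true(any(is.na(si$matrix)))
  expect_true(all(rowSums(!is.na(si$matrix)) >= 1))
})

test_that("sequences, structures and FASTA stay mutually consistent", {
  cfg <- sim_config(seed = 31, n_proteins = 8, motif_fraction = 0.5)
  b <- simulate_bundle(cfg)
  to1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
           HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
           PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
           TRP = "W", TYR = "Y")
  for (k in seq_len(nrow(b$proteome$sequences))) {
    id <- b$proteome$sequences$id[k]
    seq <- strsplit(b$proteome$sequences$sequence[k], "")[[1]]
    at <- b$proteome$structures[[id]]$atoms
    ca <- at[at$atom == "CA", ]
    expect_equal(nrow(ca), length(seq))
    expect_identical(unname(to1[ca$resname]), seq)
  }
  # FASTA on disk matches the in-memory sequences
  d <- tempfile()
  b2 <- simulate_bundle(cfg, dir = d)
  fa <- read_fasta(file.path(d, "proteome.fa"))
  expect_identical(fa, b2$proteome$sequences)
  # every planted motif site really has a cysteine at the configured offset
  planted <- b2$sites[b2$sites$motif_planted, ]
  seqs <- stats::setNames(b2$proteome$sequences$sequence,
                          b2$proteome$sequences$id)
  for (r in seq_len(nrow(planted))) {
    pos <- planted$position[r] + cfg$motif_offset
    expect_equal(substr(seqs[[planted$protein_id[r]]], pos, pos), "C")
  }
})
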