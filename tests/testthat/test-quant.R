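test_that("relative normalization divides by the observed-sample row mean", {
  m <- rbind(a = c(100, 100, 100), b = c(50, 150, NA))
  r <- normalize_relative(m)
  expect_equal(unname(r["a", ]), c(1, 1, 1))
  expect_equal(unname(r["b", ]), c(0.5, 1.5, NA))

  set.seed(1)
  m2 <- random_intensity_matrix(50, paste0("s", 1:6), missing = 0.2)
  r2 <- normalize_relative(m2)
  expect_true(all(abs(rowMeans(r2, na.rm = TRUE) - 1) < 1e-9))

  # idempotence and row-scale invariance
  expect_equal(normalize_relative(r2), r2)
  expect_equal(normalize_relative(m2 * 7), r2)
  # scaling one sample column changes R but the row-mean-one identity holds
  m3 <- m2; m3[, 2] <- m3[, 2] * 13
  expect_true(all(abs(rowMeans(normalize_relative(m3), na.rm = TRUE) - 1) < 1e-9))

  m4 <- rbind(ok = c(1, 2), dead = c(NA, NA))
  expect_error(normalize_relative(m4), "dead")
})

test_that("protein correction cancels protein-driven profiles", {
  samples <- c("s1", "s2")
  site_R <- matrix(c(0.5, 1.5), 1, dimnames = list("P1_K5", samples))
  prot_same <- matrix(c(0.5, 1.5), 1, dimnames = list("P1", samples))
  prot_flat <- matrix(c(1, 1), 1, dimnames = list("P1", samples))
  expect_equal(unname(protein_correct(site_R, prot_same, "P1")[1, ]),
               c(1, 1))
  expect_equal(unname(protein_correct(site_R, prot_flat, "P1")[1, ]),
               c(0.5, 1.5))

  # scaling a protein's raw intensities by any constant leaves the
  # correction unchanged (normalization absorbs the scale)
  set.seed(2)
  praw <- random_intensity_matrix(1, paste0("s", 1:4))
  rownames(praw) <- "P9"
  sraw <- random_intensity_matrix(3, paste0("s", 1:4))
  rownames(sraw) <- rep("P9_K2", 3)
  base <- protein_correct(normalize_relative(sraw), normalize_relative(praw),
                          rep("P9", 3))
  for (const in c(0.01, 3, 1e4)) {
    scaled <- protein_correct(normalize_relative(sraw),
                              normalize_relative(praw * const), rep("P9", 3))
    expect_equal(scaled, base)
  }

  expect_warning(
    out <- protein_correct(site_R, prot_flat, "UNKNOWN"),
    "without protein-level")
  expect_equal(nrow(out), 0)
})

test_that("fold changes follow group means and respect symmetry", {
  design <- data.frame(sample = paste0("s", 1:6),
                       group = rep(c("control", "treated"), each = 3))
  m <- rbind(flat = rep(2, 6), up4 = c(1, 1, 1, 4, 4, 4))
  colnames(m) <- design$sample
  fc <- site_fold_change(m, design)
  expect_equal(fc$fold_change, c(1, 4))
  expect_equal(fc$log2_fc, c(0, 2))

  # permuting samples within a group changes nothing
  design2 <- design[c(3, 1, 2, 5, 6, 4), ]
  expect_equal(site_fold_change(m, design2)$fold_change, fc$fold_change)
  expect_equal(site_fold_change(m, design2)$p_value, fc$p_value)

  # a group with no observed values gives a missing fold change
  m2 <- rbind(gone = c(NA, NA, NA, 4, 4, 4))
  colnames(m2) <- design$sample
  expect_true(is.na(site_fold_change(m2, design)$fold_change))
  # one observed value: fold change reported, p missing
  m3 <- rbind(thin = c(2, NA, NA, 4, 4, 4))
  colnames(m3) <- design$sample
  out3 <- site_fold_change(m3, design)
  expect_equal(out3$fold_change, 2)
  expect_true(is.na(out3$p_value))
})

test_that("row-wise Welch p-values agree with stats::t.test", {
  set.seed(33)
  design <- data.frame(sample = paste0("s", 1:8),
                       group = rep(c("control", "treated"), each = 4))
  m <- random_intensity_matrix(25, design$sample, missing = 0.15)
  fc <- site_fold_change(m, design, test = "welch")
  for (i in seq_len(nrow(m))) {
    x0 <- log2(m[i, 1:4]); x1 <- log2(m[i, 5:8])
    if (sum(!is.na(x0)) < 2 || sum(!is.na(x1)) < 2) {
      expect_true(is.na(fc$p_value[i]))
    } else {
      ref <- t.test(x1, x0)$p.value
      expect_equal(fc$p_value[i], ref, tolerance = 1e-12)
    }
  }
})

test_that("site classification applies both the fold and significance gates", {
  tab <- data.frame(
    site_id = letters[1:5],
    fold_change = c(3.0, 3.0, 0.2, 1.2, 5.0),
    adj_p = c(0.01, 0.30, 0.001, 0.001, NA))
  cls <- classify_sites(tab)$class
  expect_equal(cls, c("up", "unchanged", "down", "unchanged", "unchanged"))
  # threshold is strict: FC exactly at the cut-off stays unchanged
  at <- data.frame(site_id = "x", fold_change = 2.0, adj_p = 1e-5)
  expect_equal(classify_sites(at)$class, "unchanged")
})

test_that("quantify_sites aggregates duplicate peptides and flags correction", {
  design <- data.frame(sample = c("s1", "s2"),
                       group = c("control", "treated"))
  sites <- data.frame(protein_id = c("P1", "P1", "P2"),
                      position = c(5L, 5L, 3L), residue = "K",
                      s1 = c(100, 300, 50), s2 = c(200, 600, 150))
  attr(sites, "sample_cols") <- c("s1", "s2")
  q <- quantify_sites(sites, design)
  expect_false(q$protein_corrected)
  expect_equal(nrow(q$table), 2)          # P1_K5 peptides merged
  # both P1_K5 peptides have the same relative profile, so the median
  # equals that profile
  expect_equal(q$corrected["P1_K5", ],
               c(s1 = 100 / 150, s2 = 200 / 150))
})
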