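# Shared fixtures and independent oracles for the test suite.

# Hand-rolled fixed-column ATOM line (independent of write_pdb).
atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                      occ = 1, b = 0, altloc = " ", record = "ATOM  ") {
  sprintf("%s%5d  %-3s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, altloc, resname, chain, resno, x, y, z, occ, b)
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Minimal two-residue structure: LYS NZ at the origin, CYS SG at (3,4,0),
# a 3-4-5 triangle with KC distance exactly 5.
minimal_kc_pdb <- function() {
  write_pdb_text(c(
    atom_line(1, "CA", "LYS", "A", 1, 0, 0, 1),
    atom_line(2, "NZ", "LYS", "A", 1, 0, 0, 0),
    atom_line(3, "CA", "CYS", "A", 2, 3, 4, 1),
    atom_line(4, "SG", "CYS", "A", 2, 3, 4, 0)
  ))
}

# Independent brute-force KC oracle: plain double loop over every
# (LYS NZ, CYS SG) atom pair, same chain only.
brute_force_kc <- function(st) {
  a <- st$atoms
  nzr <- a[a$resname == "LYS" & a$atom == "NZ", , drop = FALSE]
  sgr <- a[a$resname == "CYS" & a$atom == "SG", , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(nzr))) {
    best <- Inf; best_res <- NA_integer_
    for (j in seq_len(nrow(sgr))) {
      if (sgr$chain[j] != nzr$chain[i]) next
      d <- sqrt((nzr$x[i] - sgr$x[j])^2 + (nzr$y[i] - sgr$y[j])^2 +
                  (nzr$z[i] - sgr$z[j])^2)
      if (d < best) { best <- d; best_res <- sgr$resno[j] }
    }
    out <- rbind(out, data.frame(
      chain = nzr$chain[i], lys_position = as.integer(nzr$resno[i]),
      nearest_cys_position = as.integer(best_res),
      kc_distance = if (is.finite(best)) best else NA_real_))
  }
  if (is.null(out)) {
    return(data.frame(chain = character(), lys_position = integer(),
                      nearest_cys_position = integer(),
                      kc_distance = numeric()))
  }
  out <- out[order(out$chain, out$lys_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric two-sided p for a 2x2 table (Fisher oracle):
# sum the probabilities of all tables with the given margins whose
# probability does not exceed the observed table's.
fisher_oracle <- function(a, f_tot, b, b_tot) {
  k <- a + b
  support <- max(0, k - b_tot):min(k, f_tot)
  probs <- stats::dhyper(support, f_tot, b_tot, k)
  p_obs <- stats::dhyper(a, f_tot, b_tot, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random intensity matrix with optional missing cells.
random_intensity_matrix <- function(n, samples, missing = 0) {
  m <- matrix(2^runif(n * length(samples), 15, 25), n, length(samples),
              dimnames = list(paste0("site", seq_len(n)), samples))
  if (missing > 0) {
    m[runif(length(m)) < missing] <- NA_real_
    dead <- rowSums(!is.na(m)) == 0
    m[dead, 1] <- 1000
  }
  m
}
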