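AA_3LETTER <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
                G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
                M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
                S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Simulation configuration
#'
#' Collects every parameter of the synthetic study generator. Defaults encode
#' the study conditions the analyses are designed around: 3 replicates per
#' group, log-normal intensity noise with sd 0.3 on the log2 scale, planted
#' 4-fold (log2 effect 2) regulated sites, and a logistic lactylation
#' susceptibility in the KC distance with midpoint 10 Angstrom and slope
#' scale 3 Angstrom. Identical config + seed yields byte-identical outputs.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param length_range Min/max protein length (residues).
#' @param lys_freq,cys_freq Per-residue probabilities of K and C; remaining
#'   mass is spread uniformly over the other 18 amino acids.
#' @param geometry Backbone layout: `"extended"` (residues spread on a wide
#'   cubic lattice, every C-alpha pair at least `ca_spacing` Angstrom apart;
#'   the default, which makes planted KC distances exact), `"helix"` (ideal
#'   alpha-helical trace, 2.3 A radius, 1.5 A rise and 100 degrees twist per
#'   residue; distances emergent) or `"packed"` (residues placed uniformly
#'   in a cube).
#' @param ca_spacing C-alpha spacing for the extended layout (Angstrom).
#' @param kc_range Range the per-lysine target KC distances are drawn from
#'   (uniform, Angstrom).
#' @param d0,s Midpoint and scale (Angstrom) of the logistic lactylation
#'   rule `P(lacK | KC = d) = 1 / (1 + exp((d - d0) / s))`.
#' @param plant_rule `"logistic"` (KC-dependent) or `"uniform"` (null,
#'   probability `p_uniform` independent of KC).
#' @param p_uniform Planting probability under the uniform rule.
#' @param motif_offset,motif_fraction Plant a cysteine at this sequence
#'   offset from a fraction of planted sites (0 disables planting).
#' @param n_per_group Replicates per group in the intensity model.
#' @param log2_effect Planted treated-vs-control log2 effect for upregulated
#'   sites.
#' @param up_d0 Midpoint of the logistic rule assigning which planted sites
#'   are upregulated (shorter KC -> more likely up).
#' @param up_rule `"logistic"` or `"none"` (no upregulated sites).
#' @param noise_sd Replicate noise sd on the log2 scale.
#' @param missing_rate Missing-completely-at-random dropout rate.
#' @param baseline_range Range of per-site baseline log2 intensities.
#' @param compartment_probs Named probabilities of assigning each protein to
#'   cytosol / mitochondria / nucleus / other.
#' @param compartment_kc_shift Additive shift (Angstrom) applied to the KC
#'   target range per compartment; the default places nuclear lysines
#'   farther from cysteines than cytosolic/mitochondrial ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_proteins = 60,
                       length_range = c(120, 250),
                       lys_freq = 0.05, cys_freq = 0.05,
                       geometry = c("extended", "helix", "packed"),
                       ca_spacing = 80,
                       kc_range = c(2, 25),
                       d0 = 10, s = 3,
                       plant_rule = c("logistic", "uniform"),
                       p_uniform = 0.1,
                       motif_offset = 2L, motif_fraction = 0,
                       n_per_group = 3,
                       log2_effect = 2,
                       up_d0 = 8, up_rule = c("logistic", "none"),
                       noise_sd = 0.3,
                       missing_rate = 0.1,
                       baseline_range = c(20, 30),
                       compartment_probs = c(cytosol = 0.6,
                                             mitochondria = 0.15,
                                             nucleus = 0.2, other = 0.05),
                       compartment_kc_shift = c(cytosol = 0,
                                                mitochondria = 0,
                                                nucleus = 6, other = 0)) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  geometry <- match.arg(geometry)
  plant_rule <- match.arg(plant_rule)
  up_rule <- match.arg(up_rule)
  rates <- c(lys_freq = lys_freq, cys_freq = cys_freq,
             p_uniform = p_uniform, motif_fraction = motif_fraction,
             missing_rate = missing_rate)
  if (any(rates < 0 | rates > 1)) {
    bad <- names(rates)[rates < 0 | rates > 1]
    stop("rate(s) outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(length_range) == 2, length_range[1] >= 2 * 6 + 3,
            length(kc_range) == 2, kc_range[1] > 0, s > 0,
            n_per_group >= 1, noise_sd >= 0)
  structure(
    list(seed = as.integer(seed), n_proteins = n_proteins,
         length_range = length_range, lys_freq = lys_freq,
         cys_freq = cys_freq, geometry = geometry, ca_spacing = ca_spacing,
         kc_range = kc_range, d0 = d0, s = s, plant_rule = plant_rule,
         p_uniform = p_uniform, motif_offset = as.integer(motif_offset),
         motif_fraction = motif_fraction, n_per_group = n_per_group,
         log2_effect = log2_effect, up_d0 = up_d0, up_rule = up_rule,
         noise_sd = noise_sd, missing_rate = missing_rate,
         baseline_range = baseline_range,
         compartment_probs = compartment_probs,
         compartment_kc_shift = compartment_kc_shift),
    class = "sim_config")
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate one synthetic structure
#'
#' Places a C-alpha trace on the configured backbone geometry and emits
#' side-chain reference pseudo-atoms: an NZ for every lysine and an SG for
#' every cysteine. When target KC distances are supplied, each targeted
#' lysine is paired with a cysteine whose SG is placed exactly at the target
#' distance from the lysine's NZ (the paired cysteine residue is relocated
#' next to its lysine); with the extended layout's wide spacing that partner
#' is provably the nearest thiol. The returned ground truth is nevertheless
#' recomputed from the emitted coordinates by direct all-pairs minimisation,
#' so it is exact under any geometry.
#'
#' @param seq_string Amino-acid sequence (1-letter codes).
#' @param config A [sim_config()]. Only the geometry fields are used here.
#' @param protein_id Identifier written into the records.
#' @param kc_targets Optional named numeric vector: names are lysine
#'   positions, values target KC distances (Angstrom).
#' @return List with `structure` (a `pdb_structure` with CA/NZ/SG atoms) and
#'   `truth` (data frame: `protein_id`, `lys_position`,
#'   `nearest_cys_position`, `kc_distance`, `kc_target`).
#' @export
generate_structure <- function(seq_string, config, protein_id = "prot",
                               kc_targets = NULL) {
  aa <- strsplit(seq_string, "")[[1]]
  n <- length(aa)
  idx <- seq_len(n)
  ca <- switch(config$geometry,
    extended = {
      ## raster walk over a cubic lattice: any two C-alphas are at least
      ## ca_spacing apart while coordinates stay inside the PDB field width
      m <- ceiling(n^(1 / 3))
      i0 <- idx - 1
      config$ca_spacing * cbind(i0 %% m, (i0 %/% m) %% m, i0 %/% (m * m))
    },
    helix = {
      t <- idx * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * idx)
    },
    packed = {
      side <- max(25, 4 * n^(1 / 3) * 3)
      matrix(stats::runif(3 * n, 0, side), ncol = 3)
    })

  kpos <- which(aa == "K")
  cpos <- which(aa == "C")
  nz <- matrix(NA_real_, n, 3)
  sg <- matrix(NA_real_, n, 3)
  for (i in kpos) nz[i, ] <- ca[i, ] + 3.8 * random_unit()
  sg_placed <- rep(FALSE, n)

  if (!is.null(kc_targets) && length(kc_targets) > 0) {
    tpos <- as.integer(names(kc_targets))
    stopifnot(all(tpos %in% kpos))
    free_c <- cpos
    for (i in tpos) {
      if (length(free_c) == 0) break
      partner <- free_c[which.min(abs(free_c - i))]
      free_c <- setdiff(free_c, partner)
      u <- random_unit()
      d <- kc_targets[[as.character(i)]]
      sg[partner, ] <- nz[i, ] + d * u
      ca[partner, ] <- nz[i, ] + (d + 1.8) * u   # relocate paired residue
      sg_placed[partner] <- TRUE
    }
  }
  for (i in cpos[!sg_placed[cpos]]) sg[i, ] <- ca[i, ] + 1.8 * random_unit()

  atoms <- rbind(
    data.frame(chain = "A", resno = idx, resname = unname(AA_3LETTER[aa]),
               atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3],
               stringsAsFactors = FALSE),
    if (length(kpos) > 0)
      data.frame(chain = "A", resno = kpos, resname = "LYS", atom = "NZ",
                 x = nz[kpos, 1], y = nz[kpos, 2], z = nz[kpos, 3],
                 stringsAsFactors = FALSE),
    if (length(cpos) > 0)
      data.frame(chain = "A", resno = cpos, resname = "CYS", atom = "SG",
                 x = sg[cpos, 1], y = sg[cpos, 2], z = sg[cpos, 3],
                 stringsAsFactors = FALSE)
  )
  ## CA before side-chain atom within each residue
  atoms <- atoms[order(atoms$resno, atoms$atom != "CA"), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$b <- 90                      # constant pLDDT-style confidence
  st <- pdb_structure(protein_id, atoms)

  truth <- generator_truth(st)
  if (!is.null(kc_targets)) {
    i <- match(truth$lys_position, as.integer(names(kc_targets)))
    truth$kc_target <- as.numeric(kc_targets)[i]
  } else {
    truth$kc_target <- rep(NA_real_, nrow(truth))
  }
  list(structure = st, truth = truth)
}

## exact generator-side ground truth: plain all-pairs minimisation over the
## emitted NZ/SG coordinates (loop form, kept separate from the analysis path)
generator_truth <- function(st) {
  a <- st$atoms
  nzrow <- a[a$atom == "NZ", , drop = FALSE]
  sgrow <- a[a$atom == "SG", , drop = FALSE]
  nk <- nrow(nzrow)
  truth <- data.frame(protein_id = rep(st$source_id, nk),
                      lys_position = as.integer(nzrow$resno),
                      nearest_cys_position = rep(NA_integer_, nk),
                      kc_distance = rep(NA_real_, nk),
                      stringsAsFactors = FALSE)
  if (nrow(sgrow) > 0) {
    for (r in seq_len(nrow(nzrow))) {
      dd <- sqrt((sgrow$x - nzrow$x[r])^2 + (sgrow$y - nzrow$y[r])^2 +
                   (sgrow$z - nzrow$z[r])^2)
      j <- which.min(dd)
      truth$nearest_cys_position[r] <- as.integer(sgrow$resno[j])
      truth$kc_distance[r] <- dd[j]
    }
  }
  truth <- truth[order(truth$lys_position), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

## turn residue `pos` of a synthetic structure into a cysteine with an SG
## 1.8 Angstrom from its C-alpha
add_cys_to_structure <- function(st, pos) {
  a <- st$atoms
  i <- which(a$resno == pos & a$atom == "CA")
  stopifnot(length(i) == 1)
  a$resname[i] <- "CYS"
  u <- random_unit()
  sg <- a[i, , drop = FALSE]
  sg$atom <- "SG"
  sg$x <- a$x[i] + 1.8 * u[1]
  sg$y <- a$y[i] + 1.8 * u[2]
  sg$z <- a$z[i] + 1.8 * u[3]
  a <- rbind(a[seq_len(i), , drop = FALSE], sg,
             if (i < nrow(a)) a[seq(i + 1, nrow(a)), , drop = FALSE])
  pdb_structure(st$source_id, a, st$model_index)
}

generate_sequence <- function(len, lys_freq, cys_freq) {
  other <- setdiff(AA20, c("K", "C"))
  probs <- c(rep((1 - lys_freq - cys_freq) / length(other), length(other)),
             lys_freq, cys_freq)
  paste(sample(c(other, "K", "C"), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a synthetic proteome with known KC geometry
#'
#' Draws protein sequences, assigns each protein a subcellular compartment,
#' draws a target KC distance for each lysine (uniform over
#' `config$kc_range`, shifted by the compartment), and builds one structure
#' per protein via [generate_structure()]. The returned manifest holds the
#' exact KC distance of every lysine as realised in the emitted coordinates.
#'
#' @param config A [sim_config()]. The RNG is seeded from `config$seed`.
#' @return List with `sequences` (data frame `id`/`sequence`),
#'   `structures` (named list of `pdb_structure`), `manifest` (per-lysine
#'   truth: `protein_id`, `lys_position`, `nearest_cys_position`,
#'   `kc_distance`, `kc_target`, `compartment`), `localization` (per-protein
#'   data frame) and `config`.
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  comps <- sample(names(config$compartment_probs), n, replace = TRUE,
                  prob = config$compartment_probs)
  seqs <- vapply(lens, generate_sequence, character(1),
                 lys_freq = config$lys_freq, cys_freq = config$cys_freq)

  structures <- vector("list", n)
  names(structures) <- ids
  manifest <- vector("list", n)
  for (k in seq_len(n)) {
    aa <- strsplit(seqs[k], "")[[1]]
    kpos <- which(aa == "K")
    ncys <- sum(aa == "C")
    n_target <- min(length(kpos), ncys)
    targets <- NULL
    if (n_target > 0) {
      shift <- config$compartment_kc_shift[[comps[k]]]
      tpos <- kpos[seq_len(n_target)]
      targets <- stats::setNames(
        stats::runif(n_target, config$kc_range[1], config$kc_range[2]) + shift,
        tpos)
    }
    g <- generate_structure(seqs[k], config, protein_id = ids[k],
                            kc_targets = targets)
    structures[[k]] <- g$structure
    g$truth$compartment <- rep(comps[k], nrow(g$truth))
    manifest[[k]] <- g$truth
  }
  list(
    sequences = data.frame(id = ids, sequence = unname(seqs),
                           stringsAsFactors = FALSE),
    structures = structures,
    manifest = do.call(rbind, manifest),
    localization = data.frame(protein_id = ids, localization = comps,
                              stringsAsFactors = FALSE),
    config = config
  )
}

#' Plant modification sites on a synthetic proteome
#'
#' Marks each lysine as lactylated with a probability given by the planting
#' rule: logistic in its true KC distance,
#' `P = 1 / (1 + exp((d - d0) / s))`, or uniform (`p_uniform`, independent of
#' KC -- the null configuration). Lysines without a defined KC distance
#' (cysteine-free proteins) are never planted.
#'
#' @param manifest Per-lysine manifest from [generate_proteome()] (or any
#'   data frame with `protein_id`, `lys_position`, `kc_distance`).
#' @param config A [sim_config()] providing the rule and its parameters.
#' @return Data frame of planted sites: `protein_id`, `position`,
#'   `residue` (`"K"`), `true_kc`.
#' @export
plant_modification_sites <- function(manifest, config) {
  d <- manifest$kc_distance
  p <- switch(config$plant_rule,
    logistic = ifelse(is.finite(d), stats::plogis((config$d0 - d) / config$s), 0),
    uniform = ifelse(is.finite(d), config$p_uniform, 0))
  hit <- stats::runif(length(p)) < p
  data.frame(protein_id = manifest$protein_id[hit],
             position = manifest$lys_position[hit],
             residue = "K", true_kc = d[hit],
             stringsAsFactors = FALSE)
}

#' Plant a cysteine motif into sequences around chosen sites
#'
#' Replaces the residue at `offset` positions from a fraction of the given
#' sites with `C`, leaving existing K/C residues untouched so that other
#' sites and thiol geometry assignments survive. Used to emulate a
#' position-specific cysteine preference in foreground windows; must be
#' applied before structures are generated from the sequences.
#'
#' @param sequences Data frame `id`/`sequence`.
#' @param sites Data frame `protein_id`/`position`.
#' @param offset Relative sequence offset of the planted cysteine.
#' @param fraction Fraction of sites receiving the motif.
#' @return List with modified `sequences` and `planted` (logical per site).
#' @export
plant_motif <- function(sequences, sites, offset = 2L, fraction = 0.5) {
  seqs <- stats::setNames(sequences$sequence, sequences$id)
  planted <- rep(FALSE, nrow(sites))
  pick <- stats::runif(nrow(sites)) < fraction
  for (r in which(pick)) {
    pid <- sites$protein_id[r]
    pos <- sites$position[r] + offset
    seq <- seqs[[pid]]
    if (pos < 1 || pos > nchar(seq)) next
    if (substr(seq, pos, pos) %in% c("K", "C")) next
    substr(seq, pos, pos) <- "C"
    seqs[[pid]] <- seq
    planted[r] <- TRUE
  }
  list(sequences = data.frame(id = names(seqs), sequence = unname(seqs),
                              stringsAsFactors = FALSE),
       planted = planted)
}

#' Simulate replicate site intensities
#'
#' Log2 intensities are a per-site baseline plus the planted group effect for
#' treated samples plus Gaussian noise, exponentiated back to the intensity
#' scale; dropout is completely at random at the configured rate (a row
#' losing every observation has one value restored so each site stays
#' quantifiable).
#'
#' @param n_sites Number of sites (rows).
#' @param effects Per-site treated-vs-control log2 effects (length
#'   `n_sites`; 0 = null).
#' @param config A [sim_config()] providing `n_per_group`, `noise_sd`,
#'   `missing_rate` and `baseline_range`.
#' @return List with `matrix` (rows = sites, columns = samples `Ctrl1..`,
#'   `Treat1..`) and `design` (sample/group data frame with groups
#'   `control`/`treated`).
#' @export
simulate_site_intensities <- function(n_sites, effects, config) {
  stopifnot(length(effects) == n_sites)
  ng <- config$n_per_group
  samples <- c(paste0("Ctrl", seq_len(ng)), paste0("Treat", seq_len(ng)))
  design <- data.frame(sample = samples,
                       group = rep(c("control", "treated"), each = ng),
                       stringsAsFactors = FALSE)
  baseline <- stats::runif(n_sites, config$baseline_range[1],
                           config$baseline_range[2])
  eff <- outer(effects, as.numeric(design$group == "treated"))
  log2i <- baseline + eff +
    matrix(stats::rnorm(n_sites * 2 * ng, sd = config$noise_sd),
           n_sites, 2 * ng)
  m <- 2^log2i
  dimnames(m) <- list(NULL, samples)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(m)) < config$missing_rate,
                   nrow(m), ncol(m))
    m[drop] <- NA_real_
    dead <- rowSums(!is.na(m)) == 0
    for (r in which(dead)) {
      m[r, sample.int(ncol(m), 1)] <- 2^(baseline[r])
    }
  }
  list(matrix = m, design = design)
}

#' Generate a complete synthetic study bundle
#'
#' Runs the full generator: proteome sequences and structures with known KC
#' geometry, KC-dependent (or null) site planting, optional motif planting,
#' upregulation assignment, replicate site and protein intensities, and a
#' ground-truth manifest sufficient to recompute every expected output.
#' When `dir` is given, writes `structures/*.pdb`, `proteome.fa`,
#' `sites.tsv`, `proteins.tsv`, `design.tsv`, `localization.tsv` and
#' `truth_manifest.tsv` there.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `proteome` (see [generate_proteome()]), `sites` (site
#'   table with intensity columns), `proteins` (protein intensity table),
#'   `design`, `localization`, `truth` (per planted site: `protein_id`,
#'   `position`, `true_kc`, `true_log2_effect`, `true_class`) and `paths`
#'   (when written).
#' @export
simulate_bundle <- function(config, dir = NULL) {
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  comps <- sample(names(config$compartment_probs), n, replace = TRUE,
                  prob = config$compartment_probs)
  seqs <- vapply(lens, generate_sequence, character(1),
                 lys_freq = config$lys_freq, cys_freq = config$cys_freq)
  sequences <- data.frame(id = ids, sequence = unname(seqs),
                          stringsAsFactors = FALSE)

  ## structures with controlled KC targets, then exact realised manifest
  structures <- vector("list", n)
  names(structures) <- ids
  manifest <- vector("list", n)
  for (k in seq_len(n)) {
    aa <- strsplit(sequences$sequence[k], "")[[1]]
    kpos <- which(aa == "K")
    n_target <- min(length(kpos), sum(aa == "C"))
    kc_targets <- NULL
    if (n_target > 0) {
      shift <- config$compartment_kc_shift[[comps[k]]]
      kc_targets <- stats::setNames(
        stats::runif(n_target, config$kc_range[1], config$kc_range[2]) + shift,
        kpos[seq_len(n_target)])
    }
    g <- generate_structure(sequences$sequence[k], config,
                            protein_id = ids[k], kc_targets = kc_targets)
    structures[[k]] <- g$structure
    g$truth$compartment <- rep(comps[k], nrow(g$truth))
    manifest[[k]] <- g$truth
  }
  manifest <- do.call(rbind, manifest)

  ## planting always runs on the realised manifest (all lysines with a
  ## defined KC), so the uniform null really is KC-independent
  sites <- plant_modification_sites(manifest, config)

  if (config$motif_fraction > 0 && nrow(sites) > 0) {
    pm <- plant_motif(sequences, sites, offset = config$motif_offset,
                      fraction = config$motif_fraction)
    sequences <- pm$sequences
    sites$motif_planted <- pm$planted
    ## keep structures consistent with the edited sequences and refresh the
    ## realised truth for patched proteins
    for (r in which(pm$planted)) {
      pid <- sites$protein_id[r]
      pos <- sites$position[r] + config$motif_offset
      structures[[pid]] <- add_cys_to_structure(structures[[pid]], pos)
    }
    patched <- unique(sites$protein_id[pm$planted])
    if (length(patched) > 0) {
      comp_by_id <- stats::setNames(comps, ids)
      refreshed <- do.call(rbind, lapply(patched, function(pid) {
        tr <- generator_truth(structures[[pid]])
        tr$kc_target <- manifest$kc_target[match(
          paste(pid, tr$lys_position),
          paste(manifest$protein_id, manifest$lys_position))]
        tr$compartment <- rep(comp_by_id[[pid]], nrow(tr))
        tr
      }))
      manifest <- rbind(manifest[!(manifest$protein_id %in% patched), ,
                                 drop = FALSE], refreshed)
      manifest <- manifest[order(manifest$protein_id,
                                 manifest$lys_position), , drop = FALSE]
      rownames(manifest) <- NULL
      key <- paste(manifest$protein_id, manifest$lys_position)
      sites$true_kc <- manifest$kc_distance[match(
        paste(sites$protein_id, sites$position), key)]
    }
  }

  ## upregulation assignment and intensities
  n_sites <- nrow(sites)
  is_up <- if (config$up_rule == "logistic" && n_sites > 0) {
    stats::runif(n_sites) < stats::plogis((config$up_d0 - sites$true_kc) /
                                            config$s)
  } else {
    rep(FALSE, n_sites)
  }
  effects <- ifelse(is_up, config$log2_effect, 0)
  si <- simulate_site_intensities(n_sites, effects, config)
  site_table <- data.frame(
    protein_id = sites$protein_id, position = sites$position,
    residue = "K", stringsAsFactors = FALSE)
  site_table <- cbind(site_table, as.data.frame(si$matrix))
  attr(site_table, "sample_cols") <- colnames(si$matrix)

  ## protein-level intensities: no group effect, so correction is neutral
  pi <- simulate_site_intensities(n, rep(0, n), config)
  protein_table <- cbind(data.frame(protein_id = ids,
                                    stringsAsFactors = FALSE),
                         as.data.frame(pi$matrix))
  attr(protein_table, "sample_cols") <- colnames(pi$matrix)

  localization <- data.frame(protein_id = ids, localization = comps,
                             stringsAsFactors = FALSE)
  truth <- data.frame(
    protein_id = sites$protein_id, position = sites$position,
    true_kc = sites$true_kc, true_log2_effect = effects,
    true_class = ifelse(is_up, "up", "unchanged"),
    stringsAsFactors = FALSE)

  proteome <- list(sequences = sequences, structures = structures,
                   manifest = manifest, localization = localization,
                   config = config)
  out <- list(proteome = proteome, sites = site_table,
              proteins = protein_table, design = si$design,
              localization = localization, truth = truth)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in ids) {
      write_pdb(structures[[id]],
                file.path(dir, "structures", paste0(id, ".pdb")))
    }
    write_fasta(sequences, file.path(dir, "proteome.fa"))
    write_tsv(site_table, file.path(dir, "sites.tsv"))
    write_tsv(protein_table, file.path(dir, "proteins.tsv"))
    write_tsv(si$design, file.path(dir, "design.tsv"))
    write_tsv(localization, file.path(dir, "localization.tsv"))
    write_tsv(merge(manifest, truth,
                    by.x = c("protein_id", "lys_position"),
                    by.y = c("protein_id", "position"), all.x = TRUE),
              file.path(dir, "truth_manifest.tsv"))
    out$paths <- list(
      structures = file.path(dir, "structures"),
      fasta = file.path(dir, "proteome.fa"),
      sites = file.path(dir, "sites.tsv"),
      proteins = file.path(dir, "proteins.tsv"),
      design = file.path(dir, "design.tsv"),
      localization = file.path(dir, "localization.tsv"),
      truth = file.path(dir, "truth_manifest.tsv"))
  }
  out
}
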