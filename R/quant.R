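#' Relative intensity normalization
#'
#' Transforms a raw site (or protein) intensity matrix `I` into relative
#' quantitative values `R`, dividing each row by its mean over observed
#' samples: `R[j, i] = I[j, i] / mean(I[j, ])` with the mean taken over
#' non-missing entries only. Missing cells stay missing. After normalization
#' every row means to 1 over its observed samples, so the operation is
#' idempotent and invariant to rescaling a whole row.
#'
#' @param m Numeric matrix, rows = sites/proteins, columns = samples; `NA`
#'   denotes non-detection.
#' @return Matrix of relative values with the same dimnames.
#' @export
normalize_relative <- function(m) {
  m <- as.matrix(m)
  rm <- rowMeans(m, na.rm = TRUE)
  dead <- !is.finite(rm)
  if (any(dead)) {
    lab <- if (!is.null(rownames(m))) rownames(m)[dead] else which(dead)
    stop("row(s) with no observed intensity: ",
         paste(utils::head(lab, 5), collapse = ", "), call. = FALSE)
  }
  m / rm
}

#' Protein-abundance correction of site relative values
#'
#' Divides each site's relative value by the relative value of its parent
#' protein in the same sample, removing the contribution of protein
#' expression changes to apparent modification changes. Cells where the
#' protein value is missing (or zero) become missing. Sites that map to no
#' quantified protein are dropped with a warning by default.
#'
#' @param site_R Relative site matrix from [normalize_relative()]; rownames
#'   identify sites.
#' @param protein_R Relative protein matrix (rownames = protein ids) with the
#'   same sample columns.
#' @param site_protein Character vector, one protein id per row of `site_R`.
#' @param unmapped `"drop"` (default) or `"keep"` (kept uncorrected).
#' @return Corrected matrix; attribute `n_unmapped` counts affected sites.
#' @export
protein_correct <- function(site_R, protein_R, site_protein,
                            unmapped = c("drop", "keep")) {
  unmapped <- match.arg(unmapped)
  stopifnot(length(site_protein) == nrow(site_R))
  shared <- intersect(colnames(site_R), colnames(protein_R))
  if (length(shared) == 0) {
    stop("site and protein matrices share no sample columns", call. = FALSE)
  }
  site_R <- site_R[, shared, drop = FALSE]
  hit <- site_protein %in% rownames(protein_R)
  n_unmapped <- sum(!hit)
  if (n_unmapped > 0) {
    warning(n_unmapped, " site(s) without protein-level quantification",
            if (unmapped == "drop") " dropped" else " kept uncorrected",
            call. = FALSE)
  }
  denom <- matrix(NA_real_, nrow(site_R), length(shared),
                  dimnames = list(rownames(site_R), shared))
  denom[hit, ] <- protein_R[site_protein[hit], shared, drop = FALSE]
  denom[!is.na(denom) & denom == 0] <- NA_real_
  corrected <- site_R / denom
  if (unmapped == "keep") corrected[!hit, ] <- site_R[!hit, , drop = FALSE]
  if (unmapped == "drop") corrected <- corrected[hit, , drop = FALSE]
  attr(corrected, "n_unmapped") <- n_unmapped
  corrected
}

## Row-wise Welch t-test on log2 values; vectorised for large matrices.
## Cross-checked against stats::t.test in the unit tests.
welch_rows <- function(x0, x1) {
  n0 <- rowSums(!is.na(x0)); n1 <- rowSums(!is.na(x1))
  m0 <- rowMeans(x0, na.rm = TRUE); m1 <- rowMeans(x1, na.rm = TRUE)
  v0 <- rowSums((x0 - m0)^2, na.rm = TRUE) / pmax(n0 - 1, 1)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  se2 <- v0 / n0 + v1 / n1
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  ## degenerate zero-variance rows: identical groups carry no evidence,
  ## separated groups with zero spread are taken as maximal evidence
  zero <- is.finite(se2) & se2 == 0
  p[zero & m1 == m0] <- 1
  p[zero & m1 != m0] <- 0
  testable <- n0 >= 2 & n1 >= 2
  p[!testable] <- NA_real_
  list(p = p, n0 = n0, n1 = n1)
}

#' Per-site fold change and replicate test
#'
#' Computes, for each site, the treated/control fold change of mean corrected
#' values and a two-sided test on log2 corrected values, with
#' Benjamini-Hochberg adjustment across all tested sites. The default test is
#' the empirical-Bayes moderated t (limma), the standard choice at the
#' 3-replicates-per-group scale of label-free experiments, where per-site
#' variance estimates are too unstable for an unmoderated test; `"welch"`
#' selects a plain row-wise Welch t-test instead. A site is tested only when
#' both groups have at least two observed values; otherwise the fold change
#' (if computable) is reported with a missing p-value.
#'
#' @param corrected Corrected (or relative) value matrix; rownames = site ids.
#' @param design Data frame with `sample` and `group` columns covering the
#'   matrix columns.
#' @param control,treated Group labels in `design$group`.
#' @param test `"moderated"` (limma, default) or `"welch"`.
#' @return Data frame: `site_id`, `n_control`, `n_treated`, `mean_control`,
#'   `mean_treated`, `fold_change`, `log2_fc`, `p_value`, `adj_p`.
#' @export
site_fold_change <- function(corrected, design,
                             control = "control", treated = "treated",
                             test = c("moderated", "welch")) {
  test <- match.arg(test)
  s0 <- design$sample[design$group == control]
  s1 <- design$sample[design$group == treated]
  missing_s <- setdiff(c(s0, s1), colnames(corrected))
  if (length(missing_s) > 0) {
    stop("design sample(s) absent from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  x0 <- corrected[, s0, drop = FALSE]
  x1 <- corrected[, s1, drop = FALSE]
  n0 <- rowSums(!is.na(x0)); n1 <- rowSums(!is.na(x1))
  m0 <- rowMeans(x0, na.rm = TRUE); m1 <- rowMeans(x1, na.rm = TRUE)
  fc <- ifelse(n0 >= 1 & n1 >= 1, m1 / m0, NA_real_)
  p <- if (test == "moderated") {
    moderated_rows(log2(x0), log2(x1), n0, n1)
  } else {
    welch_rows(log2(x0), log2(x1))$p
  }
  adj <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(
    site_id = if (!is.null(rownames(corrected))) rownames(corrected)
              else as.character(seq_len(nrow(corrected))),
    n_control = n0, n_treated = n1,
    mean_control = ifelse(n0 >= 1, m0, NA_real_),
    mean_treated = ifelse(n1 >= 1, m1, NA_real_),
    fold_change = fc, log2_fc = log2(fc),
    p_value = p, adj_p = adj,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

## limma moderated t on log2 values; falls back to the Welch path when the
## matrix is too small for stable hyperparameter estimation.
moderated_rows <- function(lx0, lx1, n0, n1) {
  x <- cbind(lx0, lx1)
  ## hyperparameter estimation needs a population of residual variances;
  ## degenerate inputs (few rows, zero spread) go through the Welch path
  if (nrow(x) < 10) return(welch_rows(lx0, lx1)$p)
  grp <- factor(rep(c("a", "b"), c(ncol(lx0), ncol(lx1))), levels = c("a", "b"))
  dm <- stats::model.matrix(~grp)
  p <- tryCatch({
    fit <- suppressWarnings(limma::lmFit(x, dm))
    if (all(fit$sigma == 0, na.rm = TRUE)) stop("no residual variance")
    fit <- limma::eBayes(fit)
    unname(fit$p.value[, 2])
  }, error = function(e) welch_rows(lx0, lx1)$p)
  p[n0 < 2 | n1 < 2] <- NA_real_
  p
}

#' Classify sites as up/down/unchanged
#'
#' A site is `up` when its fold change exceeds `fc_threshold` with adjusted
#' p below `alpha`, `down` when the fold change is below `1/fc_threshold`
#' with adjusted p below `alpha`, and `unchanged` otherwise. Sites without a
#' p-value are never classified up or down.
#'
#' @param fc_table Output of [site_fold_change()].
#' @param fc_threshold Fold-change cut-off (default 2.0).
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @return `fc_table` with an added `class` column.
#' @export
classify_sites <- function(fc_table, fc_threshold = 2.0, alpha = 0.05) {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1)
  cls <- rep("unchanged", nrow(fc_table))
  ok <- !is.na(fc_table$adj_p) & !is.na(fc_table$fold_change)
  cls[ok & fc_table$adj_p < alpha & fc_table$fold_change > fc_threshold] <- "up"
  cls[ok & fc_table$adj_p < alpha &
        fc_table$fold_change < 1 / fc_threshold] <- "down"
  fc_table$class <- cls
  fc_table
}

#' Full site quantification from tables
#'
#' Convenience wrapper running the whole quantification chain on a site table
#' (and optionally a protein table): relative normalization, protein
#' correction, aggregation of multiple peptides covering one site (median of
#' corrected values per sample), fold change with Welch test and BH
#' adjustment, and classification. Without a protein table the correction
#' step is skipped and the result is flagged `corrected = FALSE`.
#'
#' @param sites Site data frame from [read_site_table()] (or equivalent).
#' @param design Design data frame (`sample`, `group`).
#' @param proteins Optional protein table from [read_protein_table()].
#' @param control,treated Group labels.
#' @param fc_threshold,alpha Passed to [classify_sites()].
#' @param test Replicate test, see [site_fold_change()].
#' @return List with `table` (per-site results incl. `protein_id`,
#'   `position`, `class`), `corrected` (the per-site value matrix) and
#'   `protein_corrected` (logical flag).
#' @export
quantify_sites <- function(sites, design, proteins = NULL,
                           control = "control", treated = "treated",
                           fc_threshold = 2.0, alpha = 0.05,
                           test = c("moderated", "welch")) {
  sample_cols <- attr(sites, "sample_cols")
  if (is.null(sample_cols)) {
    sample_cols <- intersect(design$sample, names(sites))
  }
  if (length(sample_cols) == 0) stop("no sample columns found", call. = FALSE)
  m <- as.matrix(sites[, sample_cols, drop = FALSE])
  rownames(m) <- paste0(sites$protein_id, "_K", sites$position)
  site_R <- normalize_relative(m)

  protein_corrected <- !is.null(proteins)
  if (protein_corrected) {
    pcols <- intersect(attr(proteins, "sample_cols") %||%
                         setdiff(names(proteins), "protein_id"),
                       sample_cols)
    pm <- as.matrix(proteins[, pcols, drop = FALSE])
    rownames(pm) <- proteins$protein_id
    protein_R <- normalize_relative(pm)
    vals <- protein_correct(site_R, protein_R, sites$protein_id,
                            unmapped = "drop")
  } else {
    vals <- site_R
  }

  ## aggregate peptides covering the same site: per-sample median
  ids <- rownames(vals)
  if (anyDuplicated(ids)) {
    uniq <- sort(unique(ids))
    med <- matrix(NA_real_, length(uniq), ncol(vals),
                  dimnames = list(uniq, colnames(vals)))
    for (s in seq_len(ncol(vals))) {
      med[, s] <- tapply(vals[, s], ids, stats::median, na.rm = TRUE)[uniq]
    }
    med[is.nan(med)] <- NA_real_
    vals <- med
  }

  fc <- site_fold_change(vals, design, control = control, treated = treated,
                         test = test)
  fc <- classify_sites(fc, fc_threshold = fc_threshold, alpha = alpha)
  fc$protein_id <- sub("_K[0-9]+$", "", fc$site_id)
  fc$position <- as.integer(sub("^.*_K", "", fc$site_id))
  list(table = fc, corrected = vals, protein_corrected = protein_corrected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
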