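#' Stratify proteome lysines into site classes
#'
#' Combines the proteome KC table, the quantified/classified site table, and
#' an optional subcellular localization map into one per-lysine table with
#' class labels: every proteome lysine belongs to `all-K`; lysines matching
#' an identified modification site are `lacK`; sites classified `up` by
#' [classify_sites()] are additionally `up-lacK`. Each lysine inherits its
#' protein's compartment (`other` when unannotated).
#'
#' @param kc_table Proteome KC table from [compute_kc_proteome()].
#' @param sites Optional site data frame with `protein_id`, `position` and
#'   optionally `class` columns.
#' @param localization Optional data frame (`protein_id`, `localization`).
#' @return Data frame with `protein_id`, `position`, `kc_distance`,
#'   `is_lacK`, `is_up`, `compartment`.
#' @export
stratify_sites <- function(kc_table, sites = NULL, localization = NULL) {
  out <- data.frame(
    protein_id = kc_table$protein_id,
    position = kc_table$lys_position,
    kc_distance = kc_table$kc_distance,
    is_lacK = FALSE, is_up = FALSE,
    compartment = "other",
    stringsAsFactors = FALSE
  )
  if (!is.null(sites) && nrow(sites) > 0) {
    key <- paste(out$protein_id, out$position, sep = "\r")
    skey <- paste(sites$protein_id, sites$position, sep = "\r")
    out$is_lacK <- key %in% skey
    if (!is.null(sites$class)) {
      upkey <- skey[sites$class == "up"]
      out$is_up <- key %in% upkey
    }
  }
  if (!is.null(localization)) {
    i <- match(out$protein_id, localization$protein_id)
    out$compartment <- ifelse(is.na(i), "other", localization$localization[i])
  }
  out
}

class_summary <- function(d, label) {
  d <- d[is.finite(d)]
  data.frame(class = label, n = length(d),
             mean_kc = if (length(d)) mean(d) else NA_real_,
             median_kc = if (length(d)) stats::median(d) else NA_real_,
             q25 = if (length(d)) unname(stats::quantile(d, 0.25)) else NA_real_,
             q75 = if (length(d)) unname(stats::quantile(d, 0.75)) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare KC-distance distributions across site classes
#'
#' Summarises KC distances per class (`all-K`, `lacK`, `up-lacK`, and the
#' lacK sites of each subcellular compartment) and runs pairwise two-sided
#' Mann-Whitney U tests with Benjamini-Hochberg adjustment over the pairs.
#' Because `lacK` is a subset of `all-K` (and `up-lacK` of `lacK`), each
#' nested pair is tested on disjoint underlying sets -- modified versus
#' unmodified lysines, upregulated versus non-upregulated sites -- while the
#' summary reports the classes as defined. Lysines with missing KC are
#' excluded throughout; classes with fewer than `min_n` values are excluded
#' from testing and flagged.
#'
#' @param strat Stratified table from [stratify_sites()].
#' @param min_n Minimum class size for testing (default 3).
#' @param compartments Compare lacK KC distances between compartments as well
#'   (default `TRUE` when more than one compartment label is present).
#' @return List with `summary` (per-class statistics), `tests` (pairwise
#'   results: `class_a`, `class_b`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `adj_p`) and `excluded` (classes too small to test).
#' @export
compare_kc_distributions <- function(strat, min_n = 3,
                                     compartments = NULL) {
  strat <- strat[is.finite(strat$kc_distance), , drop = FALSE]
  d <- strat$kc_distance
  lack <- d[strat$is_lacK]
  up <- d[strat$is_up]

  summary <- rbind(
    class_summary(d, "all-K"),
    class_summary(lack, "lacK"),
    class_summary(up, "up-lacK")
  )

  comp_labels <- unique(strat$compartment[strat$is_lacK])
  do_comp <- if (is.null(compartments)) length(comp_labels) > 1 else compartments
  if (do_comp) {
    for (cc in sort(comp_labels)) {
      summary <- rbind(summary,
        class_summary(d[strat$is_lacK & strat$compartment == cc],
                      paste0("lacK:", cc)))
    }
  }

  ## disjoint sample pairs actually tested
  pairs <- list(
    list("lacK", "all-K", lack, d[!strat$is_lacK]),
    list("up-lacK", "lacK", up, d[strat$is_lacK & !strat$is_up])
  )
  if (do_comp) {
    cl <- sort(comp_labels)
    if (length(cl) > 1) {
      for (i in seq_len(length(cl) - 1)) for (j in seq(i + 1, length(cl))) {
        pairs <- c(pairs, list(list(
          paste0("lacK:", cl[i]), paste0("lacK:", cl[j]),
          d[strat$is_lacK & strat$compartment == cl[i]],
          d[strat$is_lacK & strat$compartment == cl[j]])))
      }
    }
  }

  excluded <- character(0)
  rows <- list()
  for (p in pairs) {
    a <- p[[3]]; b <- p[[4]]
    if (length(a) < min_n || length(b) < min_n) {
      excluded <- union(excluded,
                        c(p[[1]], p[[2]])[c(length(a), length(b)) < min_n])
      next
    }
    ## exact U distribution for small tie-free samples, normal approximation
    ## otherwise (wilcox.test's own switching rule)
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    rows[[length(rows) + 1]] <- data.frame(
      class_a = p[[1]], class_b = p[[2]], n_a = length(a), n_b = length(b),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      stringsAsFactors = FALSE)
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_a = character(), class_b = character(),
               n_a = integer(), n_b = integer(), statistic = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  tests$adj_p <- stats::p.adjust(tests$p_value, method = "BH")
  list(summary = summary, tests = tests, excluded = excluded)
}
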