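#' Extract flanking-sequence windows around modified lysines
#'
#' Builds fixed-width sequence windows (half-width `w` on each side of the
#' central lysine) for a set of foreground sites, and background windows
#' around every other lysine in the proteome. Positions that fall outside the
#' sequence are marked with the boundary character `-` and excluded from
#' enrichment counts. Sites whose stated position is not a lysine, lies
#' beyond the sequence, or is on an unknown protein are rejected with one
#' warning reporting the count.
#'
#' @param proteome Data frame with `id` and `sequence` columns (see
#'   [read_fasta()]), or a named character vector of sequences.
#' @param sites Data frame with `protein_id` and `position` columns.
#' @param w Half-width of the window (default 6).
#' @return List with elements `fg` and `bg` (character vectors of
#'   `2w + 1`-long window strings), `w`, and `n_rejected`.
#' @export
extract_windows <- function(proteome, sites, w = 6L) {
  stopifnot(w >= 1)
  seqs <- if (is.data.frame(proteome)) {
    stats::setNames(proteome$sequence, proteome$id)
  } else {
    proteome
  }

  window_at <- function(seq, pos) {
    len <- nchar(seq)
    left_pad <- max(0L, w - pos + 1L)
    right_pad <- max(0L, pos + w - len)
    paste0(strrep("-", left_pad),
           substr(seq, max(1L, pos - w), min(len, pos + w)),
           strrep("-", right_pad))
  }

  n_rejected <- 0L
  fg <- character(0)
  fg_key <- character(0)
  for (r in seq_len(nrow(sites))) {
    pid <- sites$protein_id[r]; pos <- sites$position[r]
    seq <- unname(seqs[pid])
    if (is.null(seq) || is.na(seq) || pos < 1 || pos > nchar(seq) ||
        substr(seq, pos, pos) != "K") {
      n_rejected <- n_rejected + 1L
      next
    }
    fg <- c(fg, window_at(seq, pos))
    fg_key <- c(fg_key, paste(pid, pos, sep = "\r"))
  }
  if (n_rejected > 0) {
    warning(n_rejected, " site(s) rejected (unknown protein, position out of",
            " range, or residue not K)", call. = FALSE)
  }

  bg_parts <- lapply(names(seqs), function(pid) {
    seq <- seqs[[pid]]
    kpos <- gregexpr("K", seq, fixed = TRUE)[[1]]
    if (kpos[1] == -1) return(character(0))
    used <- as.integer(sub("^.*\r", "",
                           grep(paste0("^", pid, "\r"), fg_key, value = TRUE)))
    kpos <- setdiff(as.integer(kpos), used)
    vapply(kpos, function(pos) window_at(seq, pos), character(1))
  })
  list(fg = fg, bg = unlist(bg_parts), w = as.integer(w),
       n_rejected = n_rejected)
}

window_matrix <- function(windows, w) {
  m <- do.call(rbind, strsplit(windows, ""))
  stopifnot(ncol(m) == 2 * w + 1)
  colnames(m) <- as.character(c(-w:-1, 0, 1:w))
  m
}

#' Positional amino-acid enrichment around modified lysines
#'
#' For every relative position (-w..-1, +1..+w) and each of the 20 canonical
#' amino acids, contrasts the foreground frequency against the background
#' with a two-sided Fisher exact test on the 2x2 occurrence table, adjusted
#' with Benjamini-Hochberg across all cells. Boundary (`-`) and unknown
#' (`X`) characters are excluded from that position's totals. The displayed
#' `log2_enrichment` adds a 0.5 pseudocount to all four cells; the test uses
#' raw counts.
#'
#' @param fg,bg Character vectors of window strings sharing one half-width,
#'   as from [extract_windows()] (a list from `extract_windows()` can be
#'   given as `fg`, in which case `bg` is taken from it).
#' @param w Half-width; inferred from the window length when `NULL`.
#' @return Data frame with one row per (position, amino acid):
#'   `position`, `aa`, `fg_count`, `fg_total`, `bg_count`, `bg_total`,
#'   `log2_enrichment`, `p_value`, `adj_p`.
#' @export
position_enrichment <- function(fg, bg = NULL, w = NULL) {
  if (is.list(fg)) {
    bg <- fg$bg; w <- fg$w; fg <- fg$fg
  }
  if (length(fg) == 0) stop("empty foreground window set", call. = FALSE)
  if (length(bg) == 0) stop("empty background window set", call. = FALSE)
  if (is.null(w)) w <- (nchar(fg[1]) - 1L) %/% 2L
  fg_m <- window_matrix(fg, w)
  bg_m <- window_matrix(bg, w)
  positions <- c(-w:-1, 1:w)

  rows <- vector("list", length(positions) * length(AA20))
  k <- 0
  for (p in positions) {
    col <- as.character(p)
    fcol <- fg_m[, col]; bcol <- bg_m[, col]
    f_tab <- table(factor(fcol[fcol %in% AA20], levels = AA20))
    b_tab <- table(factor(bcol[bcol %in% AA20], levels = AA20))
    f_tot <- sum(f_tab); b_tot <- sum(b_tab)
    for (aa in AA20) {
      a <- f_tab[[aa]]; b <- b_tab[[aa]]
      p_val <- if (f_tot == 0 || b_tot == 0) NA_real_ else
        stats::fisher.test(matrix(c(a, f_tot - a, b, b_tot - b), 2))$p.value
      l2 <- log2(((a + 0.5) / (f_tot + 1)) / ((b + 0.5) / (b_tot + 1)))
      k <- k + 1
      rows[[k]] <- data.frame(position = p, aa = aa,
                              fg_count = a, fg_total = f_tot,
                              bg_count = b, bg_total = b_tot,
                              log2_enrichment = l2, p_value = p_val,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Cysteine spacing patterns around modified lysines
#'
#' Counts the cysteine patterns highlighted by short-range thiol catalysis:
#' `KXC` (C at +2), `CXXK` (C at -3) and `CXXXK` (C at -4), plus, for each
#' k = 1..w, the number of windows with a cysteine within +/- k of the
#' central lysine, and the number with no cysteine in the window at all.
#'
#' @param windows Character vector of window strings (or the list returned by
#'   [extract_windows()], whose foreground is used).
#' @param w Half-width; inferred when `NULL`.
#' @return List with `n_windows`, `pattern_counts` (named: KXC, CXXK,
#'   CXXXK), `within_k` (named integer vector, cumulative over offsets),
#'   `no_c`, and `nearest_c_offset` (per-window minimal |offset| to a C,
#'   `NA` when absent).
#' @export
count_cys_patterns <- function(windows, w = NULL) {
  if (is.list(windows)) {
    if (is.null(w)) w <- windows$w
    windows <- windows$fg
  }
  if (is.null(w)) w <- (nchar(windows[1]) - 1L) %/% 2L
  m <- window_matrix(windows, w)
  offsets <- c(-w:-1, 1:w)
  is_c <- m[, as.character(offsets), drop = FALSE] == "C"

  nearest <- apply(is_c, 1, function(row) {
    hits <- abs(offsets[row])
    if (length(hits) == 0) NA_integer_ else min(hits)
  })
  pattern_counts <- c(
    KXC   = if (w >= 2) sum(m[, "2"] == "C") else 0L,
    CXXK  = if (w >= 3) sum(m[, "-3"] == "C") else 0L,
    CXXXK = if (w >= 4) sum(m[, "-4"] == "C") else 0L
  )
  within_k <- vapply(seq_len(w), function(k) sum(!is.na(nearest) & nearest <= k),
                     integer(1))
  names(within_k) <- paste0("within_", seq_len(w))
  list(n_windows = nrow(m), pattern_counts = pattern_counts,
       within_k = within_k, no_c = sum(is.na(nearest)),
       nearest_c_offset = nearest)
}
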