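SITE_META_COLS <- c("protein_id", "position", "residue", "window", "localization")

#' Read a modification-site intensity table
#'
#' Consumes a tab-separated table in the minimal "Sites"-style schema emitted
#' by label-free search engines: one row per modified site with columns
#' `protein_id`, `position` (1-based residue index), `residue` (must be `K`),
#' optional `window` and `localization`, plus one numeric intensity column per
#' sample. Intensities equal to 0 (the label-free convention for
#' non-detection) or empty are stored as missing (`NA`). Rows whose residue is
#' not lysine are rejected with a single warning reporting the count.
#'
#' @param file Path to the TSV file (header row required).
#' @param sample_cols Character vector naming the intensity columns; defaults
#'   to every non-metadata column.
#' @return A data frame of accepted rows. Attributes: `sample_cols` (the
#'   intensity column names) and `n_rejected` (number of non-K rows dropped).
#' @export
read_site_table <- function(file, sample_cols = NULL) {
  x <- utils::read.delim(file, sep = "\t", check.names = FALSE,
                         na.strings = c("NA", ""), stringsAsFactors = FALSE)
  needed <- c("protein_id", "position", "residue")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sample_cols)) sample_cols <- setdiff(names(x), SITE_META_COLS)
  if (length(sample_cols) == 0) {
    stop("site table has no sample intensity columns", call. = FALSE)
  }
  x$position <- as.integer(x$position)
  if (any(is.na(x$position) | x$position < 1)) {
    stop("site positions must be integers >= 1", call. = FALSE)
  }
  ok <- x$residue == "K"
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " row(s) with non-lysine residue rejected",
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(x[[s]]))
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative intensity in column '", s, "'", call. = FALSE)
    }
    v[!is.na(v) & v == 0] <- NA_real_
    x[[s]] <- v
  }
  rownames(x) <- NULL
  attr(x, "sample_cols") <- sample_cols
  attr(x, "n_rejected") <- n_rejected
  x
}

#' Read a protein-level intensity table
#'
#' Same conventions as [read_site_table()] but keyed by `protein_id` only;
#' used for protein-abundance correction of site intensities.
#'
#' @param file Path to the TSV file.
#' @param sample_cols Intensity column names; default: all but `protein_id`.
#' @return Data frame with attribute `sample_cols`.
#' @export
read_protein_table <- function(file, sample_cols = NULL) {
  x <- utils::read.delim(file, sep = "\t", check.names = FALSE,
                         na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(x)) {
    stop("protein table lacks a protein_id column", call. = FALSE)
  }
  if (anyDuplicated(x$protein_id)) {
    stop("duplicate protein_id in protein table", call. = FALSE)
  }
  if (is.null(sample_cols)) sample_cols <- setdiff(names(x), "protein_id")
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(x[[s]]))
    v[!is.na(v) & v == 0] <- NA_real_
    x[[s]] <- v
  }
  attr(x, "sample_cols") <- sample_cols
  x
}

#' Read a sample-to-group design table
#'
#' @param file TSV with columns `sample` and `group`.
#' @return Data frame with those two character columns.
#' @export
read_design <- function(file) {
  x <- utils::read.delim(file, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(x))) {
    stop("design table needs 'sample' and 'group' columns", call. = FALSE)
  }
  x$sample <- as.character(x$sample)
  x$group <- as.character(x$group)
  x
}

#' Read a subcellular localization table
#'
#' @param file TSV with columns `protein_id` and `localization`
#'   (`cytosol`, `mitochondria`, `nucleus` or `other`).
#' @return Data frame; unknown labels are recoded to `other` with a warning.
#' @export
read_localization <- function(file) {
  x <- utils::read.delim(file, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("protein_id", "localization") %in% names(x))) {
    stop("localization table needs 'protein_id' and 'localization' columns",
         call. = FALSE)
  }
  known <- c("cytosol", "mitochondria", "nucleus", "other")
  bad <- !(x$localization %in% known)
  if (any(bad)) {
    warning(sum(bad), " unknown localization label(s) recoded to 'other'",
            call. = FALSE)
    x$localization[bad] <- "other"
  }
  x
}

#' Write a table as deterministic TSV
#'
#' Tab separator, `.` decimal mark, missing values rendered as `NA`, no
#' quoting, no row names. Numeric columns are serialised with 17 significant
#' digits so that [read_tsv()] round-trips them exactly.
#'
#' @param x Data frame.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_tsv <- function(x, file) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      v <- sprintf("%.17g", y[[j]])
      v[is.na(y[[j]])] <- NA_character_
      y[[j]] <- v
    }
  }
  utils::write.table(y, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param file Path to the file.
#' @return Data frame with `NA` strings restored to missing values.
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", check.names = FALSE,
                    na.strings = "NA", stringsAsFactors = FALSE)
}
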