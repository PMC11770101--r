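AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a protein FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' pipeline's sequence contract: record ids are the first whitespace-delimited
#' token of the header, sequences are upper-cased and restricted to the 20
#' canonical amino acids plus `X`.
#'
#' @param file Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`; zero rows for an
#'   empty file.
#' @export
read_fasta <- function(file) {
  empty <- data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (is.character(file) && file.exists(file)) {
    head_lines <- readLines(file, n = 50L, warn = FALSE)
    if (!any(startsWith(head_lines, ">"))) return(empty)
  }
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(file),
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        stop("illegal sequence character(s): ", conditionMessage(w),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0) return(empty)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 c(AA20, "X"))
  if (length(bad) > 0) {
    stop("illegal sequence character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence record(s) in FASTA", call. = FALSE)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Data frame with `id` and `sequence` columns (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_fasta <- function(seqs, file) {
  if (is.data.frame(seqs)) {
    v <- stats::setNames(seqs$sequence, seqs$id)
  } else {
    v <- seqs
  }
  set <- Biostrings::AAStringSet(v)
  Biostrings::writeXStringSet(set, file, width = 60L)
  invisible(file)
}
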