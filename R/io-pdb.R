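#' Parse a PDB coordinate file
#'
#' Reads fixed-column `ATOM` records from a PDB file into a light-weight
#' structure record. By default only the first `MODEL` of a multi-model
#' (NMR-style) file is retained, alternate locations are resolved to the
#' highest-occupancy conformer (ties go to the first record encountered) and
#' `HETATM` records are dropped. Residue numbering is taken verbatim from the
#' file; for AlphaFold models this equals the 1-based UniProt position.
#'
#' @param file Path to a PDB file (or a connection readable by
#'   [base::readLines()]).
#' @param source_id Identifier stored on the record; defaults to the file name
#'   without extension.
#' @param model Which `MODEL` block to keep when the file contains several
#'   (integer, 1-based). Files without `MODEL` records are treated as a single
#'   model.
#' @param keep_hetatm Retain `HETATM` records as well (default `FALSE`).
#'
#' @return An object of class `pdb_structure`: a list with elements
#'   `source_id`, `model_index`, `chains` (character vector) and `atoms`, a
#'   data frame with columns `chain`, `resno`, `icode`, `resname`, `atom`,
#'   `altloc`, `x`, `y`, `z`, `occ`, `b` (coordinates in Angstrom; `b` carries
#'   the B-factor / AlphaFold pLDDT column).
#' @export
read_pdb <- function(file, source_id = NULL, model = 1L, keep_hetatm = FALSE) {
  if (is.null(source_id)) {
    source_id <- if (is.character(file)) {
      tools::file_path_sans_ext(basename(file))
    } else {
      "structure"
    }
  }
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)

  ## restrict to the requested MODEL block, if the file declares any
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0) {
    if (model > length(model_starts)) {
      stop("requested model ", model, " but file declares only ",
           length(model_starts), " MODEL block(s)", call. = FALSE)
    }
    start <- model_starts[model]
    ends <- which(rec == "ENDMDL")
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines)
    keep <- seq(start, end)
  } else {
    keep <- seq_along(lines)
  }

  wanted <- c("ATOM  ", if (keep_hetatm) "HETATM")
  idx <- keep[rec[keep] %in% wanted]
  if (length(idx) == 0) {
    stop("no ATOM records found in '", source_id, "'", call. = FALSE)
  }
  al <- lines[idx]

  num <- function(from, to, what, required = TRUE) {
    raw <- trimws(substr(al, from, to))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & (required | nzchar(raw)))
    if (length(bad) > 0) {
      stop("malformed ", what, " field at line ", idx[bad[1]],
           " of '", source_id, "': '", raw[bad[1]], "'", call. = FALSE)
    }
    val
  }

  atoms <- data.frame(
    chain   = substr(al, 22, 22),
    resno   = as.integer(num(23, 26, "residue number")),
    icode   = trimws(substr(al, 27, 27)),
    resname = trimws(substr(al, 18, 20)),
    atom    = trimws(substr(al, 13, 16)),
    altloc  = trimws(substr(al, 17, 17)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occ = num(55, 60, "occupancy", required = FALSE),
    b   = num(61, 66, "B-factor", required = FALSE),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1

  ## altloc resolution: keep the highest-occupancy conformer of each atom,
  ## ties resolved in file order (stable sort)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  ord <- order(-atoms$occ)             # stable: preserves file order on ties
  sel <- sort(ord[!duplicated(key[ord])])
  atoms <- atoms[sel, , drop = FALSE]
  rownames(atoms) <- NULL

  structure(
    list(source_id = source_id, model_index = as.integer(model),
         chains = unique(atoms$chain), atoms = atoms),
    class = "pdb_structure"
  )
}

#' Construct a structure record from an atom table
#'
#' Low-level constructor used by the synthetic generator and by tests; takes
#' the same atom columns [read_pdb()] produces.
#'
#' @param source_id Identifier for the structure.
#' @param atoms Data frame with at least `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`; `icode`, `altloc`, `occ`, `b` are filled with defaults
#'   when absent.
#' @param model_index Model number stored on the record.
#' @return A `pdb_structure` object.
#' @export
pdb_structure <- function(source_id, atoms, model_index = 1L) {
  stopifnot(is.data.frame(atoms))
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  structure(
    list(source_id = source_id, model_index = as.integer(model_index),
         chains = unique(atoms$chain), atoms = atoms),
    class = "pdb_structure"
  )
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", x$source_id,
      ": ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues, chain(s) ",
      paste(x$chains, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Write a structure record as PDB text
#'
#' Emits fixed-column `ATOM` records (coordinates at the PDB's 3-decimal
#' precision) followed by `TER`/`END`. Round-tripping through [read_pdb()]
#' recovers coordinates to 0.001 Angstrom.
#'
#' @param structure A `pdb_structure`.
#' @param file Output path; when `NULL` the text is returned invisibly as a
#'   character vector instead of written.
#' @return Invisibly, the PDB text lines.
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atoms
  element <- substr(gsub("[^A-Za-z].*", "", a$atom), 1, 1)
  name_fmt <- ifelse(nchar(a$atom) <= 3, sprintf(" %-3s", a$atom),
                     sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, substr(paste0(a$altloc, " "), 1, 1),
    a$resname, a$chain, a$resno, substr(paste0(a$icode, " "), 1, 1),
    a$x, a$y, a$z, a$occ, a$b, element)
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
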