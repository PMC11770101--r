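SIDE_CHAIN_ATOM <- c(LYS = "NZ", CYS = "SG")

#' Extract side-chain reference atoms from a structure
#'
#' Collects one 3-D point per residue of the requested kind: the epsilon-amino
#' nitrogen (`NZ`) for lysine or the thiol sulfur (`SG`) for cysteine.
#' Residues of that kind which lack the reference atom (truncated side chains)
#' are skipped and counted, never imputed.
#'
#' @param structure A `pdb_structure` (see [read_pdb()]).
#' @param residue `"LYS"` or `"CYS"`.
#' @param chain Optional chain id to restrict to.
#' @param min_plddt Optional lower bound on the B-factor column (AlphaFold
#'   pLDDT); residues below it are dropped.
#' @return Data frame with columns `chain`, `resno`, `x`, `y`, `z`, ordered by
#'   (chain, resno); attribute `n_skipped` counts residues of the requested
#'   kind lacking the reference atom.
#' @export
extract_side_chain_points <- function(structure, residue = c("LYS", "CYS"),
                                      chain = NULL, min_plddt = NULL) {
  residue <- match.arg(residue)
  target <- SIDE_CHAIN_ATOM[[residue]]
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[a$resname == residue, , drop = FALSE]
  if (!is.null(min_plddt)) a <- a[is.na(a$b) | a$b >= min_plddt, , drop = FALSE]
  res_key <- unique(paste(a$chain, a$resno, sep = "\r"))
  hit <- a[a$atom == target, , drop = FALSE]
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  out <- data.frame(chain = hit$chain, resno = hit$resno,
                    x = hit$x, y = hit$y, z = hit$z,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(res_key) - nrow(out)
  out
}

#' Distance from one lysine to its nearest cysteine thiol
#'
#' Returns the minimum Euclidean distance from a lysine NZ point to a set of
#' cysteine SG points, together with the identity of the nearest cysteine.
#' Ties are broken towards the lower residue index (then chain order).
#'
#' @param lys Numeric length-3 vector `c(x, y, z)` or a one-row data frame
#'   with `x`, `y`, `z` columns.
#' @param cys_points Data frame of cysteine SG points as produced by
#'   [extract_side_chain_points()]; may have zero rows.
#' @return List with `nearest_chain`, `nearest_resno` and `distance`
#'   (Angstrom); all `NA` when `cys_points` is empty.
#' @export
kc_distance_for_lysine <- function(lys, cys_points) {
  if (is.data.frame(lys)) lys <- c(lys$x[1], lys$y[1], lys$z[1])
  if (nrow(cys_points) == 0) {
    return(list(nearest_chain = NA_character_, nearest_resno = NA_integer_,
                distance = NA_real_))
  }
  cp <- cys_points[order(cys_points$chain, cys_points$resno), , drop = FALSE]
  d <- sqrt((cp$x - lys[1])^2 + (cp$y - lys[2])^2 + (cp$z - lys[3])^2)
  i <- which.min(d)   # first minimum = lowest (chain, resno) on ties
  list(nearest_chain = cp$chain[i], nearest_resno = as.integer(cp$resno[i]),
       distance = d[i])
}

#' KC-distance table for one structure
#'
#' For every lysine bearing an NZ atom, computes the Euclidean distance to the
#' spatially nearest cysteine SG atom (the "KC distance") and records which
#' cysteine it is. By default the search is confined to the lysine's own chain
#' (the right scope for single-chain predicted models); `cross_chain = TRUE`
#' searches all chains, as needed for experimental multi-chain entries.
#' Lysines in a scope containing no cysteine SG get a missing distance.
#'
#' @param structure A `pdb_structure`.
#' @param cross_chain Search cysteines across all chains (default `FALSE`).
#' @param min_plddt Optional pLDDT/B-factor lower bound applied to both atom
#'   sets (no filter by default).
#' @return Data frame with one row per lysine, ordered by (chain,
#'   lys_position): `protein_id`, `chain`, `lys_position`,
#'   `nearest_cys_chain`, `nearest_cys_position`, `kc_distance` (Angstrom).
#' @export
compute_kc_table <- function(structure, cross_chain = FALSE, min_plddt = NULL) {
  lys <- extract_side_chain_points(structure, "LYS", min_plddt = min_plddt)
  cys <- extract_side_chain_points(structure, "CYS", min_plddt = min_plddt)
  empty <- data.frame(
    protein_id = character(), chain = character(), lys_position = integer(),
    nearest_cys_chain = character(), nearest_cys_position = integer(),
    kc_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(lys) == 0) return(empty)

  one_scope <- function(lys_k, cys_k) {
    n <- nrow(lys_k)
    res <- data.frame(
      protein_id = rep(structure$source_id, n),
      chain = lys_k$chain, lys_position = as.integer(lys_k$resno),
      nearest_cys_chain = NA_character_,
      nearest_cys_position = NA_integer_, kc_distance = NA_real_,
      stringsAsFactors = FALSE)
    if (nrow(cys_k) > 0) {
      ## n_lys x n_cys distance matrix; cys sorted so that the first minimum
      ## is the lowest (chain, resno) on exact ties
      d2 <- outer(lys_k$x, cys_k$x, "-")^2 +
            outer(lys_k$y, cys_k$y, "-")^2 +
            outer(lys_k$z, cys_k$z, "-")^2
      j <- apply(d2, 1, which.min)
      res$nearest_cys_chain <- cys_k$chain[j]
      res$nearest_cys_position <- as.integer(cys_k$resno[j])
      res$kc_distance <- sqrt(d2[cbind(seq_len(nrow(d2)), j)])
    }
    res
  }

  if (cross_chain) {
    out <- one_scope(lys, cys)
  } else {
    out <- do.call(rbind, lapply(split(lys, lys$chain), function(lk) {
      one_scope(lk, cys[cys$chain == lk$chain[1], , drop = FALSE])
    }))
  }
  out <- out[order(out$chain, out$lys_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' KC-distance table over a set of structures
#'
#' Applies [compute_kc_table()] to every structure of a proteome and stacks
#' the results. Structures may be given as a directory of `*.pdb` files, a
#' character vector of file paths, or a list of `pdb_structure` objects.
#'
#' @param structures Directory path, file paths, or list of structures.
#' @param ... Passed on to [compute_kc_table()].
#' @return One combined KC-distance data frame.
#' @export
compute_kc_proteome <- function(structures, ...) {
  if (is.character(structures)) {
    if (length(structures) == 1 && dir.exists(structures)) {
      structures <- list.files(structures, pattern = "\\.pdb$",
                               full.names = TRUE)
      structures <- structures[order(basename(structures))]
    }
    structures <- lapply(structures, read_pdb)
  }
  out <- do.call(rbind, lapply(structures, compute_kc_table, ...))
  rownames(out) <- NULL
  out
}

#' Annotate modification sites with KC distances
#'
#' Joins a site table to a proteome KC table on (`protein_id`, position).
#' Sites without a matching lysine record get missing KC values and are
#' counted in the `n_unmatched` attribute. Duplicate (protein, position) keys
#' in the KC table are an error: they indicate that a multi-chain structure
#' was processed without choosing a chain scope.
#'
#' @param sites Site data frame with `protein_id` and `position` columns.
#' @param kc_table Output of [compute_kc_proteome()].
#' @return `sites` with added `kc_distance` and `nearest_cys_position`
#'   columns; attribute `n_unmatched`.
#' @export
annotate_sites_with_kc <- function(sites, kc_table) {
  key_kc <- paste(kc_table$protein_id, kc_table$lys_position, sep = "\r")
  if (anyDuplicated(key_kc)) {
    stop("duplicate (protein_id, lys_position) in KC table; ",
         "was a multi-chain structure processed without a chain scope?",
         call. = FALSE)
  }
  key_s <- paste(sites$protein_id, sites$position, sep = "\r")
  i <- match(key_s, key_kc)
  sites$kc_distance <- kc_table$kc_distance[i]
  sites$nearest_cys_position <- kc_table$nearest_cys_position[i]
  attr(sites, "n_unmatched") <- sum(is.na(i))
  sites
}
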