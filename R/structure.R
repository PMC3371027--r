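# Optional structure companion: parse a PDB chain, map one alignment
# row onto the structure's residue sequence, and annotate the pairwise
# covariation summary with inter-residue distances.  Distances are a
# pure annotation — they never change MI/MIp/Zp.

#' Parse residue coordinates from a PDB file
#'
#' Reads ATOM records of one chain (HETATM is ignored); for
#' alternate-location atoms only the first-listed altloc is kept.
#' Residues are keyed by residue number plus insertion code.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier (default `"A"`).
#' @return A `loco_structure` object: `atoms` (tibble `res_key`,
#'   `resno`, `ins`, `resid`, `elety`, `x`, `y`, `z`), `residues`
#'   (tibble `res_key`, `resno`, `resid`, `aa` one-letter), `chain`.
#' @export
parse_structure <- function(path, chain = "A") {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "locovar_input_error")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (!nrow(at)) {
    abort(paste0("no ATOM records for chain '", chain, "'"),
          class = "locovar_input_error")
  }
  # keep the first-listed altloc per (residue, atom name)
  at$ins[is.na(at$ins)] <- ""
  at$res_key <- paste0(at$resno, at$ins)
  dup <- duplicated(at[, c("res_key", "elety")])
  at <- at[!dup, , drop = FALSE]
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    abort("non-finite atom coordinates", class = "locovar_format_error")
  }
  atoms <- tibble(
    res_key = at$res_key, resno = at$resno, ins = at$ins, resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z
  )
  res <- atoms[!duplicated(atoms$res_key), c("res_key", "resno", "resid")]
  res$aa <- bio3d::aa321(res$resid)
  res$aa[is.na(res$aa) | res$aa == ""] <- "X"
  structure(list(atoms = atoms, residues = res, chain = chain),
            class = "loco_structure")
}

#' @export
print.loco_structure <- function(x, ...) {
  cat("<loco_structure> chain ", x$chain, ": ", nrow(x$residues),
      " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Map an alignment row onto a structure's residue sequence
#'
#' Globally aligns the ungapped residues of one alignment row to the
#' structure's one-letter sequence (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]) and assigns each non-gap
#' alignment column to at most one structure residue.  The fraction of
#' identical residues over the aligned overlap must reach
#' `min_identity`.
#'
#' @param aln An alignment tibble.
#' @param row_id Id of the row carrying the structure's sequence.
#' @param struct A `loco_structure` from [parse_structure()].
#' @param min_identity Identity floor over the aligned overlap
#'   (default 0.9).
#' @return A tibble with one row per original alignment column of the
#'   chosen row: `original_col`, `residue` (alignment character),
#'   `res_key` (`NA` for gaps and unmapped columns) and `mismatch`
#'   (TRUE where the mapped residue differs).
#' @export
map_row_to_structure <- function(aln, row_id, struct, min_identity = 0.9) {
  aln <- as_alignment(aln)
  stopifnot(inherits(struct, "loco_structure"))
  if (!row_id %in% aln$id) {
    abort(paste0("row '", row_id, "' not in alignment"), class = "locovar_input_error")
  }
  row_chars <- strsplit(aln$seq[aln$id == row_id], "")[[1]]
  non_gap_cols <- which(row_chars != GAP)
  row_seq <- paste(row_chars[non_gap_cols], collapse = "")
  str_seq <- paste(struct$residues$aa, collapse = "")
  pa <- Biostrings::pairwiseAlignment(row_seq, str_seq, type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ri <- cumsum(p_chars != "-")   # index into the ungapped row
  si <- cumsum(s_chars != "-")   # index into the structure residues
  both <- p_chars != "-" & s_chars != "-"
  if (!any(both)) {
    abort("row and structure sequences do not align", class = "locovar_mapping_error")
  }
  identity <- mean(p_chars[both] == s_chars[both])
  if (identity < min_identity) {
    abort(sprintf("row/structure identity %.2f below floor %.2f over %d aligned residues",
                  identity, min_identity, sum(both)),
          class = "locovar_mapping_error")
  }
  res_key_of_row_pos <- rep(NA_character_, length(non_gap_cols))
  mism <- rep(NA, length(non_gap_cols))
  res_key_of_row_pos[ri[both]] <- struct$residues$res_key[si[both]]
  mism[ri[both]] <- p_chars[both] != s_chars[both]
  out <- tibble(
    original_col = seq_along(row_chars),
    residue = row_chars,
    res_key = NA_character_,
    mismatch = NA
  )
  out$res_key[non_gap_cols] <- res_key_of_row_pos
  out$mismatch[non_gap_cols] <- mism
  out
}

# minimum heavy-atom distance between two residues (res_key strings)
min_residue_distance <- function(struct, key_a, key_b, convention = "min_heavy") {
  atoms <- struct$atoms
  sel_a <- atoms[atoms$res_key == key_a, , drop = FALSE]
  sel_b <- atoms[atoms$res_key == key_b, , drop = FALSE]
  if (convention == "cb") {
    pick <- function(s) {
      cb <- s[s$elety == "CB", , drop = FALSE]
      if (nrow(cb)) cb else s[s$elety == "CA", , drop = FALSE]  # GLY fallback
    }
    sel_a <- pick(sel_a); sel_b <- pick(sel_b)
  } else {
    sel_a <- sel_a[!grepl("^H", sel_a$elety), , drop = FALSE]
    sel_b <- sel_b[!grepl("^H", sel_b$elety), , drop = FALSE]
  }
  if (!nrow(sel_a) || !nrow(sel_b)) return(NA_real_)
  ca <- as.matrix(sel_a[, c("x", "y", "z")])
  cb <- as.matrix(sel_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  sqrt(max(min(d2), 0))
}

#' Inter-residue distances for mapped column pairs
#'
#' @param struct A `loco_structure`.
#' @param mapping Column-to-residue mapping from
#'   [map_row_to_structure()].
#' @param pairs Tibble with `col_a`, `col_b` (original 1-based
#'   columns); self-pairs are rejected.
#' @param convention `"min_heavy"` (default): minimum distance over
#'   all heavy-atom pairs; `"cb"`: CB-CB (CA for glycine).
#' @return `pairs` with a `distance_angstrom` column; `NA` where
#'   either column is unmapped.
#' @export
pair_distances <- function(struct, mapping, pairs, convention = c("min_heavy", "cb")) {
  convention <- match.arg(convention)
  stopifnot(all(c("col_a", "col_b") %in% names(pairs)))
  if (any(pairs$col_a == pairs$col_b)) {
    abort("self-pairs are not reported", class = "locovar_input_error")
  }
  key_of <- setNames(mapping$res_key, mapping$original_col)
  pairs$distance_angstrom <- purrr::map2_dbl(pairs$col_a, pairs$col_b, function(a, b) {
    ka <- key_of[[as.character(a)]]
    kb <- key_of[[as.character(b)]]
    if (is.na(ka) || is.na(kb)) return(NA_real_)
    min_residue_distance(struct, ka, kb, convention)
  })
  pairs
}

#' Annotate a covariation summary with structure distances
#'
#' Joins minimum inter-residue distances onto the tidy per-pair
#' covariation table, using one alignment row as the bridge to the
#' structure.  Covariation values are untouched.
#'
#' @param cv A `loco_covariation` object (or its [tidy()] table).
#' @param aln The alignment the covariation was computed from.
#' @param row_id Alignment row matching the structure.
#' @param struct A `loco_structure`.
#' @param min_identity Identity floor for the row/structure mapping.
#' @param convention Distance convention, see [pair_distances()].
#' @return The tidy pair tibble with `distance_angstrom` appended.
#' @export
annotate_distances <- function(cv, aln, row_id, struct, min_identity = 0.9,
                               convention = "min_heavy") {
  pairs <- if (inherits(cv, "loco_covariation")) tidy(cv) else cv
  mapping <- map_row_to_structure(aln, row_id, struct, min_identity = min_identity)
  pair_distances(struct, mapping, pairs, convention = convention)
}
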