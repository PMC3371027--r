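# Curation helpers: cluster sequences over a flagged column range by
# percent-identity neighbour joining, reorder by the tree, apply
# segment shift edits, and recompute the local-covariation profile.
# Systematically misaligned rows cluster into their own clade over the
# flagged range; sliding them back into register dissolves the clade
# and drops the local-covariation peak.

#' Percent-identity distance matrix over a column range
#'
#' Distance is `1 - fraction identity` computed over the selected
#' columns, with pairwise deletion: positions where either sequence
#' has a gap are excluded from the comparison.  A pair with zero
#' comparable positions gets distance 1 with a warning.
#'
#' @param aln An alignment tibble.
#' @param col_range Inclusive 1-based original-column range
#'   `c(first, last)`; default spans the whole alignment.
#' @return A symmetric `dist`-compatible matrix with sequence ids as
#'   dimnames, values in `[0, 1]`, zero diagonal.
#' @export
percent_identity_distances <- function(aln, col_range = NULL) {
  aln <- as_alignment(aln)
  w <- alignment_width(aln)
  col_range <- col_range %||% c(1L, w)
  stopifnot(length(col_range) == 2)
  if (col_range[1] < 1 || col_range[2] > w || col_range[1] > col_range[2]) {
    abort("column range outside the alignment", class = "locovar_input_error")
  }
  m <- aln_matrix(aln)[, col_range[1]:col_range[2], drop = FALSE]
  n <- nrow(m)
  ng <- (m != GAP) * 1
  comparable <- tcrossprod(ng)           # gap-free positions per pair
  matches <- matrix(0, n, n)
  for (s in unique(as.vector(m))) {
    if (s == GAP) next
    is_s <- (m == s) * 1
    matches <- matches + tcrossprod(is_s)
  }
  d <- 1 - matches / pmax(comparable, 1)
  if (any(comparable[upper.tri(comparable)] == 0)) {
    warn("some sequence pairs share no comparable (gap-free) positions; distance set to 1")
    d[comparable == 0] <- 1
  }
  diag(d) <- 0
  dimnames(d) <- list(aln$id, aln$id)
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration (via [ape::nj()]).  Negative
#' branch lengths, which NJ can produce on non-additive matrices, are
#' clamped to zero and recorded in the `clamped` attribute.
#'
#' @param dm Symmetric distance matrix with row/column ids.
#' @return An [ape] `phylo` tree whose tips are the sequence ids, with
#'   attribute `clamped` (TRUE if any branch length was raised to 0).
#' @export
neighbour_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) {
    abort("neighbour joining needs at least 3 sequences",
          class = "locovar_input_error")
  }
  tr <- ape::nj(stats::as.dist(dm))
  clamped <- any(tr$edge.length < 0)
  if (clamped) tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Tip order of a tree as drawn
#'
#' @param tree A `phylo` object.
#' @return Character vector of tip labels in plotted (cladewise) order.
#' @export
tree_leaf_order <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  tr$tip.label[tr$edge[tr$edge[, 2] <= ape::Ntip(tr), 2]]
}

#' Reorder alignment rows to match a tree
#'
#' @param aln An alignment tibble.
#' @param tree A `phylo` whose tip set equals the alignment ids.
#' @return The alignment with rows permuted to tree leaf order;
#'   residues untouched.
#' @export
sort_by_tree <- function(aln, tree) {
  aln <- as_alignment(aln)
  ord <- tree_leaf_order(tree)
  if (!setequal(ord, aln$id) || length(ord) != nrow(aln)) {
    abort("tree tips do not match alignment ids", class = "locovar_input_error")
  }
  aln[match(ord, aln$id), ]
}

#' Does the tree contain a clean bipartition of a set of tips?
#'
#' TRUE when some internal edge of the (unrooted) tree splits exactly
#' `ids` from the remaining tips — the signature of a misaligned
#' cluster sitting in its own clade.
#'
#' @param tree A `phylo` object.
#' @param ids Tip labels forming the candidate group.
#' @return Logical.
#' @export
has_bipartition <- function(tree, ids) {
  tips <- tree$tip.label
  stopifnot(all(ids %in% tips))
  k <- length(ids)
  if (k == 0 || k == length(tips)) return(TRUE)
  if (k == 1 || k == length(tips) - 1) return(TRUE)  # trivial pendant split
  target <- sort(match(ids, tips))
  parts <- ape::prop.part(ape::unroot(tree))
  for (p in parts) {
    if (length(p) == k && all(sort(p) == target)) return(TRUE)
    if (length(p) == length(tips) - k &&
        all(sort(setdiff(seq_along(tips), p)) == target)) return(TRUE)
  }
  FALSE
}

#' Apply a segment shift edit
#'
#' Slides the residues of the chosen rows by `offset` columns within
#' `col_range`, emulating dragging a misaligned segment back into
#' register.  The move must be absorbed by gaps at the corresponding
#' edge of the range: a right shift (+k) needs k gap columns at the
#' right edge of the segment, a left shift (-k) needs them at the
#' left.  Total width is unchanged and the ungapped residue content of
#' every row is preserved; rows not listed are untouched.
#'
#' @param aln An alignment tibble.
#' @param rows Ids of rows to edit.
#' @param col_range Inclusive 1-based original-column range.
#' @param offset Signed shift (positive = right); must be non-zero.
#' @return The edited alignment tibble.
#' @export
apply_shift_edit <- function(aln, rows, col_range, offset) {
  aln <- as_alignment(aln)
  stopifnot(length(col_range) == 2, offset == round(offset))
  offset <- as.integer(offset)
  if (offset == 0L) abort("offset must be non-zero", class = "locovar_input_error")
  w <- alignment_width(aln)
  if (col_range[1] < 1 || col_range[2] > w || col_range[1] > col_range[2]) {
    abort("column range outside the alignment", class = "locovar_input_error")
  }
  missing_rows <- setdiff(rows, aln$id)
  if (length(missing_rows)) {
    abort(paste0("rows not in alignment: ", paste(head(missing_rows, 5), collapse = ", ")),
          class = "locovar_input_error")
  }
  m <- aln_matrix(aln)
  rng <- col_range[1]:col_range[2]
  len <- length(rng)
  if (abs(offset) >= len) {
    abort("offset exceeds the segment length", class = "locovar_input_error")
  }
  for (r in rows) {
    seg <- m[r, rng]
    if (offset > 0L) {
      if (!all(seg[(len - offset + 1L):len] == GAP)) {
        abort(paste0("blocked edit: row '", r, "' has no absorbing gap at the ",
                     "right edge of columns ", col_range[1], "-", col_range[2]),
              class = "locovar_blocked_edit_error")
      }
      m[r, rng] <- c(rep(GAP, offset), seg[1:(len - offset)])
    } else {
      k <- -offset
      if (!all(seg[1:k] == GAP)) {
        abort(paste0("blocked edit: row '", r, "' has no absorbing gap at the ",
                     "left edge of columns ", col_range[1], "-", col_range[2]),
              class = "locovar_blocked_edit_error")
      }
      m[r, rng] <- c(seg[(k + 1L):len], rep(GAP, k))
    }
  }
  matrix_to_alignment(m)
}

#' Read a JSON edit script
#'
#' An edit script is a JSON array of objects with fields `rows`
#' (array of ids), `range` (`[first, last]`, 1-based inclusive) and
#' `offset` (signed integer).
#'
#' @param path Path to the JSON file.
#' @return A list of edits, each a list with `rows`, `range`, `offset`.
#' @export
read_edit_script <- function(path) {
  edits <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(edits)) edits <- split(edits, seq_len(nrow(edits)))
  lapply(edits, function(e) {
    list(rows = unlist(e$rows), range = as.integer(unlist(e$range)),
         offset = as.integer(e$offset))
  })
}

#' Apply an edit script
#'
#' @param aln An alignment tibble.
#' @param edits A list of edits (see [read_edit_script()]).
#' @return The edited alignment tibble.
#' @export
apply_edit_script <- function(aln, edits) {
  for (e in edits) {
    aln <- apply_shift_edit(aln, e$rows, e$range, e$offset)
  }
  aln
}

#' Recompute the local-covariation profile after editing
#'
#' Reruns the full pipeline (gap filter, MI, MIp, Zp, windowed
#' profile) on the current state of the alignment.
#'
#' @inheritParams local_covariation
#' @return A `loco_profile` object.
#' @export
recompute_after_edit <- function(aln, gap_threshold = 0, window = 6L,
                                 base = 2, sd_convention = "sample",
                                 track = "max") {
  local_covariation(aln, gap_threshold = gap_threshold, window = window,
                    base = base, sd_convention = sd_convention, track = track)
}
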