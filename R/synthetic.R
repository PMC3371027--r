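# Planted-shift synthetic alignments with ground truth.
#
# The generator builds a short block of randomly assorting columns in
# which each column draws from a small private residue alphabet that
# is disjoint from its neighbours' alphabets (non-adjacent columns may
# share letters).  A chosen fraction of rows is then shifted one
# position to the right across an interior column range: each shifted
# column inherits its left neighbour's residue and the vacated
# left-most column is refilled from a reserved "source" alphabet
# disjoint from every column alphabet.  The block is prepended to a
# synthetic host alignment built from a per-column conservation model.
# Ground-truth labels (which rows were shifted) and the pre-shift draw
# are kept for benchmarking detectors and curation tools.

derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483629)
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Specify a planted-shift simulation
#'
#' Defaults mirror the reference demonstration: a 7-column block of
#' 3-letter columns on 200 sequences, shifts planted across columns
#' 2-6, prepended to a 200-column host.
#'
#' @param n_seqs Number of sequences (default 200).
#' @param block_cols Number of block columns (default 7).
#' @param alphabet_size Residues per column alphabet (default 3).
#' @param shifted_cols Inclusive 1-based range of block columns to
#'   shift, strictly inside the block so an unshifted column flanks it
#'   on both sides (default `c(2, 6)`).
#' @param shift_fraction Fraction of rows to shift (e.g. 0.03, 0.05).
#' @param host_cols Columns in the synthetic host alignment (default
#'   200; 0 for no host).
#' @param host_substitution_rate Per-site probability that a host
#'   residue differs from its column's dominant residue (default 0.2).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return A `loco_shift_spec` list, validated.
#' @export
shift_spec <- function(n_seqs = 200L, block_cols = 7L, alphabet_size = 3L,
                       shifted_cols = c(2L, 6L), shift_fraction = 0.05,
                       host_cols = 200L, host_substitution_rate = 0.2,
                       seed = NULL) {
  stopifnot(n_seqs >= 2, block_cols >= 3, alphabet_size >= 2,
            length(shifted_cols) == 2, shift_fraction >= 0, shift_fraction <= 1,
            host_cols >= 0, host_substitution_rate >= 0, host_substitution_rate < 1)
  shifted_cols <- as.integer(shifted_cols)
  if (shifted_cols[1] <= 1L || shifted_cols[2] >= block_cols ||
      shifted_cols[1] > shifted_cols[2]) {
    abort("shifted_cols must lie strictly inside the block (flanked on both sides)",
          class = "locovar_spec_error")
  }
  alpha <- block_alphabets(block_cols, alphabet_size)
  structure(
    list(n_seqs = as.integer(n_seqs), block_cols = as.integer(block_cols),
         alphabet_size = as.integer(alphabet_size), shifted_cols = shifted_cols,
         shift_fraction = shift_fraction, host_cols = as.integer(host_cols),
         host_substitution_rate = host_substitution_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         alphabets = alpha$columns, source_alphabet = alpha$source),
    class = "loco_shift_spec"
  )
}

# Allocate per-column alphabets.  Only ADJACENT columns must be
# mutually exclusive, so disjoint alphabets are allocated from the
# 20-letter pool (minus the reserved source alphabet) and reused
# cyclically at distance >= 2 when the pool runs out.
block_alphabets <- function(block_cols, alphabet_size) {
  source_alpha <- tail(AA20, alphabet_size)
  pool <- head(AA20, length(AA20) - alphabet_size)
  n_distinct <- length(pool) %/% alphabet_size
  if (n_distinct < 2) {
    abort(paste0("alphabet_size ", alphabet_size,
                 " exceeds the 20-letter capacity (need 2 disjoint column ",
                 "alphabets plus a reserved source alphabet)"),
          class = "locovar_spec_error")
  }
  cols <- lapply(seq_len(block_cols), function(k) {
    slot <- (k - 1L) %% n_distinct
    pool[(slot * alphabet_size + 1L):((slot + 1L) * alphabet_size)]
  })
  list(columns = cols, source = source_alpha)
}

#' Generate the randomly assorting block
#'
#' Each block column is filled i.i.d. uniformly from that column's
#' private alphabet.  Deterministic given `spec$seed`.
#'
#' @param spec A `loco_shift_spec`.
#' @return An alignment tibble of `spec$n_seqs` rows and
#'   `spec$block_cols` columns.
#' @export
generate_block <- function(spec) {
  stopifnot(inherits(spec, "loco_shift_spec"))
  m <- with_seed_maybe(derive_seed(spec$seed, 1L), {
    vapply(spec$alphabets,
           function(a) sample(a, spec$n_seqs, replace = TRUE),
           character(spec$n_seqs))
  })
  rownames(m) <- sprintf("seq%04d", seq_len(spec$n_seqs))
  matrix_to_alignment(m)
}

#' Plant a one-position right shift in a fraction of rows
#'
#' For each selected row, every column in the shifted range (except the
#' first) inherits the residue of the column to its left; the vacated
#' first shifted column is redrawn from the reserved source alphabet.
#' Columns outside the range are untouched.  Row selection is uniform
#' without replacement and deterministic given `spec$seed`.
#'
#' @param block Alignment tibble from [generate_block()].
#' @param spec The `loco_shift_spec` used to generate it.
#' @return A `loco_synth` object: `alignment` (shifted block),
#'   `pre_shift` (the untouched draw), `shifted_rows` (character ids),
#'   `labels` (tibble `id`, `shifted`), `spec`.
#' @export
plant_shift <- function(block, spec) {
  stopifnot(inherits(spec, "loco_shift_spec"))
  block <- as_alignment(block)
  n <- nrow(block)
  n_shift <- round(spec$shift_fraction * n)
  if (spec$shift_fraction > 0 && n_shift < 1) {
    warn("shift_fraction rounds to zero rows; no shift planted")
  }
  m <- aln_matrix(block)
  pre <- matrix_to_alignment(m)
  lo <- spec$shifted_cols[1]; hi <- spec$shifted_cols[2]
  shifted_ids <- character(0)
  if (n_shift >= 1) {
    sel <- with_seed_maybe(derive_seed(spec$seed, 2L), {
      rows <- sort(sample.int(n, n_shift))
      fills <- sample(spec$source_alphabet, n_shift, replace = TRUE)
      list(rows = rows, fills = fills)
    })
    for (j in seq_along(sel$rows)) {
      r <- sel$rows[[j]]
      m[r, (lo + 1L):hi] <- m[r, lo:(hi - 1L)]
      m[r, lo] <- sel$fills[[j]]
    }
    shifted_ids <- rownames(m)[sel$rows]
  }
  structure(
    list(
      alignment = matrix_to_alignment(m),
      pre_shift = pre,
      shifted_rows = shifted_ids,
      labels = tibble(id = block$id, shifted = as.integer(block$id %in% shifted_ids)),
      spec = spec
    ),
    class = "loco_synth"
  )
}

#' Generate a synthetic host alignment
#'
#' Per-column conservation model emulating a curated protein family:
#' each column has a dominant residue and a small column-specific set
#' of tolerated alternatives (biochemically constrained sites admit
#' only a few residues).  Every cell carries the dominant residue with
#' probability `1 - substitution_rate`, otherwise a uniform draw from
#' the column's alternatives.  Columns are independent and gap-free,
#' so every host column passes the default gap filter.
#'
#' @param n_seqs,n_cols Dimensions.
#' @param substitution_rate Per-site substitution probability
#'   (default 0.2, a moderately conserved family).
#' @param n_alternatives Tolerated non-dominant residues per column
#'   (default 3, i.e. four residues observable per column).
#' @param seed RNG seed (`NULL` = current state).
#' @param ids Row ids (default `seq0001`...).
#' @return An alignment tibble.
#' @export
generate_host <- function(n_seqs, n_cols, substitution_rate = 0.2,
                          n_alternatives = 3L, seed = NULL, ids = NULL) {
  stopifnot(n_seqs >= 2, n_cols >= 1, n_alternatives >= 1, n_alternatives <= 19)
  m <- with_seed_maybe(seed, {
    mm <- matrix("", n_seqs, n_cols)
    for (j in seq_len(n_cols)) {
      resset <- sample(AA20, 1L + n_alternatives)
      mut <- stats::runif(n_seqs) < substitution_rate
      col <- rep(resset[1L], n_seqs)
      if (any(mut)) col[mut] <- sample(resset[-1L], sum(mut), replace = TRUE)
      mm[, j] <- col
    }
    mm
  })
  rownames(m) <- ids %||% sprintf("seq%04d", seq_len(n_seqs))
  matrix_to_alignment(m)
}

#' Concatenate a block in front of a host alignment
#'
#' @param block Alignment tibble (or `loco_synth`) whose columns come
#'   first.
#' @param host Alignment tibble with the same number of rows (may have
#'   zero columns via `NULL` for "no host").
#' @return An alignment tibble; row order and block ids are preserved.
#' @export
compose_with_host <- function(block, host = NULL) {
  baln <- if (inherits(block, "loco_synth")) block$alignment else as_alignment(block)
  if (is.null(host)) return(baln)
  host <- as_alignment(host)
  if (nrow(host) != nrow(baln)) {
    abort("block and host have different numbers of sequences",
          class = "locovar_composition_error")
  }
  tibble(id = baln$id, seq = paste0(baln$seq, host$seq))
}

#' Simulate a full planted-shift benchmark alignment
#'
#' One-call wrapper: generates the block, plants the shift, generates
#' the host and composes them.  This is the study condition used
#' throughout the package's tests: a 7-column block on 200 sequences
#' in front of a 200-column moderately conserved host.
#'
#' @inheritParams shift_spec
#' @return A `loco_synth` object whose `alignment` and `pre_shift` are
#'   the full composed alignments (block columns are original columns
#'   `1:block_cols`), with `labels`, `shifted_rows` and the `spec`
#'   echoed.
#' @examples
#' syn <- simulate_shifted_alignment(shift_fraction = 0.05, seed = 42)
#' glance(local_covariation(syn$alignment))
#' @export
simulate_shifted_alignment <- function(n_seqs = 200L, block_cols = 7L,
                                       alphabet_size = 3L,
                                       shifted_cols = c(2L, 6L),
                                       shift_fraction = 0.05,
                                       host_cols = 200L,
                                       host_substitution_rate = 0.2,
                                       seed = NULL) {
  spec <- shift_spec(n_seqs = n_seqs, block_cols = block_cols,
                     alphabet_size = alphabet_size, shifted_cols = shifted_cols,
                     shift_fraction = shift_fraction, host_cols = host_cols,
                     host_substitution_rate = host_substitution_rate, seed = seed)
  block <- generate_block(spec)
  syn <- plant_shift(block, spec)
  if (spec$host_cols > 0) {
    host <- generate_host(spec$n_seqs, spec$host_cols,
                          substitution_rate = spec$host_substitution_rate,
                          seed = derive_seed(spec$seed, 3L), ids = block$id)
    syn$alignment <- compose_with_host(syn$alignment, host)
    syn$pre_shift <- compose_with_host(syn$pre_shift, host)
  }
  syn
}

#' Restore planted-shift rows from ground truth
#'
#' Replaces the block-range residues of (by default all) shifted rows
#' with their pre-shift draw.  The planted shift overwrites the last
#' shifted column's residue, so the exact inverse requires the
#' recorded pre-shift content; this is the "ground-truth correcting
#' edit" used to benchmark curation.
#'
#' @param syn A `loco_synth` object.
#' @param rows Ids of rows to correct (default: all shifted rows).
#' @return The corrected alignment tibble.
#' @export
correct_planted_shift <- function(syn, rows = NULL) {
  stopifnot(inherits(syn, "loco_synth"))
  rows <- rows %||% syn$shifted_rows
  m <- aln_matrix(syn$alignment)
  pre <- aln_matrix(syn$pre_shift)
  rng <- seq(syn$spec$shifted_cols[1], syn$spec$shifted_cols[2])
  m[rows, rng] <- pre[rows, rng]
  matrix_to_alignment(m)
}

#' Write a synthetic benchmark to disk
#'
#' Emits the aligned FASTA, a ground-truth labels TSV (`id`,
#' `shifted`) and a JSON echo of the generating parameters.
#'
#' @param syn A `loco_synth` object.
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>_labels.tsv`, `<prefix>_spec.json`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(syn, prefix) {
  stopifnot(inherits(syn, "loco_synth"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             labels = paste0(prefix, "_labels.tsv"),
             spec = paste0(prefix, "_spec.json"))
  write_alignment(syn$alignment, paths[["fasta"]])
  utils::write.table(syn$labels, paths[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spec <- syn$spec
  echo <- spec[c("n_seqs", "block_cols", "alphabet_size", "shift_fraction",
                 "host_cols", "host_substitution_rate")]
  echo$shifted_cols <- spec$shifted_cols
  echo$seed <- spec$seed
  echo$alphabets <- vapply(spec$alphabets, paste, collapse = "", FUN.VALUE = "")
  echo$source_alphabet <- paste(spec$source_alphabet, collapse = "")
  jsonlite::write_json(echo, paths[["spec"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @export
print.loco_synth <- function(x, ...) {
  cat("<loco_synth> ", nrow(x$alignment), " sequences x ",
      alignment_width(x$alignment), " columns; ",
      length(x$shifted_rows), " shifted row(s) over block columns ",
      x$spec$shifted_cols[1], "-", x$spec$shifted_cols[2], "\n", sep = "")
  invisible(x)
}
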