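# Pairwise column covariation: mutual information, the average-product
# correction (MIp) and its z-normalisation (Zp).
#
# MIp(a,b) = MI(a,b) - MI(a,.) * MI(b,.) / mean(MI)
#   where MI(a,.) is the mean MI of column a with all other columns and
#   mean(MI) is the overall mean over unordered pairs.
# Zp(a,b)  = (MIp(a,b) - mean(MIp)) / sd(MIp)
#   with mean/sd taken over all unordered column pairs.
#
# Counting is pairwise-complete: a sequence row enters the count for a
# column pair only if it carries a standard residue in both columns
# (gaps and ambiguity codes are excluded).  No pseudocounts, no
# sequence weighting.

#' Joint residue counts for one column pair
#'
#' Tallies co-occurring residues in two analysis columns, excluding any
#' sequence row holding a gap or unknown/ambiguous residue in either
#' column.  Only observed residue pairs are stored.
#'
#' @param aln An alignment tibble.
#' @param cols Analysis-column map from [select_analysis_columns()].
#' @param a,b Distinct analysis-column indices.
#' @return A list with `pair_counts`, a tibble (`sym_a`, `sym_b`, `n`)
#'   containing only pairs with `n > 0`, and `n_effective`, the number
#'   of rows counted.
#' @export
joint_counts <- function(aln, cols, a, b) {
  aln <- as_alignment(aln)
  stopifnot(a != b, a >= 1, b >= 1, a <= nrow(cols), b <= nrow(cols))
  m <- aln_matrix(aln)
  ca <- unname(m[, cols$original_col[[a]]])
  cb <- unname(m[, cols$original_col[[b]]])
  ok <- ca %in% AA20 & cb %in% AA20
  if (sum(ok) < 2) {
    abort("fewer than 2 rows with standard residues in both columns",
          class = "locovar_insufficient_data_error")
  }
  counts <- dplyr::count(tibble(sym_a = ca[ok], sym_b = cb[ok]), .data$sym_a, .data$sym_b)
  list(pair_counts = counts, n_effective = sum(ok))
}

#' Mutual information of a joint count table
#'
#' `MI = sum p(x,y) log(p(x,y) / (p(x) p(y)))` with probabilities taken
#' as plain relative counts.  Reported in bits by default.
#'
#' @param jc Output of [joint_counts()].
#' @param base Logarithm base; 2 gives bits, `exp(1)` nats.  The
#'   base cancels out of Zp but fixes the unit of reported MI.
#' @return Non-negative MI score.
#' @export
mutual_information <- function(jc, base = 2) {
  n <- jc$n_effective
  stopifnot(n >= 2)
  tab <- jc$pair_counts
  pa <- tapply(tab$n, tab$sym_a, sum) / n
  pb <- tapply(tab$n, tab$sym_b, sum) / n
  p <- tab$n / n
  mi <- sum(p * log(p / (pa[tab$sym_a] * pb[tab$sym_b]), base = base))
  max(mi, 0)  # clip the -0 that floating point produces on independence
}

# x * log2(x) with the 0 log 0 = 0 convention; x is a count matrix
xlog2x <- function(x) x * log2(pmax(x, 1))

#' Mutual-information matrix over all analysis-column pairs
#'
#' Computes MI for every unordered pair of analysis columns, plus the
#' per-column mean MI and overall mean MI needed by the
#' average-product correction.  The computation is vectorised through
#' per-symbol indicator matrices, so cost scales with the residues
#' actually observed rather than the full 20 x 20 table.
#'
#' @inheritParams joint_counts
#' @param base Logarithm base for MI (2 = bits).
#' @return An object of class `loco_covariation` holding the symmetric
#'   `mi` matrix (diagonal `NA`), `row_mean_mi`, `overall_mean_mi`, and
#'   the column map.  Pass to [apply_apc()] then [normalize_zp()], or
#'   use the [covariation()] wrapper.
#' @export
mi_matrix <- function(aln, cols, base = 2) {
  aln <- as_alignment(aln)
  if (nrow(cols) < 2) {
    abort("need at least 2 analysis columns", class = "locovar_empty_analysis_error")
  }
  m <- aln_matrix(aln)[, cols$original_col, drop = FALSE]
  code <- apply(m, 2L, encode_column)       # n x m integer, 0 = gap/unknown
  n <- nrow(code); p <- ncol(code)
  ng <- (code != 0) * 1                     # non-gap indicator
  neff <- crossprod(ng)                     # pairwise-complete row counts
  off <- upper.tri(neff)
  if (any(neff[off] < 2)) {
    abort("some column pairs have fewer than 2 pairwise-complete rows; raise coverage or lower gap_threshold",
          class = "locovar_insufficient_data_error")
  }
  syms <- sort(unique(as.vector(code)))
  syms <- syms[syms != 0]
  ind <- lapply(syms, function(s) (code == s) * 1)
  # joint term: sum over symbol pairs of N log2 N
  s_joint <- matrix(0, p, p)
  allind <- do.call(cbind, ind)             # n x (p * nsym)
  for (ia in ind) {
    cross <- crossprod(ia, allind)          # p x (p * nsym), blocked by symbol
    cross <- xlog2x(cross)
    for (k in seq_along(ind)) {
      s_joint <- s_joint + cross[, ((k - 1L) * p + 1L):(k * p), drop = FALSE]
    }
  }
  # marginal term: counts of each symbol in column a among rows where
  # column b is non-gap (pairwise-complete marginals)
  s_a <- matrix(0, p, p)
  for (ia in ind) s_a <- s_a + xlog2x(crossprod(ia, ng))
  mi <- log2(neff) - (s_a + t(s_a) - s_joint) / neff
  mi[mi < 0] <- 0                           # numerical noise at independence
  if (base != 2) mi <- mi / log2(base)
  diag(mi) <- NA_real_
  dimnames(mi) <- list(cols$original_col, cols$original_col)
  structure(
    list(
      mi = mi,
      row_mean_mi = unname(rowMeans(mi, na.rm = TRUE)),
      overall_mean_mi = mean(mi[upper.tri(mi)]),
      mip = NULL, zp = NULL,
      mean_mip = NULL, sd_mip = NULL,
      columns = cols,
      n_seqs = n,
      log_base = base
    ),
    class = "loco_covariation"
  )
}

#' Apply the average-product correction
#'
#' Subtracts the background term `MI(a,.) MI(b,.) / mean(MI)` from each
#' pairwise MI, removing the shared-background (phylogenetic and
#' entropic) component.  Corrected values may be negative.
#'
#' @param x A `loco_covariation` object from [mi_matrix()].
#' @return The object with the `mip` matrix filled.
#' @export
apply_apc <- function(x) {
  stopifnot(inherits(x, "loco_covariation"), !is.null(x$mi))
  if (!(x$overall_mean_mi > 0)) {
    abort("overall mean MI is zero (all columns conserved); APC undefined",
          class = "locovar_degenerate_alignment_error")
  }
  x$mip <- x$mi - outer(x$row_mean_mi, x$row_mean_mi) / x$overall_mean_mi
  diag(x$mip) <- NA_real_
  x
}

#' Z-normalise MIp to Zp
#'
#' Standardises MIp over all unordered column pairs to zero mean and
#' unit standard deviation (sample convention, `n - 1`).
#'
#' @param x A `loco_covariation` object with `mip` filled.
#' @param sd_convention `"sample"` (n - 1, default) or `"population"`.
#' @return The object with `zp`, `mean_mip` and `sd_mip` filled.
#' @export
normalize_zp <- function(x, sd_convention = c("sample", "population")) {
  stopifnot(inherits(x, "loco_covariation"), !is.null(x$mip))
  sd_convention <- match.arg(sd_convention)
  vals <- x$mip[upper.tri(x$mip)]
  if (length(vals) < 3) {
    abort("need at least 3 column pairs to normalise",
          class = "locovar_degenerate_distribution_error")
  }
  mu <- mean(vals)
  s <- sd(vals)
  if (sd_convention == "population") {
    s <- s * sqrt((length(vals) - 1) / length(vals))
  }
  if (!(s > 0)) {
    abort("MIp has zero spread; Zp undefined",
          class = "locovar_degenerate_distribution_error")
  }
  x$mean_mip <- mu
  x$sd_mip <- s
  x$zp <- (x$mip - mu) / s
  x
}

#' Full covariation pipeline: MI, MIp and Zp for an alignment
#'
#' Convenience wrapper running [select_analysis_columns()],
#' [mi_matrix()], [apply_apc()] and [normalize_zp()].
#'
#' @param aln An alignment tibble (or data frame with `id`, `seq`).
#' @param gap_threshold Maximum gap fraction for analysis columns.
#' @param base Logarithm base for MI.
#' @param sd_convention Standard-deviation convention for Zp.
#' @return A `loco_covariation` object; see [tidy.loco_covariation()]
#'   for the per-pair table.
#' @examples
#' aln <- tibble::tibble(
#'   id = paste0("s", 1:4),
#'   seq = c("ACDEF", "ACDEG", "AVDEF", "AVDEG"))
#' cv <- covariation(aln)
#' tidy(cv)
#' @export
covariation <- function(aln, gap_threshold = 0, base = 2,
                        sd_convention = "sample") {
  cols <- select_analysis_columns(aln, gap_threshold)
  x <- mi_matrix(aln, cols, base = base)
  x <- apply_apc(x)
  normalize_zp(x, sd_convention = sd_convention)
}

#' @export
print.loco_covariation <- function(x, ...) {
  p <- nrow(x$columns)
  cat("<loco_covariation> ", x$n_seqs, " sequences, ", p,
      " analysis columns (", p * (p - 1) / 2, " pairs)\n", sep = "")
  if (!is.null(x$sd_mip)) {
    cat("  mean MIp = ", signif(x$mean_mip, 4),
        ", sd MIp = ", signif(x$sd_mip, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a covariation object into a per-pair table
#'
#' @param x A `loco_covariation` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered column pair: `col_a`,
#'   `col_b` (1-based original alignment coordinates, `col_a < col_b`),
#'   `mi`, and when computed `mip` and `zp`.
#' @method tidy loco_covariation
#' @export
tidy.loco_covariation <- function(x, ...) {
  orig <- x$columns$original_col
  idx <- which(upper.tri(x$mi), arr.ind = TRUE)
  out <- tibble(
    col_a = orig[idx[, 1]],
    col_b = orig[idx[, 2]],
    mi = x$mi[idx]
  )
  if (!is.null(x$mip)) out$mip <- x$mip[idx]
  if (!is.null(x$zp)) out$zp <- x$zp[idx]
  dplyr::arrange(out, .data$col_a, .data$col_b)
}

#' One-row summary of a covariation object
#'
#' @param x A `loco_covariation` object.
#' @param ... Unused.
#' @return A one-row tibble: sequence and column counts, overall mean
#'   MI, and the MIp normalisation statistics.
#' @method glance loco_covariation
#' @export
glance.loco_covariation <- function(x, ...) {
  tibble(
    n_seqs = x$n_seqs,
    n_analysis_cols = nrow(x$columns),
    n_pairs = nrow(x$columns) * (nrow(x$columns) - 1) / 2,
    overall_mean_mi = x$overall_mean_mi,
    mean_mip = x$mean_mip %||% NA_real_,
    sd_mip = x$sd_mip %||% NA_real_,
    log_base = x$log_base
  )
}
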