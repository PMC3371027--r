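# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; nothing is read from disk except
# files the tests themselves write.

`%||%` <- function(x, y) if (is.null(x)) y else x

make_aln <- function(...) {
  seqs <- c(...)
  ids <- names(seqs) %||% paste0("s", seq_along(seqs))
  tibble::tibble(id = ids, seq = unname(seqs))
}

# random gapless alignment over the 20-letter alphabet
random_aln <- function(n_seqs, n_cols, seed, gap_prob = 0) {
  withr::with_seed(seed, {
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    pool <- c(alpha, "-")
    probs <- c(rep((1 - gap_prob) / 20, 20), gap_prob)
    m <- matrix(sample(pool, n_seqs * n_cols, replace = TRUE, prob = probs),
                n_seqs, n_cols)
    tibble::tibble(id = paste0("s", seq_len(n_seqs)),
                   seq = apply(m, 1, paste, collapse = ""))
  })
}

# Dense brute-force oracle: tally a full 21 x 21 table with explicit
# loops and sum MI cell by cell.  Deliberately written with none of
# the package's machinery.
oracle_dense_mi <- function(chars_a, chars_b, base = 2) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tab <- matrix(0L, 20, 20, dimnames = list(alpha, alpha))
  n_eff <- 0L
  for (i in seq_along(chars_a)) {
    x <- chars_a[[i]]; y <- chars_b[[i]]
    if (x %in% alpha && y %in% alpha) {
      tab[x, y] <- tab[x, y] + 1L
      n_eff <- n_eff + 1L
    }
  }
  mi <- 0
  row_sums <- rowSums(tab); col_sums <- colSums(tab)
  for (x in alpha) {
    for (y in alpha) {
      if (tab[x, y] > 0) {
        pxy <- tab[x, y] / n_eff
        mi <- mi + pxy * log(pxy / ((row_sums[[x]] / n_eff) * (col_sums[[y]] / n_eff)),
                             base = base)
      }
    }
  }
  list(mi = max(mi, 0), n_effective = n_eff, table = tab)
}

# hand-built covariation object for unit-testing downstream steps
fake_covariation <- function(mat, what = c("zp", "mip")) {
  what <- match.arg(what)
  p <- nrow(mat)
  cols <- tibble::tibble(analysis_col = seq_len(p), original_col = seq_len(p))
  attr(cols, "width") <- p
  obj <- list(mi = mat, row_mean_mi = rowMeans(mat, na.rm = TRUE),
              overall_mean_mi = mean(mat[upper.tri(mat)], na.rm = TRUE),
              mip = NULL, zp = NULL, mean_mip = NULL, sd_mip = NULL,
              columns = cols, n_seqs = NA_integer_, log_base = 2)
  obj[[what]] <- mat
  if (what == "zp") {
    obj$mip <- mat
    obj$mean_mip <- 0
    obj$sd_mip <- 1
  }
  structure(obj, class = "loco_covariation")
}

fake_profile <- function(scores) {
  p <- length(scores) + 5L
  cols <- tibble::tibble(analysis_col = seq_len(p), original_col = seq_len(p))
  attr(cols, "width") <- p
  structure(list(
    windows = tibble::tibble(window = seq_along(scores),
                             start_col = seq_along(scores),
                             end_col = seq_along(scores) + 5L,
                             score = scores),
    column_track = rep(NA_real_, p), window_size = 6L, track = "max",
    n_seqs = NA_integer_, columns = cols
  ), class = "loco_profile")
}

# minimal synthetic PDB writer (fixed-width ATOM records)
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          record = "ATOM", altloc = " ", element = NULL) {
  element <- element %||% substr(elety, 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, elety, altloc, resid, chain, resno, x, y, z, 1, 0, element)
}

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
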