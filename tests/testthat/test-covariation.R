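two_col_cols <- function(aln) select_analysis_columns(aln)

test_that("joint counts are sparse, pairwise-complete and drop unknowns", {
  aln <- make_aln(s1 = "AC", s2 = "AC", s3 = "RD", s4 = "RD")
  cols <- select_analysis_columns(aln)
  jc <- joint_counts(aln, cols, 1, 2)
  expect_equal(jc$n_effective, 4L)
  expect_equal(nrow(jc$pair_counts), 2L)
  expect_equal(sum(jc$pair_counts$n), jc$n_effective)
  expect_true(all(jc$pair_counts$n > 0))
  got <- jc$pair_counts[order(jc$pair_counts$sym_a), ]
  expect_equal(got$sym_a, c("A", "R"))
  expect_equal(got$sym_b, c("C", "D"))
  expect_equal(got$n, c(2L, 2L))

  # X is an unknown: its row leaves the count entirely
  aln <- make_aln(s1 = "AC", s2 = "XC", s3 = "RD", s4 = "RD")
  jc <- joint_counts(aln, select_analysis_columns(aln), 1, 2)
  expect_equal(jc$n_effective, 3L)
  expect_equal(sort(jc$pair_counts$n), c(1L, 2L))

  aln <- make_aln(s1 = "AC", s2 = "XC", s3 = "XD")
  expect_error(joint_counts(aln, select_analysis_columns(aln), 1, 2),
               class = "locovar_insufficient_data_error")
})

test_that("mutual information matches hand-computed values in bits", {
  mi_of <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    aln <- tibble::tibble(id = paste0("r", seq_along(ca)), seq = paste0(ca, cb))
    mutual_information(joint_counts(aln, select_analysis_columns(aln), 1, 2))
  }
  # one-to-one mapping of two equiprobable symbols = 1 bit
  expect_equal(mi_of("AARR", "CCDD"), 1.0, tolerance = 1e-12)
  # conserved column carries no information
  expect_equal(mi_of("AAAA", "CDCD"), 0.0, tolerance = 1e-12)
  # brute-force sum over the four occupied joint cells
  expect_equal(mi_of("AAARRR", "CCDDDC"), 0.0817042, tolerance = 1e-6)
})

test_that("sparse counting and MI equal the dense brute-force oracle", {
  aln <- random_aln(80, 12, seed = 21, gap_prob = 0.05)
  cols <- select_analysis_columns(aln, gap_threshold = 0.3)
  for (pair in list(c(1, 2), c(3, 7), c(2, nrow(cols)))) {
    jc <- joint_counts(aln, cols, pair[1], pair[2])
    m <- do.call(rbind, strsplit(aln$seq, ""))
    oracle <- oracle_dense_mi(m[, cols$original_col[pair[1]]],
                              m[, cols$original_col[pair[2]]])
    expect_equal(jc$n_effective, oracle$n_effective)
    expect_equal(mutual_information(jc), oracle$mi, tolerance = 1e-12)
    # the sparse map holds exactly the non-zero cells of the dense tally
    expect_equal(nrow(jc$pair_counts), sum(oracle$table > 0))
  }
})

test_that("the MI matrix agrees with independent per-pair recomputation", {
  aln <- random_aln(40, 10, seed = 5)
  cols <- select_analysis_columns(aln)
  x <- mi_matrix(aln, cols)
  expect_true(isSymmetric(unname(x$mi)))
  expect_true(all(x$mi[upper.tri(x$mi)] >= 0))
  expect_true(all(is.na(diag(x$mi))))
  for (a in 1:9) {
    for (b in (a + 1):10) {
      expect_equal(x$mi[a, b],
                   mutual_information(joint_counts(aln, cols, a, b)),
                   tolerance = 1e-12)
    }
  }
  # row means and overall mean follow from the matrix
  expect_equal(unname(x$row_mean_mi),
               unname(rowMeans(x$mi, na.rm = TRUE)))
  expect_equal(x$overall_mean_mi, mean(x$mi[upper.tri(x$mi)]))

  aln2 <- make_aln(a = "AC", b = "AD", c = "RC")
  expect_error(mi_matrix(aln2, select_analysis_columns(aln2)[1, ]),
               class = "locovar_empty_analysis_error")
})

test_that("the average-product correction follows the defining formula", {
  # homogeneous MI matrix: row means and overall mean coincide, so the
  # correction cancels every pair exactly
  mat <- matrix(0.5, 4, 4); diag(mat) <- NA
  x <- apply_apc(fake_covariation(mat, "mip"))
  expect_equal(max(abs(x$mip[upper.tri(x$mip)])), 0, tolerance = 1e-12)

  # a fully conserved column (zero MI row) keeps zero after correction
  aln <- make_aln(s1 = "AACC", s2 = "ARCD", s3 = "RACD", s4 = "RRCC",
                  s5 = "AACD", s6 = "ARCC")
  cv <- mi_matrix(aln, select_analysis_columns(aln))
  cv <- apply_apc(cv)
  expect_equal(unname(cv$mip[3, -3]), rep(0, 3), tolerance = 1e-12)

  # random alignment: every entry equals the scalar formula
  aln <- random_aln(30, 6, seed = 9)
  x <- apply_apc(mi_matrix(aln, select_analysis_columns(aln)))
  for (a in 1:5) {
    for (b in (a + 1):6) {
      expect_equal(x$mip[a, b],
                   x$mi[a, b] - x$row_mean_mi[a] * x$row_mean_mi[b] / x$overall_mean_mi,
                   tolerance = 1e-12)
    }
  }

  # all-conserved alignment has zero mean MI: APC undefined
  aln <- make_aln(s1 = "ACD", s2 = "ACD", s3 = "ACD")
  expect_error(apply_apc(mi_matrix(aln, select_analysis_columns(aln))),
               class = "locovar_degenerate_alignment_error")
})

test_that("Zp standardisation is exact and uses the sample sd", {
  mip <- matrix(NA_real_, 3, 3)
  mip[1, 2] <- mip[2, 1] <- 0
  mip[1, 3] <- mip[3, 1] <- 1
  mip[2, 3] <- mip[3, 2] <- 2
  obj <- fake_covariation(mip, "mip")
  z <- normalize_zp(obj)
  expect_equal(z$mean_mip, 1)
  expect_equal(z$sd_mip, 1)  # sample sd of {0,1,2}
  expect_equal(sort(z$zp[upper.tri(z$zp)]), c(-1, 0, 1))

  # normalisation identity on a real alignment
  aln <- random_aln(50, 12, seed = 33)
  cv <- covariation(aln)
  vals <- cv$zp[upper.tri(cv$zp)]
  expect_equal(mean(vals), 0, tolerance = 1e-9)
  expect_equal(sd(vals), 1, tolerance = 1e-9)

  # degenerate spread
  mip0 <- matrix(NA_real_, 3, 3); mip0[upper.tri(mip0)] <- 1
  mip0[lower.tri(mip0)] <- 1
  expect_error(normalize_zp(fake_covariation(mip0, "mip")),
               class = "locovar_degenerate_distribution_error")
})

test_that("Zp is invariant to the MI log base", {
  aln <- random_aln(60, 10, seed = 17)
  z_bits <- covariation(aln, base = 2)$zp
  z_nats <- covariation(aln, base = exp(1))$zp
  expect_equal(z_bits, z_nats, tolerance = 1e-9)
})

test_that("tidy and glance expose pairs in original coordinates", {
  aln <- make_aln(a = "A-CDE", b = "AACDF", c = "R-CEG", d = "RACFG")
  cv <- covariation(aln)  # columns 1, 3, 4, 5 survive the gap filter
  td <- tidy(cv)
  expect_setequal(names(td), c("col_a", "col_b", "mi", "mip", "zp"))
  expect_equal(nrow(td), choose(4, 2))
  expect_true(all(td$col_a < td$col_b))
  expect_setequal(unique(c(td$col_a, td$col_b)), c(1L, 3L, 4L, 5L))
  g <- glance(cv)
  expect_equal(g$n_seqs, 4L)
  expect_equal(g$n_analysis_cols, 4L)
  expect_gt(g$sd_mip, 0)
})
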