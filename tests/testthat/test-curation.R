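test_that("percent-identity distances use pairwise deletion of gaps", {
  aln <- make_aln(a = "ACDE", b = "ACDE")
  expect_equal(percent_identity_distances(aln)["a", "b"], 0)

  aln <- make_aln(a = "ACDE", b = "ACDF")
  expect_equal(percent_identity_distances(aln)["a", "b"], 0.25)

  # gap-vs-anything positions are excluded: 3 comparable, 3 matches
  aln <- make_aln(a = "AC-E", b = "ACDE")
  expect_equal(percent_identity_distances(aln)["a", "b"], 0)

  aln <- make_aln(a = "A--D", b = "-CC-")
  expect_warning(d <- percent_identity_distances(aln), "no comparable")
  expect_equal(d["a", "b"], 1)

  aln <- make_aln(a = "ACDE", b = "ACDF", c = "AAAA")
  d <- percent_identity_distances(aln, col_range = c(1, 2))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(d["a", "b"], 0)      # identical over columns 1-2
  expect_error(percent_identity_distances(aln, c(0, 2)),
               class = "locovar_input_error")
})

test_that("neighbour joining recovers additive and clade structure", {
  # three leaves: branch lengths follow the closest pair
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbour_joining(d)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.1)
  expect_equal(bl[["C"]], 0.3)

  # four-leaf additive matrix from a known tree: topology recovered
  # tree: (A:1,B:2):1 joined to (C:1,D:3)
  dd <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  dd["A", "B"] <- dd["B", "A"] <- 3
  dd["C", "D"] <- dd["D", "C"] <- 4
  dd["A", "C"] <- dd["C", "A"] <- 3
  dd["A", "D"] <- dd["D", "A"] <- 5
  dd["B", "C"] <- dd["C", "B"] <- 4
  dd["B", "D"] <- dd["D", "B"] <- 6
  tr4 <- neighbour_joining(dd)
  expect_true(has_bipartition(tr4, c("A", "B")))
  expect_true(has_bipartition(tr4, c("C", "D")))

  # ultrametric two-clade matrix: the bipartition separates the clades
  ids <- c("x1", "x2", "x3", "y1", "y2", "y3")
  du <- matrix(0.8, 6, 6, dimnames = list(ids, ids))
  du[1:3, 1:3] <- 0.1; du[4:6, 4:6] <- 0.1; diag(du) <- 0
  tru <- neighbour_joining(du)
  expect_true(has_bipartition(tru, c("x1", "x2", "x3")))
  expect_false(has_bipartition(tru, c("x1", "x2", "y1")))

  expect_error(neighbour_joining(d[1:2, 1:2]), class = "locovar_input_error")
})

test_that("sorting by tree permutes rows without touching residues", {
  aln <- make_aln(A = "AAAA", B = "CCCC", C = "DDDD", D = "EEEE")
  d <- percent_identity_distances(aln)
  tr <- neighbour_joining(d)
  sorted <- sort_by_tree(aln, tr)
  expect_setequal(sorted$id, aln$id)
  expect_equal(sorted$id, tree_leaf_order(tr))
  expect_identical(sort(sorted$seq), sort(aln$seq))
  expect_error(sort_by_tree(make_aln(E = "AAAA", F = "CCCC"), tr),
               class = "locovar_input_error")
})

test_that("planted-shift rows cluster into their own clade and sort together", {
  syn <- simulate_shifted_alignment(shift_fraction = 0.05, seed = 19)
  rng <- syn$spec$shifted_cols
  d <- percent_identity_distances(syn$alignment, col_range = rng)
  tr <- neighbour_joining(d)
  expect_true(has_bipartition(tr, syn$shifted_rows))
  sorted <- sort_by_tree(syn$alignment, tr)
  pos <- which(sorted$id %in% syn$shifted_rows)
  expect_equal(pos, seq(min(pos), max(pos)))  # contiguous block after sort
})

test_that("shift edits move segments into gaps and preserve content", {
  aln <- make_aln(a = "-ACD", b = "ACDE")
  out <- apply_shift_edit(aln, "a", c(1, 4), -1)
  expect_equal(out$seq[out$id == "a"], "ACD-")
  expect_equal(out$seq[out$id == "b"], "ACDE")

  # no terminal gap to absorb a right shift: blocked, row named
  aln <- make_aln(a = "AC-D", b = "ACDE")
  expect_error(apply_shift_edit(aln, "a", c(1, 4), 1),
               class = "locovar_blocked_edit_error", regexp = "'a'")

  # right shift into a terminal gap, then back: identity
  aln <- make_aln(a = "ACD-", b = "ACDE")
  right <- apply_shift_edit(aln, "a", c(1, 4), 1)
  expect_equal(right$seq[right$id == "a"], "-ACD")
  back <- apply_shift_edit(right, "a", c(1, 4), -1)
  expect_equal(back, as_alignment(aln))

  # ungapped residue content is invariant under any legal edit
  strip <- function(s) gsub("-", "", s)
  aln <- make_aln(a = "AC--EF--", b = "GHIKLMNP")
  edited <- apply_shift_edit(aln, "a", c(1, 8), 2)
  expect_equal(strip(edited$seq[1]), strip(aln$seq[1]))
  expect_equal(alignment_width(edited), alignment_width(aln))

  expect_error(apply_shift_edit(aln, "a", c(1, 8), 0), class = "locovar_input_error")
  expect_error(apply_shift_edit(aln, "zz", c(1, 8), 1), class = "locovar_input_error")
  expect_error(apply_shift_edit(aln, "a", c(1, 8), 8), class = "locovar_input_error")
})

test_that("edit scripts apply row/range/offset triples in order", {
  aln <- make_aln(a = "-ACD", b = "-CDE")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(rows = list("a"), range = c(1, 4), offset = -1),
         list(rows = list("b"), range = c(1, 4), offset = -1)),
    f, auto_unbox = TRUE)
  out <- apply_edit_script(aln, read_edit_script(f))
  expect_equal(out$seq, c("ACD-", "CDE-"))
})

test_that("ground-truth correction restores the pre-shift block", {
  syn <- simulate_shifted_alignment(shift_fraction = 0.05, seed = 23)
  corrected <- correct_planted_shift(syn)
  expect_identical(corrected, syn$pre_shift)

  # partial correction leaves the remaining rows shifted
  half <- syn$shifted_rows[1:5]
  partial <- correct_planted_shift(syn, rows = half)
  expect_false(identical(partial, syn$pre_shift))
  m_part <- do.call(rbind, strsplit(partial$seq, ""))
  m_pre <- do.call(rbind, strsplit(syn$pre_shift$seq, ""))
  rownames(m_part) <- partial$id; rownames(m_pre) <- syn$pre_shift$id
  expect_identical(m_part[half, ], m_pre[half, ])
})

test_that("correcting the shift lowers the block's local covariation", {
  syn <- simulate_shifted_alignment(shift_fraction = 0.05, host_cols = 120, seed = 29)
  block_windows <- 1:2  # windows fully or mostly inside the 7-column block
  before <- local_covariation(syn$alignment)
  after <- recompute_after_edit(correct_planted_shift(syn))
  expect_lt(max(after$windows$score[block_windows]),
            max(before$windows$score[block_windows]))

  # partial correction lands between uncorrected and fully corrected
  partial <- recompute_after_edit(correct_planted_shift(syn, syn$shifted_rows[1:5]))
  expect_lt(max(partial$windows$score[block_windows]),
            max(before$windows$score[block_windows]))
  expect_gt(max(partial$windows$score[block_windows]),
            max(after$windows$score[block_windows]))

  # editing zero rows is a no-op on the profile
  same <- recompute_after_edit(correct_planted_shift(syn, rows = character(0)))
  expect_equal(same$windows$score, before$windows$score, tolerance = 1e-12)
})
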