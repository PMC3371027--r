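# Alignment I/O and gap-column selection.
#
# An alignment is an ordinary tibble with two columns, `id` and `seq`,
# one row per sequence.  All residue strings have equal length, ids are
# unique, and '.' has been normalised to '-'.  Keeping the container a
# plain tibble means every downstream verb (filter rows, join labels,
# mutate ids) is just dplyr.

# standard 20-letter amino-acid alphabet, fixed order
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ambiguity / non-standard codes collapsed to one unknown symbol
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J", "*")
UNKNOWN <- "X"
GAP <- "-"

#' Validate (and lightly normalise) an alignment tibble
#'
#' Checks the invariants every function in the package relies on: at
#' least two sequences, non-empty unique ids, equal-length residue
#' strings.  Sequences are upper-cased and '.' gap characters replaced
#' with '-'.
#'
#' @param x A data frame with character columns `id` and `seq`.
#' @return A validated tibble with columns `id` and `seq`.
#' @export
as_alignment <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("an alignment needs `id` and `seq` columns", class = "locovar_input_error")
  }
  aln <- tibble(id = as.character(x$id), seq = toupper(as.character(x$seq)))
  aln$seq <- gsub(".", GAP, aln$seq, fixed = TRUE)
  if (nrow(aln) < 2) {
    abort("an alignment needs at least 2 sequences", class = "locovar_input_error")
  }
  if (anyNA(aln$id) || any(!nzchar(aln$id))) {
    abort("sequence ids must be non-empty", class = "locovar_input_error")
  }
  if (anyDuplicated(aln$id)) {
    dup <- unique(aln$id[duplicated(aln$id)])
    abort(paste0("duplicate sequence ids: ", paste(head(dup, 5), collapse = ", ")),
          class = "locovar_input_error")
  }
  widths <- nchar(aln$seq)
  if (length(unique(widths)) != 1L) {
    abort("sequences have unequal lengths; not a valid alignment",
          class = "locovar_format_error")
  }
  if (widths[1] < 1L) {
    abort("alignment has zero columns", class = "locovar_input_error")
  }
  aln
}

#' Number of columns in an alignment
#' @param aln An alignment tibble (see [as_alignment()]).
#' @return Integer width.
#' @export
alignment_width <- function(aln) nchar(aln$seq[[1]])

#' Read a protein multiple sequence alignment
#'
#' Reads aligned FASTA (the canonical interchange format here) or
#' CLUSTAL.  Residues are upper-cased and '.' is treated as '-'.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @return An alignment tibble with columns `id`, `seq`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-D", ">s2", "ACAD"), f)
#' read_alignment(f)
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path), class = "locovar_input_error")
  }
  if (format == "fasta") {
    recs <- parse_fasta(path)
  } else {
    recs <- parse_clustal(path)
  }
  as_alignment(recs)
}

# Minimal tolerant FASTA reader.  Biostrings refuses ragged alignments
# outright; parsing lines ourselves lets us report ragged input as a
# format error with the offending context, and keeps '.' and unusual
# letters intact until as_alignment() normalises them.
parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    abort("not FASTA: no '>' header on first record", class = "locovar_format_error")
  }
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)  # first whitespace-delimited token
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, collapse = "", FUN.VALUE = "")
  if (length(seqs) != length(ids)) {
    abort("FASTA record with no sequence lines", class = "locovar_format_error")
  }
  tibble(id = ids, seq = unname(gsub("\\s", "", seqs)))
}

parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1], ignore.case = TRUE)) {
    abort("not CLUSTAL: missing header line", class = "locovar_format_error")
  }
  body <- lines[-1]
  body <- body[!grepl("^\\s*$", body)]
  # sequence lines: name, whitespace, residue block; skip conservation
  # rows (leading whitespace or only consensus characters)
  seq_line <- grepl("^\\S+\\s+\\S+", body) & !grepl("^[\\s.:*]+$", body, perl = TRUE)
  parts <- strsplit(body[seq_line], "\\s+")
  ids <- vapply(parts, `[[`, "", 1L)
  chunks <- vapply(parts, `[[`, "", 2L)
  # drop trailing cumulative residue counts some writers emit
  chunks <- gsub("[0-9]+$", "", chunks)
  keep <- grepl("^[A-Za-z.*-]+$", chunks)
  ids <- ids[keep]; chunks <- chunks[keep]
  if (!length(ids)) abort("no sequence lines in CLUSTAL file", class = "locovar_format_error")
  seqs <- vapply(split(chunks, factor(ids, levels = unique(ids))),
                 paste, collapse = "", FUN.VALUE = "")
  tibble(id = unique(ids), seq = unname(seqs))
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An alignment tibble.
#' @param path Output path.
#' @param width Line-wrap width for residue lines (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  aln <- as_alignment(aln)
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    abort(paste0("cannot write alignment: ", conditionMessage(e)),
          class = "locovar_io_error")
  })
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[[i]]), con)
    s <- aln$seq[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# alignment as a character matrix (rows = sequences, cols = positions)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

matrix_to_alignment <- function(m) {
  tibble(id = rownames(m), seq = unname(apply(m, 1L, paste, collapse = "")))
}

# residues as integer codes: 1..20 for AA20, 0 for gap/unknown
encode_column <- function(chars) {
  code <- match(chars, AA20)
  code[is.na(code)] <- 0L
  code
}

#' Select the gap-filtered analysis columns
#'
#' All covariation statistics operate on "analysis columns": original
#' alignment columns whose gap fraction does not exceed
#' `gap_threshold`.  The default 0 keeps only strictly ungapped
#' columns.
#'
#' @param aln An alignment tibble.
#' @param gap_threshold Maximum tolerated gap fraction in `[0, 1]`.
#' @return A tibble with columns `analysis_col` (1-based index into the
#'   kept set) and `original_col` (1-based index into the alignment),
#'   plus attributes `gap_threshold` and `width`.  The two columns form
#'   an invertible map between coordinate systems.
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), seq = c("A-C", "AAC"))
#' select_analysis_columns(aln)              # keeps columns 1 and 3
#' select_analysis_columns(aln, 0.5)         # keeps all three
#' @export
select_analysis_columns <- function(aln, gap_threshold = 0) {
  aln <- as_alignment(aln)
  stopifnot(gap_threshold >= 0, gap_threshold <= 1)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == GAP)
  kept <- which(gap_frac <= gap_threshold)
  if (!length(kept)) {
    abort("no columns pass the gap filter; nothing to analyse",
          class = "locovar_empty_analysis_error")
  }
  out <- tibble(analysis_col = seq_along(kept), original_col = as.integer(kept))
  attr(out, "gap_threshold") <- gap_threshold
  attr(out, "width") <- ncol(m)
  out
}
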