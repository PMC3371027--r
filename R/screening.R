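# Batch screening of alignment collections: run the full pipeline on
# every file with identical parameters and tabulate peak/region
# structure per alignment.  Failed alignments are carried in the
# report with an error note, never silently dropped.

#' Screen a set of alignment files for local covariation
#'
#' @param paths Character vector of alignment files, or a single
#'   directory (screened non-recursively for `.fa`, `.fasta`, `.afa`,
#'   `.aln`, `.clustal` files).
#' @param format Alignment format passed to [read_alignment()]; files
#'   ending in `.aln`/`.clustal` are read as CLUSTAL regardless.
#' @param gap_threshold,window,threshold Pipeline parameters (defaults
#'   0, 6, 2.0).
#' @return A `loco_screen` tibble: one row per input with
#'   `alignment_id`, `n_seqs`, `n_analysis_cols`, `n_windows`,
#'   `max_score`, `n_peaks`, `n_regions`, `max_run_length`, `category`
#'   and `note` (`NA` on success, the error message on failure;
#'   failed rows have category `"error"`).  Alignments with fewer
#'   analysis columns than the window are reported as category
#'   `"none"` with a `"too short/too gapped"` note.
#' @export
screen_alignments <- function(paths, format = "fasta", gap_threshold = 0,
                              window = 6L, threshold = 2.0) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta|afa|aln|clustal)$",
                        full.names = TRUE)
  }
  if (!length(paths)) {
    warn("no alignment files to screen")
    return(empty_screen_report())
  }
  rows <- purrr::map(sort(paths), function(p) {
    screen_one(p, format = format, gap_threshold = gap_threshold,
               window = window, threshold = threshold)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("loco_screen", class(out))
  attr(out, "params") <- list(gap_threshold = gap_threshold,
                              window = as.integer(window), threshold = threshold)
  out
}

empty_screen_report <- function() {
  out <- tibble(
    alignment_id = character(), n_seqs = integer(), n_analysis_cols = integer(),
    n_windows = integer(), max_score = numeric(), n_peaks = integer(),
    n_regions = integer(), max_run_length = integer(), category = character(),
    note = character()
  )
  class(out) <- c("loco_screen", class(out))
  out
}

screen_one <- function(path, format, gap_threshold, window, threshold) {
  id <- sub("\\.[^.]+$", "", basename(path))
  fmt <- if (grepl("\\.(aln|clustal)$", path)) "clustal" else format
  res <- tryCatch({
    aln <- read_alignment(path, format = fmt)
    prof <- withCallingHandlers(
      local_covariation(aln, gap_threshold = gap_threshold, window = window),
      warning = function(w) invokeRestart("muffleWarning")
    )
    g <- glance(prof, threshold = threshold)
    too_short <- g$n_windows == 0L
    tibble(
      alignment_id = id, n_seqs = g$n_seqs, n_analysis_cols = g$n_analysis_cols,
      n_windows = g$n_windows, max_score = g$max_score, n_peaks = g$n_peaks,
      n_regions = g$n_regions, max_run_length = g$max_run_length,
      category = if (too_short) "none" else g$category,
      note = if (too_short) "too short/too gapped" else NA_character_
    )
  }, error = function(e) {
    tibble(
      alignment_id = id, n_seqs = NA_integer_, n_analysis_cols = NA_integer_,
      n_windows = NA_integer_, max_score = NA_real_, n_peaks = NA_integer_,
      n_regions = NA_integer_, max_run_length = NA_integer_,
      category = "error", note = conditionMessage(e)
    )
  })
  res
}

#' Tabulate a screening report by category
#'
#' @param report A `loco_screen` tibble.
#' @return A one-row tibble: `n_alignments`, counts per category
#'   (`none`, `isolated`, `adjacent_pair`, `extended`, `error`),
#'   `n_with_peak` (at least one peak) and `n_extended_runs` (maximal
#'   run of 3+ peak windows).
#' @export
summarize_screen <- function(report) {
  stopifnot(inherits(report, "loco_screen") || is.data.frame(report))
  cats <- c("none", "isolated", "adjacent_pair", "extended", "error")
  counts <- vapply(cats, function(k) sum(report$category == k, na.rm = TRUE), 0L)
  tibble(
    n_alignments = nrow(report),
    !!!setNames(as.list(counts), cats),
    n_with_peak = sum(report$n_peaks >= 1L, na.rm = TRUE),
    n_extended_runs = sum(report$max_run_length >= 3L, na.rm = TRUE)
  )
}

#' Plot a screening report
#'
#' Scatter of sequence count against peak count, one point per
#' alignment, coloured by category.
#'
#' @param object A `loco_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loco_screen
#' @export
autoplot.loco_screen <- function(object, ...) {
  ok <- object[object$category != "error", , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$n_seqs, y = .data$n_peaks,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      none = "grey60", isolated = "black",
      adjacent_pair = "blue", extended = "red")) +
    ggplot2::labs(x = "sequences in alignment", y = "local covariation peaks (≥ threshold)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
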