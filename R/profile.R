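# Sliding-window local covariation, peak detection and alignment
# classification.
#
# The local-covariation score of a window is the mean Zp over all
# C(window, 2) column pairs fully inside the window.  Windows slide
# over consecutive *analysis* columns (post gap filter); reports map
# window spans back to 1-based original alignment coordinates.  A
# window scoring >= 2.0 is a peak; maximal runs of consecutive peaks
# form regions.

#' Local-covariation profile from a Zp matrix
#'
#' @param x A `loco_covariation` object with `zp` computed (see
#'   [covariation()]).
#' @param window Window length in analysis columns (default 6).
#' @param track `"max"` (default) or `"mean"`: how the per-column
#'   display track summarises the windows covering a column.
#' @return A `loco_profile` object.  [tidy()] gives the per-window
#'   table (`window`, `start_col`, `end_col` in original coordinates,
#'   `score`); `column_track` in the object maps every original
#'   alignment column to a display value (`NA` for columns outside all
#'   windows).  If there are fewer analysis columns than `window`, the
#'   profile is empty and a warning is raised.
#' @export
local_covariation_profile <- function(x, window = 6L, track = c("max", "mean")) {
  stopifnot(inherits(x, "loco_covariation"))
  if (is.null(x$zp)) abort("Zp not computed; run covariation() or normalize_zp() first")
  track <- match.arg(track)
  p <- nrow(x$columns)
  orig <- x$columns$original_col
  n_win <- p - window + 1L
  if (n_win < 1L) {
    warn(paste0("fewer analysis columns (", p, ") than the window (", window,
                "); profile is empty"))
    scores <- numeric(0)
    starts <- integer(0)
  } else {
    starts <- seq_len(n_win)
    scores <- vapply(starts, function(w) {
      block <- x$zp[w:(w + window - 1L), w:(w + window - 1L)]
      mean(block[upper.tri(block)])
    }, numeric(1))
  }
  windows <- tibble(
    window = starts,
    start_col = orig[starts],
    end_col = orig[starts + window - 1L],
    score = scores
  )
  # per-original-column display value over the windows covering it
  width <- attr(x$columns, "width") %||% max(orig)
  col_track <- rep(NA_real_, width)
  if (n_win >= 1L) {
    fun <- if (track == "max") max else mean
    for (j in seq_len(p)) {
      covering <- starts[starts <= j & starts + window - 1L >= j]
      if (length(covering)) col_track[orig[j]] <- fun(scores[covering])
    }
  }
  structure(
    list(windows = windows, column_track = col_track, window_size = as.integer(window),
         track = track, n_seqs = x$n_seqs, columns = x$columns),
    class = "loco_profile"
  )
}

#' Full pipeline: alignment to local-covariation profile
#'
#' Runs gap filtering, MI, the average-product correction, Zp and the
#' sliding-window profile in one call.
#'
#' @param aln An alignment tibble.
#' @inheritParams covariation
#' @inheritParams local_covariation_profile
#' @return A `loco_profile` object.
#' @examples
#' syn <- simulate_shifted_alignment(shift_fraction = 0.05, seed = 1)
#' prof <- local_covariation(syn$alignment)
#' detect_peaks(prof)
#' @export
local_covariation <- function(aln, gap_threshold = 0, window = 6L,
                              base = 2, sd_convention = "sample",
                              track = "max") {
  cv <- covariation(aln, gap_threshold = gap_threshold, base = base,
                    sd_convention = sd_convention)
  local_covariation_profile(cv, window = window, track = track)
}

#' Detect local-covariation peaks and contiguous regions
#'
#' A window is a peak if its score meets `threshold` (default 2.0); a
#' secondary advisory threshold of 2.5 marks windows that are strong
#' candidates even under a conservative reading.  Maximal runs of
#' consecutive peak windows are grouped into regions.
#'
#' @param profile A `loco_profile` object.
#' @param threshold Peak threshold on the window score (default 2.0).
#' @param advisory Advisory threshold echoed in the output (default 2.5).
#' @return A `loco_peaks` object with `peaks` (tibble of peak windows)
#'   and `regions` (tibble with `region`, `start_col`, `end_col`,
#'   `n_windows`, `max_score` per maximal run).
#' @export
detect_peaks <- function(profile, threshold = 2.0, advisory = 2.5) {
  stopifnot(inherits(profile, "loco_profile"))
  w <- profile$windows
  is_peak <- !is.na(w$score) & w$score >= threshold
  peaks <- w[is_peak, , drop = FALSE]
  peaks$above_advisory <- peaks$score >= advisory
  regions <- tibble(region = integer(), start_col = integer(), end_col = integer(),
                    n_windows = integer(), max_score = numeric())
  if (nrow(peaks)) {
    run_id <- cumsum(c(1L, diff(peaks$window) != 1L))
    regions <- peaks |>
      dplyr::mutate(region = run_id) |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        start_col = min(.data$start_col),
        end_col = max(.data$end_col),
        n_windows = dplyr::n(),
        max_score = max(.data$score),
        .groups = "drop"
      )
  }
  structure(
    list(peaks = peaks, regions = regions,
         threshold = threshold, advisory = advisory,
         n_windows = nrow(w)),
    class = "loco_peaks"
  )
}

#' Classify an alignment by its peak-region structure
#'
#' Categories follow the screening convention: `extended` if any region
#' spans three or more consecutive peak windows, else `adjacent_pair`
#' if any region spans exactly two, else `isolated` if at least one
#' peak exists, else `none`.
#'
#' @param peaks A `loco_peaks` object from [detect_peaks()].
#' @return One of `"none"`, `"isolated"`, `"adjacent_pair"`,
#'   `"extended"`.
#' @export
classify_alignment <- function(peaks) {
  stopifnot(inherits(peaks, "loco_peaks"))
  runs <- peaks$regions$n_windows
  if (!length(runs)) return("none")
  if (any(runs >= 3L)) return("extended")
  if (any(runs == 2L)) return("adjacent_pair")
  "isolated"
}

#' @export
print.loco_profile <- function(x, ...) {
  cat("<loco_profile> window ", x$window_size, ", ",
      nrow(x$windows), " windows over ", nrow(x$columns),
      " analysis columns\n", sep = "")
  if (nrow(x$windows)) {
    cat("  max window score: ", signif(max(x$windows$score), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.loco_peaks <- function(x, ...) {
  cat("<loco_peaks> ", nrow(x$peaks), " peak(s) >= ", x$threshold,
      " in ", nrow(x$regions), " region(s)\n", sep = "")
  invisible(x)
}

#' Tidy a profile into its per-window table
#'
#' @param x A `loco_profile` object.
#' @param ... Unused.
#' @return Tibble with `window`, `start_col`, `end_col` (original
#'   1-based coordinates) and `score`.
#' @method tidy loco_profile
#' @export
tidy.loco_profile <- function(x, ...) x$windows

#' One-row summary of a profile
#'
#' @param x A `loco_profile` object.
#' @param threshold Peak threshold used for the summary counts.
#' @param ... Unused.
#' @return One-row tibble with window counts, peak/region counts at
#'   `threshold`, the maximal run length and the category.
#' @method glance loco_profile
#' @export
glance.loco_profile <- function(x, threshold = 2.0, ...) {
  pk <- detect_peaks(x, threshold = threshold)
  tibble(
    n_seqs = x$n_seqs,
    n_analysis_cols = nrow(x$columns),
    n_windows = nrow(x$windows),
    max_score = if (nrow(x$windows)) max(x$windows$score) else NA_real_,
    n_peaks = nrow(pk$peaks),
    n_regions = nrow(pk$regions),
    max_run_length = if (nrow(pk$regions)) max(pk$regions$n_windows) else 0L,
    category = classify_alignment(pk)
  )
}

#' Plot a local-covariation profile
#'
#' Bar histogram of per-window scores with the peak threshold drawn;
#' windows at or above the threshold are highlighted.
#'
#' @param object A `loco_profile` object.
#' @param threshold Peak threshold to highlight (default 2.0).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loco_profile
#' @export
autoplot.loco_profile <- function(object, threshold = 2.0, ...) {
  w <- object$windows
  w$is_peak <- w$score >= threshold
  ggplot2::ggplot(w, ggplot2::aes(x = .data$start_col, y = .data$score,
                                  fill = .data$is_peak)) +
    ggplot2::geom_col(width = 1, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "gold")) +
    ggplot2::labs(x = "window start (alignment column)",
                  y = "local covariation (mean Zp)") +
    ggplot2::theme_minimal()
}
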