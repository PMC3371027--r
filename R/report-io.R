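# TSV report writers.  Every output carries a commented header
# echoing the tool version, run parameters and an MD5 checksum of the
# input, so a report can always be traced back to the exact run that
# produced it.

#' Assemble a run configuration
#'
#' Bundles the tunable pipeline parameters with their defaults: gap
#' threshold 0 (strictly ungapped analysis columns), window 6, peak
#' threshold 2.0 with advisory threshold 2.5, sample-sd Zp convention
#' and MI in bits.
#'
#' @param gap_threshold,window,peak_threshold,advisory_threshold,sd_convention,log_base,seed
#'   Pipeline parameters; see the corresponding functions.
#' @return A named list of class `loco_config`.
#' @export
run_config <- function(gap_threshold = 0, window = 6L, peak_threshold = 2.0,
                       advisory_threshold = 2.5, sd_convention = "sample",
                       log_base = 2, seed = NULL) {
  structure(list(
    gap_threshold = gap_threshold, window = as.integer(window),
    peak_threshold = peak_threshold, advisory_threshold = advisory_threshold,
    sd_convention = sd_convention, log_base = log_base, seed = seed
  ), class = "loco_config")
}

report_header <- function(config = NULL, input = NULL) {
  ver <- as.character(utils::packageVersion("locovar"))
  lines <- paste0("# locovar ", ver)
  if (!is.null(input) && file.exists(input)) {
    lines <- c(lines, paste0("# input: ", basename(input),
                             " md5=", unname(tools::md5sum(input))))
  }
  if (!is.null(config)) {
    pars <- vapply(config[!vapply(config, is.null, TRUE)],
                   function(v) paste(v, collapse = ","), "")
    lines <- c(lines, paste0("# params: ",
                             paste(names(pars), pars, sep = "=", collapse = " ")))
  }
  lines
}

write_tsv_report <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by this package
#'
#' @param path Path to the TSV; commented header lines are skipped.
#' @return A tibble.
#' @export
read_tsv_report <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#", sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Write the per-pair covariation summary
#'
#' One row per unordered analysis-column pair with MI, MIp and Zp in
#' 1-based original alignment coordinates (plus `distance_angstrom`
#' when structure annotation has been joined in).
#'
#' @param cv A `loco_covariation` object, or an already-tidied pair
#'   tibble (e.g. after [annotate_distances()]).
#' @param path Output TSV path.
#' @param config Optional `loco_config` echoed into the header.
#' @param input Optional input-file path checksummed into the header.
#' @return `path`, invisibly.
#' @export
write_pair_summary <- function(cv, path, config = NULL, input = NULL) {
  df <- if (inherits(cv, "loco_covariation")) tidy(cv) else cv
  write_tsv_report(df, path, report_header(config, input))
}

#' Write the per-window profile and per-region TSVs
#'
#' @param profile A `loco_profile` object.
#' @param path Output TSV for the windows (`window_start_col`,
#'   `window_end_col`, `score`, `is_peak`).
#' @param region_path Optional TSV for peak regions (`start`, `end`,
#'   `n_windows`, `max_score`, `category` of the whole alignment).
#' @param threshold Peak threshold (default 2.0).
#' @param config,input Header metadata as in [write_pair_summary()].
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(profile, path, region_path = NULL,
                                 threshold = 2.0, config = NULL, input = NULL) {
  pk <- detect_peaks(profile, threshold = threshold)
  w <- profile$windows
  df <- tibble(
    window_start_col = w$start_col, window_end_col = w$end_col,
    score = w$score, is_peak = as.integer(w$score >= threshold)
  )
  hdr <- report_header(config, input)
  write_tsv_report(df, path, hdr)
  if (!is.null(region_path)) {
    reg <- pk$regions
    reg$category <- classify_alignment(pk)
    write_tsv_report(reg[, c("start_col", "end_col", "n_windows", "max_score",
                             "category")], region_path, hdr)
  }
  invisible(path)
}
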