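# Plain-text interchange: TSV for events/behavior/band courses and JSON for
# cluster reports. Everything round-trips through standard data.frames.

#' Write task events or behavioral tables as TSV
#'
#' @param x data.frame (e.g. from [generate_task_events()] or
#'   [simulate_behavior()]).
#' @param path output file.
#' @export
write_events_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_events_tsv()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Export a band-power course as long-format TSV
#'
#' Columns: trial, location, time, power.
#'
#' @param course a [band_power_course()].
#' @param path output file.
#' @export
write_band_course_tsv <- function(course, path) {
  d <- dim(course$power)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    location = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(course$times, each = d[1] * d[2]),
    power = as.vector(course$power))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a cluster report as JSON
#'
#' Members are written as index lists (location, time); the permutation
#' maximum-statistic distribution is included.
#'
#' @param report a `cluster_report` from [permutation_p()].
#' @param path output file.
#' @export
write_cluster_report_json <- function(report, path) {
  out <- list(
    statistic = report$statistic,
    n_permutations = report$n_permutations,
    alpha = report$alpha,
    clusters = lapply(report$clusters, function(cl) list(
      sign = cl$sign, stat_sum = cl$stat_sum, p = cl$p,
      members = apply(cl$members, 1, as.list))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
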