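validate_hypnogram <- function(hyp, where = "hypnogram") {
  required <- c("start_s", "end_s", "state")
  if (!all(required %in% names(hyp))) {
    stop(where, " needs columns start_s, end_s, state", call. = FALSE)
  }
  hyp$state <- as.character(hyp$state)
  bad <- which(!hyp$state %in% STATE_LEVELS)
  if (length(bad)) {
    stop(where, ": unknown state(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(hyp$end_s <= hyp$start_s)
  if (length(bad)) {
    stop(where, ": empty or inverted interval(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  hyp <- hyp[order(hyp$start_s), required, drop = FALSE]
  rownames(hyp) <- NULL
  overlap <- which(utils::head(hyp$end_s, -1) > utils::tail(hyp$start_s, -1) + 1e-9)
  if (length(overlap)) {
    stop(where, ": overlapping interval(s) at data row(s) ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  hyp
}

#' Write / read the unitary-event table
#'
#' Tab-delimited UTF-8 text with a header row and one row per unitary event:
#' `mouse_id`, `neuron_id`, `session`, `time_s`, `amplitude` ('.' decimal
#' separator). `read_events` validates the table (known session labels,
#' positive amplitudes, per-neuron-session nondecreasing times) and reports
#' offending file line numbers; a write/read round trip reproduces the
#' experiment's events exactly.
#'
#' @param experiment an `abn_experiment`.
#' @param path file path.
#' @rdname event_table_io
#' @export
write_events <- function(experiment, path) {
  stopifnot(inherits(experiment, "abn_experiment"))
  utils::write.table(format_numeric_df(experiment$events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Fixed-precision formatting so written tables are byte-stable across platforms.
format_numeric_df <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = digits,
                                                format = "g")
  }
  df
}

#' @param session_durations named numeric vector of session durations in
#'   seconds (the event table itself does not carry durations).
#' @param hypnogram optional hypnogram (see [read_hypnogram()]).
#' @param neurons optional neuron roster (for declaring silent neurons).
#' @return `read_events`: an `abn_experiment`.
#' @rdname event_table_io
#' @export
read_events <- function(path, session_durations, hypnogram = NULL,
                        neurons = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("mouse_id", "neuron_id", "session", "time_s", "amplitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!df$session %in% SESSION_LEVELS)
  if (length(bad)) {
    stop(path, ": unknown session label at line(s) ",
         paste(utils::head(line_no[bad], 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$amplitude) | df$amplitude <= 0)
  if (length(bad)) {
    stop(path, ": non-positive amplitude at line(s) ",
         paste(utils::head(line_no[bad], 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad)) {
    stop(path, ": invalid time at line(s) ",
         paste(utils::head(line_no[bad], 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$mouse_id, df$neuron_id, df$session)
  unsorted <- unlist(lapply(split(seq_len(nrow(df)), key), function(ix) {
    drop <- which(diff(df$time_s[ix]) < 0)
    if (length(drop)) ix[drop + 1] else integer(0)
  }), use.names = FALSE)
  if (length(unsorted)) {
    stop(path, ": unsorted event times at line(s) ",
         paste(utils::head(sort(line_no[unsorted]), 5), collapse = ", "),
         call. = FALSE)
  }
  new_experiment(df, session_durations, hypnogram = hypnogram, neurons = neurons)
}

#' Write / read a hypnogram
#'
#' Tab-delimited intervals `start_s`, `end_s`, `state` with states from
#' `wake`, `NREM`, `REM`; intervals must be non-overlapping. Overlaps, unknown
#' states and inverted intervals are rejected with data-row numbers.
#'
#' @param hypnogram data.frame of intervals.
#' @param path file path.
#' @rdname hypnogram_io
#' @export
write_hypnogram <- function(hypnogram, path) {
  hyp <- validate_hypnogram(hypnogram)
  utils::write.table(format_numeric_df(hyp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @return `read_hypnogram`: validated data.frame sorted by start time.
#' @rdname hypnogram_io
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_hypnogram(df, where = path)
}

#' Fraction of hypnogram time spent in given states
#'
#' @param hypnogram a validated hypnogram.
#' @param states state subset (default REM).
#' @return fraction of total covered time.
#' @export
state_fraction <- function(hypnogram, states = "REM") {
  hyp <- validate_hypnogram(hypnogram)
  len <- hyp$end_s - hyp$start_s
  sum(len[hyp$state %in% states]) / sum(len)
}
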