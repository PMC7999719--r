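#' Assemble an experiment from an event table
#'
#' An experiment bundles the deconvolved unitary calcium events of every neuron
#' across the recording sessions of a fear-conditioning paradigm, the session
#' durations, the hypnogram of the consolidation recording, and (for synthetic
#' data) the ground-truth neuron labels.
#'
#' @param events data.frame with columns `mouse_id`, `neuron_id`, `session`,
#'   `time_s`, `amplitude`; one row per unitary event. `session` must come from
#'   `preC`, `preS`, `postS`, `consolidation`, `test`. Times are seconds from
#'   the start of the session; amplitudes are positive fluorescence units.
#' @param session_durations named numeric vector of session durations in
#'   seconds, names from the session vocabulary.
#' @param hypnogram optional data.frame with columns `start_s`, `end_s`,
#'   `state` covering the consolidation recording (see [read_hypnogram()]).
#' @param neurons optional data.frame (`mouse_id`, `neuron_id`) fixing the
#'   neuron roster and its order; defaults to the neurons present in `events`.
#'   Neurons silent in every session must be declared here to be analysed.
#' @param ground_truth optional data.frame of generator labels.
#' @return an object of class `abn_experiment`.
#' @export
new_experiment <- function(events, session_durations, hypnogram = NULL,
                           neurons = NULL, ground_truth = NULL) {
  required <- c("mouse_id", "neuron_id", "session", "time_s", "amplitude")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("events table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events$mouse_id <- as.character(events$mouse_id)
  events$neuron_id <- as.character(events$neuron_id)
  events$session <- as.character(events$session)

  bad_session <- !events$session %in% SESSION_LEVELS
  if (any(bad_session)) {
    stop("unknown session label(s): ",
         paste(unique(events$session[bad_session]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(session_durations)) ||
      !all(names(session_durations) %in% SESSION_LEVELS)) {
    stop("session_durations must be named with known session labels", call. = FALSE)
  }
  if (any(!is.finite(session_durations)) || any(session_durations <= 0)) {
    stop("session durations must be positive and finite", call. = FALSE)
  }
  missing_dur <- setdiff(unique(events$session), names(session_durations))
  if (length(missing_dur)) {
    stop("no duration given for session(s): ", paste(missing_dur, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$amplitude <= 0 | !is.finite(events$amplitude))) {
    stop("all event amplitudes must be positive and finite", call. = FALSE)
  }
  dur <- session_durations[events$session]
  if (any(events$time_s < 0 | events$time_s > dur)) {
    stop("event times must lie within [0, session duration]", call. = FALSE)
  }

  if (is.null(neurons)) {
    neurons <- unique(events[, c("mouse_id", "neuron_id")])
  } else {
    neurons <- data.frame(mouse_id = as.character(neurons$mouse_id),
                          neuron_id = as.character(neurons$neuron_id),
                          stringsAsFactors = FALSE)
  }
  neurons <- neurons[order(neurons$mouse_id, neurons$neuron_id), , drop = FALSE]
  rownames(neurons) <- NULL
  if (anyDuplicated(neurons$neuron_id)) {
    stop("neuron ids must be unique across mice", call. = FALSE)
  }
  stray <- setdiff(events$neuron_id, neurons$neuron_id)
  if (length(stray)) {
    stop("events reference undeclared neuron(s): ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }

  # Canonical event order: mouse, neuron, session, time.
  ord <- order(events$mouse_id, events$neuron_id,
               match(events$session, SESSION_LEVELS), events$time_s)
  events <- events[ord, required, drop = FALSE]
  rownames(events) <- NULL

  if (!is.null(hypnogram)) hypnogram <- validate_hypnogram(hypnogram)

  structure(
    list(events = events,
         session_durations = session_durations,
         neurons = neurons,
         hypnogram = hypnogram,
         ground_truth = ground_truth),
    class = "abn_experiment"
  )
}

#' @export
print.abn_experiment <- function(x, ...) {
  cat("<abn_experiment>\n")
  cat("  neurons:", nrow(x$neurons), "across", length(unique(x$neurons$mouse_id)),
      "mice\n")
  cat("  events:", nrow(x$events), "\n")
  cat("  sessions:", paste(sprintf("%s (%ds)", names(x$session_durations),
                                   round(x$session_durations)), collapse = ", "), "\n")
  cat("  hypnogram:", if (is.null(x$hypnogram)) "none" else
    paste(nrow(x$hypnogram), "intervals"), "\n")
  invisible(x)
}

#' Neuron roster of an experiment, in fixed analysis order
#' @param experiment an `abn_experiment`.
#' @return data.frame with `mouse_id`, `neuron_id`, ordered by mouse then neuron.
#' @export
neuron_table <- function(experiment) {
  stopifnot(inherits(experiment, "abn_experiment"))
  experiment$neurons
}

#' Duration of one session in seconds
#' @param experiment an `abn_experiment`.
#' @param session session label.
#' @export
session_duration <- function(experiment, session) {
  stopifnot(inherits(experiment, "abn_experiment"))
  if (!session %in% names(experiment$session_durations)) {
    stop("experiment has no session '", session, "'", call. = FALSE)
  }
  unname(experiment$session_durations[[session]])
}

#' Extract one neuron's event train for one session
#'
#' @param experiment an `abn_experiment`.
#' @param neuron_id neuron identifier.
#' @param session session label.
#' @return an [event_train()] (possibly empty if the neuron was silent).
#' @export
get_event_train <- function(experiment, neuron_id, session) {
  stopifnot(inherits(experiment, "abn_experiment"))
  if (!neuron_id %in% experiment$neurons$neuron_id) {
    stop("unknown neuron '", neuron_id, "'", call. = FALSE)
  }
  dur <- session_duration(experiment, session)
  rows <- experiment$events$neuron_id == neuron_id &
    experiment$events$session == session
  ev <- experiment$events[rows, , drop = FALSE]
  mouse <- experiment$neurons$mouse_id[match(neuron_id, experiment$neurons$neuron_id)]
  event_train(neuron_id = neuron_id, mouse_id = mouse, session = session,
              times = ev$time_s, amplitudes = ev$amplitude, duration = dur)
}
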