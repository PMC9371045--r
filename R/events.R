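# From per-packet state predictions to energy events (incision intervals).

#' Build a state stream
#'
#' A state stream pairs strictly increasing timestamps on the 50 ms packet
#' grid with one state code per timestamp.
#'
#' @param timestamps_s numeric timestamps in seconds, strictly increasing.
#' @param states state codes or names, one per timestamp.
#' @return a data.frame with columns `timestamp_s` and `state`.
#' @export
stateStream <- function(timestamps_s, states) {
  states <- asStateCode(states)
  if (length(timestamps_s) != length(states))
    stop("timestamps and states must have equal length")
  if (length(timestamps_s) > 1L && any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  data.frame(timestamp_s = as.numeric(timestamps_s), state = states)
}

#' Majority-vote smoothing of a state stream
#'
#' Replaces each per-packet state with the modal label of the trailing
#' `window` packets (fewer near the start of the stream). The window is
#' causal — only past packets are consulted — because the clinical use is
#' real-time notification. Ties keep the previously emitted label, which
#' suppresses spurious event edges from oscillating predictions; a tie on the
#' very first packet resolves to the lowest state code. `window = 1` is the
#' identity.
#'
#' Combining ~20 classifications (1 s at 20 packets/s) stabilizes the label,
#' but a window as long as a typical 1 s incision can swallow the incision
#' entirely, so the window is a parameter and event-detection work typically
#' uses windows no longer than half the expected incision.
#'
#' @param stream a state stream (see [stateStream()]).
#' @param window trailing window length in packets (>= 1).
#' @return a state stream of the same length and timestamps.
#' @examples
#' s <- stateStream((0:4) * 0.05, c("cut_air", "cut_air", "cut_tissue",
#'                                  "cut_air", "cut_air"))
#' majorityVote(s, window = 3)$state
#' @export
majorityVote <- function(stream, window = 20L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  states <- stream$state
  n <- length(states)
  out <- integer(n)
  prev <- NA_integer_
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    counts <- table(states[lo:i])
    top <- as.integer(names(counts)[counts == max(counts)])
    pick <- if (length(top) == 1L) top else if (!is.na(prev)) prev else min(top)
    out[i] <- pick
    prev <- pick
  }
  data.frame(timestamp_s = stream$timestamp_s, state = out)
}

#' Detect energy events in a state stream
#'
#' An event (incision) opens at the first timestamp of a maximal run of
#' tissue-contact states entered from off/air (or from the stream start) and
#' closes at the last timestamp of that run. A direct switch between
#' cut-on-tissue and coagulate-on-tissue closes the current event and opens a
#' new one with the new mode, so per-mode bookkeeping survives. A stream that
#' ends mid-contact yields an event closed at the final timestamp and flagged
#' `truncated`.
#'
#' @param stream a state stream (see [stateStream()]).
#' @return a data.frame of events with columns `start_s`, `end_s`, `mode`,
#'   `n_packets`, `truncated`, ordered in time.
#' @examples
#' s <- stateStream((0:4) * 0.05,
#'                  c("cut_air", "cut_air", "cut_tissue", "cut_tissue",
#'                    "cut_air"))
#' detectEvents(s)
#' @export
detectEvents <- function(stream) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      mode = character(0), n_packets = integer(0),
                      truncated = logical(0))
  n <- nrow(stream)
  if (!n) return(empty)
  contact <- isTissueState(stream$state)
  if (!any(contact)) return(empty)
  # maximal runs of identical state; contact runs become events
  r <- rle(stream$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- isTissueState(r$values)
  ev <- data.frame(
    start_s = stream$timestamp_s[starts[keep]],
    end_s = stream$timestamp_s[ends[keep]],
    mode = stateMode(r$values[keep]),
    n_packets = r$lengths[keep],
    truncated = FALSE)
  if (contact[n]) ev$truncated[nrow(ev)] <- TRUE
  rownames(ev) <- NULL
  ev
}

#' Streaming detection: packets to events
#'
#' End-to-end composition of the pipeline on a packet sequence: spectral
#' features, per-packet state prediction, causal majority-vote smoothing,
#' and event detection. Packets are processed in arrival order; only the
#' trailing `window` predictions are consulted, so the same result would be
#' obtained packet by packet in real time.
#'
#' A trailing majority vote reacts to a genuine state change only once the
#' new state holds a majority of the window — a fixed group delay of
#' `floor((window - 1) / 2)` packets. Since that delay is known, reported
#' event boundaries are shifted back by it (never before the first packet),
#' so under accurate per-packet predictions start/end timestamps land within
#' one packet of the true transition while detection itself stays causal.
#'
#' @param pset a [PacketSet] (states may be unknown).
#' @param model a `TrainedModel` with task `"state"`.
#' @param window majority-vote window in packets.
#' @return a list with elements `stream` (the smoothed state stream) and
#'   `events` (see [detectEvents()]).
#' @export
streamDetect <- function(pset, model, window = 5L) {
  stopifnot(is(pset, "PacketSet"), is(model, "TrainedModel"))
  if (model@spec@task != "state") stop("model task is not 'state'")
  if (!ncol(pset)) {
    s <- data.frame(timestamp_s = numeric(0), state = integer(0))
    return(list(stream = s, events = detectEvents(s)))
  }
  fx <- extractFeatures(pset)
  pred <- predictStates(model, fx)
  raw <- stateStream(packetInfo(pset)$timestamp_s, pred)
  smooth <- majorityVote(raw, window)
  events <- detectEvents(smooth)
  if (nrow(events)) {
    delay <- floor((as.integer(window) - 1L) / 2L) /
             packetRateHz(acquisitionConfig(pset))
    events$start_s <- pmax(events$start_s - delay, smooth$timestamp_s[1L])
    events$end_s <- pmax(events$end_s - delay, smooth$timestamp_s[1L])
  }
  list(stream = smooth, events = events)
}
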