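#' Build an event table
#'
#' An event table lists stimulus onsets as 0-based sample indices at a fixed
#' sampling rate, together with a label (`click1`, `click2`, `train_onset`,
#' `click`, `standard`, `deviant`, ...), a block id and, for tonal stimuli,
#' the tone frequency.  It is the timing contract between the stimulation
#' protocols, the simulator and every analysis stage.
#'
#' @param onset_sample integer vector of 0-based onsets (strictly increasing).
#' @param label character vector of event labels (recycled if length 1).
#' @param fs sampling rate in Hz.
#' @param block_id integer block identifier (e.g. flip-flop half).
#' @param tone_freq_hz tone frequency in Hz or `NA` for broadband clicks.
#' @return a `data.frame` of class `event_table` with columns
#'   `onset_sample`, `onset_s`, `label`, `block_id`, `tone_freq_hz` and an
#'   `fs` attribute.
#' @export
event_table <- function(onset_sample, label, fs, block_id = 1L,
                        tone_freq_hz = NA_real_) {
  onset_sample <- as.integer(round(onset_sample))
  if (length(onset_sample) && any(diff(onset_sample) <= 0))
    stop("event onsets must be strictly increasing", call. = FALSE)
  if (length(onset_sample) && any(onset_sample < 0))
    stop("event onsets must be non-negative", call. = FALSE)
  ev <- data.frame(
    onset_sample = onset_sample,
    onset_s      = onset_sample / fs,
    label        = rep_len(as.character(label), length(onset_sample)),
    block_id     = rep_len(as.integer(block_id), length(onset_sample)),
    tone_freq_hz = rep_len(as.numeric(tone_freq_hz), length(onset_sample)),
    stringsAsFactors = FALSE
  )
  attr(ev, "fs") <- fs
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events @ %g Hz\n", nrow(x), attr(x, "fs")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more events\n", nrow(x) - 10L))
  invisible(x)
}

#' Write / read an event table as tab-separated text
#'
#' The sidecar format is a UTF-8 TSV with a header row and the columns
#' `onset_sample`, `onset_s`, `label`, `block_id`, `tone_freq_hz`.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an [event_table()].
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_table
#' @param fs sampling rate in Hz; if `NULL`, recovered from the
#'   `onset_sample`/`onset_s` ratio of the first nonzero onset.
#' @export
read_event_table <- function(path, fs = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("onset_sample", "onset_s", "label", "block_id", "tone_freq_hz")
  if (!all(need %in% names(df)))
    stop("event table file is missing required columns", call. = FALSE)
  if (is.null(fs)) {
    nz <- which(df$onset_sample > 0L)
    if (!length(nz))
      stop("cannot recover sampling rate from a table with no nonzero onset; ",
           "pass `fs` explicitly", call. = FALSE)
    fs <- df$onset_sample[nz[1L]] / df$onset_s[nz[1L]]
  }
  event_table(df$onset_sample, df$label, fs = fs,
              block_id = df$block_id, tone_freq_hz = df$tone_freq_hz)
}
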