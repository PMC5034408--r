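#' Multi-channel temperature trace
#'
#' A temperature trace is a tibble with a `time_s` column (uniformly spaced,
#' strictly increasing, seconds) and one column per thermocouple channel
#' (degrees Celsius). `temp_trace()` validates a data frame and attaches the
#' sample rate and optional metadata as attributes.
#'
#' @param data Data frame with a `time_s` column and at least one channel
#'   column. All channel columns must be numeric.
#' @param sample_rate_hz Sampling frequency in Hz. Inferred from `time_s`
#'   when `NULL`.
#' @param meta Named list of free-form metadata (set-point, seed, warnings...).
#'
#' @return A tibble of class `temp_trace` with attributes `sample_rate_hz`
#'   and `meta`.
#' @export
#' @examples
#' tr <- temp_trace(tibble::tibble(time_s = 0:9 * 2, T0 = 22 + 0:9 * 0.1))
#' trace_channels(tr)
temp_trace <- function(data, sample_rate_hz = NULL, meta = list()) {
  data <- tibble::as_tibble(data)
  if (!"time_s" %in% names(data)) {
    abort("trace must have a `time_s` column", class = "prosthermal_format_error")
  }
  chans <- setdiff(names(data), "time_s")
  if (length(chans) == 0) {
    abort("trace must have at least one channel column",
          class = "prosthermal_format_error")
  }
  bad <- chans[!vapply(data[chans], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric channel column(s): ", paste(bad, collapse = ", ")),
          class = "prosthermal_format_error")
  }
  t <- data$time_s
  if (length(t) < 2 || any(diff(t) <= 0)) {
    abort("`time_s` must be strictly increasing with at least 2 samples",
          class = "prosthermal_format_error")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(t))) {
    abort(sprintf(
      "`time_s` must be uniformly spaced (max deviation %.3g s from dt = %.6g s)",
      max(abs(dt - dt[1])), dt[1]), class = "prosthermal_format_error")
  }
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / dt[1]
  structure(data,
            class = c("temp_trace", class(tibble::tibble())),
            sample_rate_hz = sample_rate_hz,
            meta = meta)
}

#' @rdname temp_trace
#' @param x A `temp_trace`.
#' @export
trace_channels <- function(x) setdiff(names(x), "time_s")

#' @rdname temp_trace
#' @export
trace_sample_rate <- function(x) attr(x, "sample_rate_hz")

#' @rdname temp_trace
#' @export
trace_meta <- function(x) attr(x, "meta") %||% list()

#' @export
print.temp_trace <- function(x, ...) {
  cat(sprintf("<temp_trace: %d samples x %d channel(s) @ %.3g Hz, %.1f s>\n",
              nrow(x), length(trace_channels(x)), trace_sample_rate(x),
              max(x$time_s) - min(x$time_s)))
  NextMethod()
}

get_channel <- function(trace, channel) {
  if (!channel %in% names(trace)) {
    abort(sprintf("channel '%s' not found (available: %s)", channel,
                  paste(setdiff(names(trace), "time_s"), collapse = ", ")),
          class = "prosthermal_format_error")
  }
  trace[[channel]]
}

#' Read and write temperature trace CSV files
#'
#' The trace CSV dialect has a header `time_s,<channel>,...`, one row per
#' sample, UTF-8 with a decimal point. `read_trace()` validates uniform time
#' spacing and reports malformed content with the offending column or line.
#'
#' @param path File path.
#' @param trace A [temp_trace()].
#' @return `read_trace()` returns a validated [temp_trace()];
#'   `write_trace()` invisibly returns `path`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "prosthermal_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed trace CSV '%s': %d parsing problem(s), first at line %d (%s)",
                  path, nrow(prob), prob$row[1] + 1L, prob$expected[1]),
          class = "prosthermal_format_error")
  }
  if (!"time_s" %in% names(df)) {
    abort(sprintf("trace CSV '%s' is missing required column 'time_s'", path),
          class = "prosthermal_format_error")
  }
  temp_trace(df, meta = list(source = path))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "temp_trace"))
  readr::write_csv(tibble::as_tibble(unclass_trace(trace)), path, progress = FALSE)
  invisible(path)
}

unclass_trace <- function(trace) {
  class(trace) <- setdiff(class(trace), "temp_trace")
  attr(trace, "sample_rate_hz") <- NULL
  attr(trace, "meta") <- NULL
  trace
}

#' Block-average a trace in time
#'
#' Non-overlapping block means over windows of `window_s` seconds, applied
#' identically to every channel; used to smooth logger fluctuations before
#' trend analysis (the trials use a 5-s window). The block size is
#' `floor(window_s * sample_rate)` samples and any trailing partial block is
#' dropped, so a 5-s window at 0.5 Hz averages pairs of samples.
#'
#' @param trace A [temp_trace()].
#' @param window_s Averaging window in seconds; must cover at least one
#'   sample interval.
#' @return A [temp_trace()] at the reduced rate; block times are the mean
#'   time of each block.
#' @export
time_average <- function(trace, window_s) {
  stopifnot(inherits(trace, "temp_trace"))
  rate <- trace_sample_rate(trace)
  block <- floor(window_s * rate)
  if (block < 1) {
    abort(sprintf("window_s = %g s is smaller than one sample interval (%g s)",
                  window_s, 1 / rate), class = "prosthermal_validation_error")
  }
  n_blocks <- nrow(trace) %/% block
  if (n_blocks < 1) {
    abort("trace shorter than one averaging window",
          class = "prosthermal_validation_error")
  }
  idx <- rep(seq_len(n_blocks), each = block)
  kept <- seq_len(n_blocks * block)
  out <- tibble::as_tibble(unclass_trace(trace))[kept, ]
  out <- dplyr::summarise(dplyr::group_by(out, block = idx),
                          dplyr::across(dplyr::everything(), mean),
                          .groups = "drop")
  out$block <- NULL
  temp_trace(out, sample_rate_hz = rate / block,
             meta = c(trace_meta(trace), list(averaged_window_s = window_s)))
}

#' Plot a temperature trace
#'
#' @param object A [temp_trace()].
#' @param ... Unused.
#' @return A ggplot with one line per channel.
#' @export
autoplot.temp_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass_trace(object)),
                              -"time_s", names_to = "channel",
                              values_to = "temperature_c")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 60, .data$temperature_c,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [min]", y = "temperature [°C]", colour = NULL)
}
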