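# SEMG signal container: a tibble (time_s, value_mV) carrying the sampling
# rate as an attribute, so signals pipe through dplyr verbs naturally.

#' Construct an SEMG signal tibble
#'
#' @param values Numeric vector of samples in millivolts.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `semg_signal` with columns `time_s` and
#'   `value_mV` and attribute `fs`.
#' @export
#' @examples
#' s <- semg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1e-3)), fs = 1000)
#' semg_fs(s)
semg_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  stopifnot(is.numeric(fs), fs > 0)
  out <- tibble::tibble(
    time_s = t0 + (seq_along(values) - 1) / fs,
    value_mV = values
  )
  class(out) <- c("semg_signal", class(out))
  attr(out, "fs") <- fs
  out
}

#' Sampling rate of an SEMG signal
#' @param x A `semg_signal`.
#' @return Sampling rate in Hz.
#' @export
semg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) rlang::abort("object carries no sampling rate")
  fs
}

# accept either a semg_signal tibble or a bare numeric vector
.signal_values <- function(x) {
  if (inherits(x, "semg_signal") || (is.data.frame(x) && "value_mV" %in% names(x))) {
    as.numeric(x$value_mV)
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    rlang::abort("expected a semg_signal tibble or a numeric vector")
  }
}

.signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  if (!is.null(attr(x, "fs"))) return(attr(x, "fs"))
  rlang::abort("sampling rate not supplied and not carried by the object")
}

#' Write / read an SEMG signal as CSV
#'
#' The CSV has columns `time_s` and `value_mV`; the sampling rate is
#' recovered on read from the time column spacing.
#'
#' @param x A `semg_signal`.
#' @param path File path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a `semg_signal`.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("time_s", "value_mV") %in% names(x)))
  utils::write.csv(as.data.frame(x)[, c("time_s", "value_mV")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value_mV") %in% names(df)))
  dt <- stats::median(diff(df$time_s))
  semg_signal(df$value_mV, fs = 1 / dt, t0 = df$time_s[1])
}
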