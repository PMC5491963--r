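# broom-style tidiers and re-exported generics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a time-frequency matrix into a long tibble
#'
#' @param x A `tg_tfr`.
#' @param drop_invalid Drop edge samples flagged invalid per frequency.
#' @param ... Unused.
#' @return A tibble with columns `freq_hz`, `time_s`, `power`.
#' @export
tidy.tg_tfr <- function(x, drop_invalid = TRUE, ...) {
  nt <- length(x$times)
  rows <- purrr::map(seq_along(x$freqs), function(i) {
    v <- if (drop_invalid) tfr_valid_idx(x, i) else seq_len(nt)
    tibble::tibble(freq_hz = x$freqs[i], time_s = x$times[v],
                   power = x$power[i, v])
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a time-frequency matrix
#'
#' @param x A `tg_tfr`.
#' @param ... Unused.
#' @return A one-row tibble: grid sizes, frequency and time ranges,
#'   normalization state, trigger count (NA unless trigger-averaged).
#' @export
glance.tg_tfr <- function(x, ...) {
  tibble::tibble(
    n_freqs = length(x$freqs),
    n_times = length(x$times),
    freq_min_hz = min(x$freqs),
    freq_max_hz = max(x$freqs),
    time_min_s = min(x$times),
    time_max_s = max(x$times),
    normalized = isTRUE(x$normalized),
    n_triggers = x$n_triggers %||% NA_integer_
  )
}
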