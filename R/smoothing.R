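#' Causal Savitzky-Golay smoother for the baseline stream
#'
#' Creates the state of an online smoother for the per-minute raw baseline
#' estimates produced by the recognition model. The smoother fits a
#' polynomial of order `poly_order` to the trailing `window_length` values
#' and evaluates the fit at the newest point. This is the causal variant of
#' Savitzky-Golay filtering: a centered filter would need future samples,
#' which a controller does not have, so the endpoint fit is used instead
#' (the last row of the Savitzky-Golay projection matrix).
#'
#' During warm-up, while fewer than `window_length` values have been seen,
#' the running mean of the buffer is returned as a documented fallback.
#'
#' @param window_length odd number of trailing points fitted (minutes of
#'   baseline history); default 15.
#' @param poly_order polynomial order, strictly less than `window_length`;
#'   default 2.
#' @return an object of class `sg_smoother`.
#' @export
sg_smoother <- function(window_length = 15L, poly_order = 2L) {
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length < 3L || window_length %% 2L == 0L)
    stop("'window_length' must be an odd integer >= 3", call. = FALSE)
  if (poly_order < 0L || poly_order >= window_length)
    stop("'poly_order' must be non-negative and < window_length",
         call. = FALSE)
  sg <- signal::sgolay(p = poly_order, n = window_length)
  coef <- as.numeric(sg[window_length, ])  # endpoint (newest-sample) fit
  structure(list(window_length = window_length, poly_order = poly_order,
                 coef = coef, buffer = numeric(0)),
            class = "sg_smoother")
}

#' Advance the smoother by one raw baseline value
#'
#' @param state an [sg_smoother()] state.
#' @param raw_baseline newest raw baseline estimate (\%DO, finite).
#' @return a list with `state` (updated smoother) and `value` (the smoothed
#'   baseline, \%DO).
#' @export
smooth_update <- function(state, raw_baseline) {
  stopifnot(inherits(state, "sg_smoother"))
  if (!is.numeric(raw_baseline) || length(raw_baseline) != 1L ||
      !is.finite(raw_baseline))
    stop("'raw_baseline' must be a single finite number", call. = FALSE)
  buf <- c(state$buffer, raw_baseline)
  if (length(buf) > state$window_length)
    buf <- buf[(length(buf) - state$window_length + 1L):length(buf)]
  state$buffer <- buf
  value <- if (length(buf) < state$window_length) mean(buf)
           else sum(state$coef * buf)
  list(state = state, value = value)
}

#' Smooth a whole vector through the causal filter
#'
#' Convenience wrapper that streams `x` through [smooth_update()] and
#' returns the smoothed sequence, e.g. for offline recognition of a recorded
#' DO trace.
#'
#' @param x numeric vector of raw baseline values.
#' @param state an [sg_smoother()] state (fresh by default).
#' @return numeric vector of smoothed values, same length as `x`.
#' @export
smooth_stream <- function(x, state = sg_smoother()) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    upd <- smooth_update(state, x[i])
    state <- upd$state
    out[i] <- upd$value
  }
  out
}
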