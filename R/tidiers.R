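#' Tidy a fitted staining-kinetics model
#'
#' @param x A `kinetics_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `part`, `unit`.
#' @export
tidy.kinetics_fit <- function(x, ...) {
  if (is.null(x$model)) return(tibble::tibble(term = character(),
                                              estimate = numeric()))
  m <- x$model
  tibble::tibble(
    term = c("Q",
             paste0("decay_tau", seq_along(m$decay_taus)),
             paste0("decay_w", seq_along(m$decay_weights)),
             paste0("assoc_tau", seq_along(m$assoc_taus)),
             paste0("assoc_w", seq_along(m$assoc_weights))),
    estimate = c(x$Q, m$decay_taus, m$decay_weights, m$assoc_taus,
                 m$assoc_weights),
    part = c("amplitude",
             rep("decay", length(m$decay_taus) + length(m$decay_weights)),
             rep("association", length(m$assoc_taus) + length(m$assoc_weights))),
    unit = c("signal", rep(m$time_unit, length(m$decay_taus)),
             rep("", length(m$decay_weights)),
             rep(m$time_unit, length(m$assoc_taus)),
             rep("", length(m$assoc_weights)))
  )
}

#' @rdname tidy.kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = x$n,
                 sigma = if (is.finite(x$rss)) sqrt(x$rss / x$n) else NA_real_)
}

#' Tidy a 2D Gaussian spot fit
#'
#' @param x A `gaussian_fit` from [fit_dss_gaussian()].
#' @param ... Unused.
#' @return A one-row tibble: `fitted`, `x`, `y`, `height`, `sigma_x`,
#'   `sigma_y`, `offset`.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  f <- unclass(x)
  tibble::tibble(fitted = f$fitted, x = f$x, y = f$y, height = f$height,
                 sigma_x = f$sigma_x, sigma_y = f$sigma_y, offset = f$offset)
}

#' @rdname tidy.gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, reason = x$reason)
}
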