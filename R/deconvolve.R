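#' Forward staining-kinetics convolution
#'
#' Predicts the cumulative secretion signal (CSS) produced by a train of
#' per-bin release amounts (a DSS train). Release in bin `i` (covering the
#' interval `[i*dt, (i+1)*dt)`) contributes `A((k - i + 1) * dt)` to the CSS
#' observed at the end of bin `k`, so the CSS at bin `k` is the causal
#' convolution
#' \deqn{CSS_k = \sum_{i \le k} DSS_i\, A\big((k - i + 1)\,\Delta t\big).}
#' This is the simulation forward model and the oracle the deconvolution
#' recursion inverts.
#'
#' @param dss Non-negative numeric vector of per-bin release amounts.
#' @param model An [ab_kinetics] staining-kinetics model.
#' @param dt_time Width of one bin in `model$time_unit` (frame interval times
#'   the number of frames per bin).
#' @param time_unit Optional unit check against the model.
#' @return Numeric CSS vector, one value per bin end (same length as `dss`).
#' @export
forward_convolve <- function(dss, model, dt_time, time_unit = NULL) {
  stopifnot(inherits(model, "ab_kinetics"))
  if (any(dss < 0)) abort("DSS release amounts must be non-negative")
  if (dt_time <= 0) abort("dt_time must be positive")
  n <- length(dss)
  if (n == 0) return(numeric(0))
  A <- eval_kinetics(model, (1:n) * dt_time, time_unit = time_unit)
  css <- numeric(n)
  for (k in seq_len(n)) {
    css[k] <- sum(dss[1:k] * A[k:1])
  }
  css
}

#' Temporal deconvolution of a cumulative secretion signal
#'
#' Inverts the staining-kinetics convolution to recover per-bin release
#' amounts (the deconvoluted secretion signal, DSS) from a CSS trace. On the
#' binned grid the recursion is
#' \deqn{DSS_k = \Big(CSS_k - \sum_{i < k} DSS_i\,
#'   A\big((k - i + 1)\Delta t\big)\Big) / A(\Delta t),}
#' evaluated bin by bin. Negative intermediate values are clamped to 0
#' (secretion activity cannot be negative) and the clamped value enters all
#' subsequent history sums. An optional non-negative least squares solve over
#' the whole trace is available as a cross-check (`method = "nnls"`).
#'
#' @param css Numeric per-frame CSS trace (baseline-subtracted, so the signal
#'   at the start of observation is 0).
#' @param model An [ab_kinetics] model.
#' @param dt_frames Frames per deconvolution bin (default 5, the standard
#'   time resolution).
#' @param frame_interval Frame interval in `time_unit` (default 1).
#' @param time_unit Unit of `frame_interval`; must match the model.
#' @param method `"recursive"` (the standard bin-by-bin inversion) or
#'   `"nnls"` (whole-trace non-negative least squares via bounded
#'   Levenberg-Marquardt).
#' @return A tibble with columns `bin` (0-based), `time` (end of bin), `dss`,
#'   `clamped`. Attribute `clamped_mass` holds the total negative mass that
#'   was clamped.
#' @export
deconvolve_css <- function(css, model, dt_frames = 5, frame_interval = 1,
                           time_unit = NULL,
                           method = c("recursive", "nnls")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ab_kinetics"))
  if (!all(is.finite(css))) abort("CSS values must be finite")
  if (length(css) < 2) abort("CSS trace must have length >= 2")
  dt_time <- dt_frames * frame_interval
  n <- floor(length(css) / dt_frames)
  if (n < 1) abort("CSS trace shorter than one bin")
  cssb <- css[(1:n) * dt_frames]
  A <- eval_kinetics(model, (1:n) * dt_time, time_unit = time_unit)
  if (A[1] < 1e-12) {
    abort("A(dt) is numerically zero: staining kinetics too slow for this bin width")
  }
  if (method == "recursive") {
    dss <- numeric(n)
    clamped <- logical(n)
    clamped_mass <- 0
    for (k in seq_len(n)) {
      hist_sum <- if (k > 1) sum(dss[1:(k - 1)] * A[k:2]) else 0
      v <- (cssb[k] - hist_sum) / A[1]
      if (v < 0) {
        clamped[k] <- TRUE
        clamped_mass <- clamped_mass - v
        v <- 0
      }
      dss[k] <- v
    }
  } else {
    # design matrix of the forward model; bounded LM solve enforces dss >= 0
    G <- matrix(0, n, n)
    for (k in seq_len(n)) G[k, 1:k] <- A[k:1]
    fit <- minpack.lm::nls.lm(
      par = pmax(0, solve(G, cssb)),
      lower = rep(0, n),
      fn = function(p) cssb - as.vector(G %*% p)
    )
    dss <- pmax(0, coef(fit))
    clamped <- dss == 0 & cssb > 0
    clamped_mass <- NA_real_
  }
  out <- tibble::tibble(
    bin = 0:(n - 1),
    time = (1:n) * dt_time,
    dss = dss,
    clamped = clamped
  )
  attr(out, "clamped_mass") <- clamped_mass
  attr(out, "dt_time") <- dt_time
  attr(out, "time_unit") <- model$time_unit
  out
}

#' Compensate IL-13 signal for cross-reaction with captured IL-5
#'
#' The anti-IL-13 detection antibody binds captured IL-5 immunocomplexes,
#' adding a spurious cross-signal to the raw IL-13 fluorescence. Given the
#' deconvolved IL-5 release train, the cross-signal at bin `k` is
#' \deqn{X_k = \sum_{i \le k} DSS^{IL5}_i\, \chi\big((k-i+1)\Delta t\big)}
#' and the corrected CSS is `FI - X`, floored at 0 (consistent with DSS
#' clamping). The corrected CSS is then deconvolved with the IL-13 kernel.
#'
#' @param fi_il13 Raw per-bin IL-13 fluorescence trace (baseline-subtracted),
#'   on the same bin grid as `dss_il5`.
#' @param dss_il5 Per-bin IL-5 release train (numeric vector, or the tibble
#'   returned by [deconvolve_css()]).
#' @param kernel A [crosstalk_kernel].
#' @param dt_time Bin width in hours.
#' @return Corrected CSS vector with attribute `cross_signal`.
#' @export
compensate_crosstalk <- function(fi_il13, dss_il5, kernel, dt_time) {
  stopifnot(inherits(kernel, "crosstalk_kernel"))
  if (is.data.frame(dss_il5)) dss_il5 <- dss_il5$dss
  n <- length(fi_il13)
  if (length(dss_il5) != n) {
    abort("IL-13 trace and IL-5 DSS train must share the bin grid")
  }
  chi <- eval_crosstalk(kernel, (1:n) * dt_time)
  X <- numeric(n)
  for (k in seq_len(n)) X[k] <- sum(dss_il5[1:k] * chi[k:1])
  out <- pmax(0, fi_il13 - X)
  attr(out, "cross_signal") <- X
  out
}

#' Smooth a release train for calling and display
#'
#' The release train is already temporally integrated over its bin width by
#' the deconvolution grid; this applies the complementary moving median
#' (window shrinking symmetrically at the edges, so no signal is fabricated
#' at the boundaries) to reject the impulsive processing noise the recursion
#' amplifies. A single-bin spike below the median of its neighbours is
#' removed while plateaus pass unchanged. Intended for positivity calling and
#' visualization only -- never re-deconvolve a smoothed trace.
#'
#' @param dss Numeric per-bin release train.
#' @param window Odd moving-median window in bins (default 5).
#' @return Smoothed numeric vector, same length.
#' @export
smooth_dss <- function(dss, window = 5) {
  if (window %% 2 != 1) abort("window must be odd")
  n <- length(dss)
  if (n == 0) return(dss)
  pmax(0, moving_median(dss, window))
}

# moving median with symmetric shrink at the edges (no padding)
moving_median <- function(x, window) {
  n <- length(x)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    median(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Deconvolve a table of well CSS traces
#'
#' Applies [deconvolve_css()] per well and channel of a tidy CSS table, with
#' optional IL-13 cross-talk compensation (the IL-5 channel is deconvolved
#' first, its release train drives the cross-signal subtracted from the
#' IL-13 channel).
#'
#' @param css_tbl Tibble with columns `well_id`, `channel`, `frame`, `css`
#'   (e.g. from [subtract_baseline()]).
#' @param kinetics Named list mapping each channel to an [ab_kinetics].
#' @param crosstalk Optional [crosstalk_kernel]; when supplied together with
#'   channels `"IL5"` and `"IL13"`, the IL-13 channel is compensated before
#'   deconvolution.
#' @param dt_frames,frame_interval,time_unit As in [deconvolve_css()].
#' @return Tibble with columns `well_id`, `channel`, `bin`, `time`, `dss`,
#'   `clamped`.
#' @export
deconvolve_wells <- function(css_tbl, kinetics, crosstalk = NULL,
                             dt_frames = 5, frame_interval = 1,
                             time_unit = NULL) {
  stopifnot(all(c("well_id", "channel", "frame", "css") %in% names(css_tbl)))
  channels <- unique(css_tbl$channel)
  missing_k <- setdiff(channels, names(kinetics))
  if (length(missing_k)) {
    abort(sprintf("no kinetics calibration for channel(s): %s",
                  paste(missing_k, collapse = ", ")))
  }
  css_tbl <- dplyr::arrange(css_tbl, .data$well_id, .data$channel, .data$frame)

  dec_one <- function(values, model) {
    deconvolve_css(values, model, dt_frames = dt_frames,
                   frame_interval = frame_interval, time_unit = time_unit)
  }

  # IL-5 first so its release train can drive cross-talk compensation
  ordered_channels <- c(intersect("IL5", channels), setdiff(channels, "IL5"))
  out <- list()
  il5_dss <- NULL
  for (ch in ordered_channels) {
    sub <- dplyr::filter(css_tbl, .data$channel == ch)
    res <- sub |>
      dplyr::group_by(.data$well_id) |>
      dplyr::group_modify(function(d, key) {
        dec_one(d$css, kinetics[[ch]])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(channel = ch, .after = "well_id")
    if (ch == "IL13" && !is.null(crosstalk) && !is.null(il5_dss)) {
      dt_time <- dt_frames * frame_interval
      res <- sub |>
        dplyr::group_by(.data$well_id) |>
        dplyr::group_modify(function(d, key) {
          n <- floor(length(d$css) / dt_frames)
          fib <- d$css[(1:n) * dt_frames]
          d5 <- il5_dss$dss[il5_dss$well_id == key$well_id]
          corrected <- compensate_crosstalk(fib, d5, crosstalk, dt_time)
          # corrected CSS is on the bin grid; deconvolve with dt_frames = 1
          deconvolve_css(as.numeric(corrected), kinetics[[ch]],
                         dt_frames = 1, frame_interval = dt_time,
                         time_unit = time_unit)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(channel = ch, .after = "well_id")
    }
    if (ch == "IL5") il5_dss <- res
    out[[ch]] <- res
  }
  dplyr::bind_rows(out)
}
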