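#' Fit a 2D Gaussian to a secretion-signal image
#'
#' Models a deconvolved secretion-signal (DSS) image as a single elliptical
#' Gaussian plus a constant offset,
#' `z = b + h * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2)))`,
#' fitted by Levenberg-Marquardt least squares. Localization is only
#' meaningful when the spot is clearly above the noise floor, so images whose
#' peak (max minus median) falls below `min_peak` return a below-threshold
#' verdict instead of a fit.
#'
#' @param image 2D numeric matrix (rows = y, columns = x).
#' @param pixel_size Pixel size in micrometres (default 1).
#' @param min_peak Minimum peak amplitude (signal units) for a fit to be
#'   attempted; a natural default is 3x the robust SD of the empty-well DSS
#'   noise floor.
#' @return A `gaussian_fit` object with fields `fitted` (logical), `x`, `y`
#'   (centre, micrometres), `height`, `sigma_x`, `sigma_y`, `offset`, `rss`,
#'   `converged`, `reason`. [tidy()] and [glance()] methods are provided.
#' @export
fit_dss_gaussian <- function(image, pixel_size = 1, min_peak = 0) {
  stopifnot(is.matrix(image))
  peak <- max(image) - median(image)
  below <- structure(
    list(fitted = FALSE, x = NA_real_, y = NA_real_, height = NA_real_,
         sigma_x = NA_real_, sigma_y = NA_real_, offset = NA_real_,
         rss = NA_real_, converged = FALSE, reason = "below_threshold",
         pixel_size = pixel_size),
    class = "gaussian_fit")
  if (!is.finite(peak) || peak < min_peak || peak == 0) return(below)

  ny <- nrow(image); nx <- ncol(image)
  xs <- rep((seq_len(nx) - 0.5) * pixel_size, each = ny)
  ys <- rep((seq_len(ny) - 0.5) * pixel_size, times = nx)
  z <- as.vector(image)
  imax <- which.max(z)
  p0 <- c(x0 = xs[imax], y0 = ys[imax],
          lh = log(peak), b = median(z),
          lsx = log(nx * pixel_size / 8), lsy = log(ny * pixel_size / 8))
  model <- function(p) {
    p["b"] + exp(p["lh"]) *
      exp(-((xs - p["x0"])^2 / (2 * exp(2 * p["lsx"])) +
            (ys - p["y0"])^2 / (2 * exp(2 * p["lsy"]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) z - model(setNames(p, names(p0))),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    below$reason <- "fit_failed"
    return(below)
  }
  p <- setNames(coef(fit), names(p0))
  width <- c(nx, ny) * pixel_size
  if (p["x0"] < -exp(p["lsx"]) || p["x0"] > width[1] + exp(p["lsx"]) ||
      p["y0"] < -exp(p["lsy"]) || p["y0"] > width[2] + exp(p["lsy"])) {
    below$reason <- "centre_out_of_bounds"
    return(below)
  }
  structure(
    list(fitted = TRUE, x = unname(p["x0"]), y = unname(p["y0"]),
         height = exp(unname(p["lh"])),
         sigma_x = exp(unname(p["lsx"])), sigma_y = exp(unname(p["lsy"])),
         offset = unname(p["b"]), rss = sum(fit$fvec^2),
         converged = fit$info %in% 1:3, reason = NA_character_,
         pixel_size = pixel_size),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$fitted) {
    cat("<gaussian_fit> no fit:", x$reason, "\n")
  } else {
    cat(sprintf("<gaussian_fit> centre (%.2f, %.2f) um, height %.3g, sigma (%.2f, %.2f) um\n",
                x$x, x$y, x$height, x$sigma_x, x$sigma_y))
  }
  invisible(x)
}

#' Cell centroid from a label mask
#'
#' Geometric centroid and area of each labelled cell in a mask image.
#'
#' @param mask Integer matrix; 0 = background, positive integers label cells.
#' @param pixel_size Pixel size in micrometres.
#' @return Tibble `label`, `x`, `y` (micrometres), `area` (square
#'   micrometres).
#' @export
mask_centroids <- function(mask, pixel_size = 1) {
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  ny <- nrow(mask); nx <- ncol(mask)
  xs <- matrix(rep((seq_len(nx) - 0.5), each = ny), ny, nx)
  ys <- matrix(rep((seq_len(ny) - 0.5), times = nx), ny, nx)
  purrr::map_dfr(labs, function(l) {
    sel <- mask == l
    tibble::tibble(label = l,
                   x = mean(xs[sel]) * pixel_size,
                   y = mean(ys[sel]) * pixel_size,
                   area = sum(sel) * pixel_size^2)
  })
}

#' Displacement between secretion spots and the cell
#'
#' Per-frame Euclidean distance between the fitted DSS spot centre and the
#' tracked cell centroid; frames without a valid fit are dropped. The
#' intensity-distance pairs support checking that brighter spots localize
#' closer to the cell.
#'
#' @param fits Tibble with columns `frame`, `x`, `y`, `height`, `fitted`
#'   (e.g. one [fit_dss_gaussian()] row per frame, see [tidy.gaussian_fit()]).
#' @param track Tibble with columns `frame`, `x`, `y` (cell centroid,
#'   micrometres).
#' @return A `qlcis_displacement` tibble `frame`, `distance`, `height`.
#'   [displacement_summary()] reduces it to median and quartiles.
#' @export
displacement_series <- function(fits, track) {
  stopifnot(all(c("frame", "x", "y") %in% names(fits)),
            all(c("frame", "x", "y") %in% names(track)))
  if ("fitted" %in% names(fits)) fits <- dplyr::filter(fits, .data$fitted)
  joined <- dplyr::inner_join(fits, track, by = "frame",
                              suffix = c("_spot", "_cell"))
  out <- tibble::tibble(
    frame = joined$frame,
    distance = sqrt((joined$x_spot - joined$x_cell)^2 +
                    (joined$y_spot - joined$y_cell)^2),
    height = if ("height" %in% names(joined)) joined$height else NA_real_
  )
  class(out) <- c("qlcis_displacement", class(out))
  out
}

#' @rdname displacement_series
#' @param displacements A `qlcis_displacement` tibble.
#' @export
displacement_summary <- function(displacements) {
  if (!nrow(displacements)) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, reason = "no valid fits"))
  }
  tibble::tibble(
    n = nrow(displacements),
    median = median(displacements$distance),
    q1 = unname(quantile(displacements$distance, 0.25)),
    q3 = unname(quantile(displacements$distance, 0.75)),
    reason = NA_character_
  )
}
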