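#' Robust standard deviation from empty wells
#'
#' Estimates the noise SD of the detection channel from the intensities of
#' empty wells (wells containing no cell) as 1.4826 times the median absolute
#' deviation, which is consistent for the SD under Gaussian noise and immune
#' to the occasional contaminated well.
#'
#' @param x Numeric vector of empty-well intensities (>= 5 values).
#' @return The robust SD. If the MAD is exactly zero the value 0 is returned
#'   with attribute `degenerate = TRUE`; callers must refuse to call
#'   positivity against a degenerate threshold.
#' @examples
#' robust_sd(c(1, 2, 3, 4, 5)) # exactly 1.4826
#' @export
robust_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) abort("need >= 5 finite values to estimate a robust SD")
  s <- 1.4826 * median(abs(x - median(x)))
  attr(s, "degenerate") <- s == 0
  s
}

#' Detection thresholds for secretion calling
#'
#' @param sigma Robust SD of the empty-well intensities (see [robust_sd()]).
#' @param detect_mult Multiplier for the detection limit (default 3).
#' @param hyper_mult Multiplier for the hyperactive limit (default 50).
#' @return A `threshold_set` list: `sigma`, `detect` (= 3 sigma),
#'   `hyper` (= 50 sigma).
#' @export
threshold_set <- function(sigma, detect_mult = 3, hyper_mult = 50) {
  if (isTRUE(attr(sigma, "degenerate"))) {
    abort("degenerate (zero) robust SD: cannot form thresholds")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  structure(list(sigma = as.numeric(sigma),
                 detect = detect_mult * as.numeric(sigma),
                 hyper = hyper_mult * as.numeric(sigma)),
            class = "threshold_set")
}

#' Call secretion positivity on a single trace
#'
#' A trajectory is positive when it stays above the detection threshold for
#' at least `min_run` consecutive frames; once such a run is confirmed,
#' transient falls below the threshold of up to `max_gap` frames do not
#' terminate the episode (the cumulative signal is continuous in time, so
#' short dips are measurement noise). A run shorter than `min_run` that never
#' reaches confirmation is discarded and does not seed an episode.
#'
#' @param values Numeric trace (typically a baseline-subtracted CSS).
#' @param threshold Detection limit (typically `3 * sigma`).
#' @param min_run Minimum consecutive supra-threshold frames to confirm
#'   (default 2).
#' @param max_gap Maximum tolerated sub-threshold gap inside a confirmed
#'   episode, in frames (default 3).
#' @return A list: `positive`, `onset` (index of the first frame of the first
#'   confirmed episode, `NA` if negative), `episodes` (tibble with `start`,
#'   `end`), `insufficient_data`.
#' @export
call_positive <- function(values, threshold, min_run = 2, max_gap = 3) {
  n <- length(values)
  if (n < min_run) {
    return(list(positive = FALSE, onset = NA_integer_,
                episodes = tibble::tibble(start = integer(), end = integer()),
                insufficient_data = TRUE))
  }
  supra <- values > threshold
  state <- "idle"
  run_len <- 0L
  run_start <- NA_integer_
  ep_start <- NA_integer_
  last_supra <- NA_integer_
  gap <- 0L
  eps <- list()
  close_ep <- function() {
    eps[[length(eps) + 1L]] <<- c(ep_start, last_supra)
  }
  for (i in seq_len(n)) {
    if (state == "idle") {
      if (supra[i]) {
        run_start <- i
        run_len <- 1L
        state <- "candidate"
        if (run_len >= min_run) {
          state <- "confirmed"; ep_start <- run_start; last_supra <- i; gap <- 0L
        }
      }
    } else if (state == "candidate") {
      if (supra[i]) {
        run_len <- run_len + 1L
        if (run_len >= min_run) {
          state <- "confirmed"; ep_start <- run_start; last_supra <- i; gap <- 0L
        }
      } else {
        state <- "idle"
      }
    } else { # confirmed
      if (supra[i]) {
        last_supra <- i
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > max_gap) {
          close_ep()
          state <- "idle"
        }
      }
    }
  }
  if (state == "confirmed") close_ep()
  episodes <- if (length(eps)) {
    tibble::tibble(start = vapply(eps, `[`, 0L, 1),
                   end = vapply(eps, `[`, 0L, 2))
  } else {
    tibble::tibble(start = integer(), end = integer())
  }
  list(positive = nrow(episodes) > 0,
       onset = if (nrow(episodes)) episodes$start[1] else NA_integer_,
       episodes = episodes,
       insufficient_data = FALSE)
}

#' Classify secretory activity of a well
#'
#' Silent if not positive; hyperactive if positive and the maximum CSS
#' reaches 50 times the robust SD (the threshold that matches a k-means
#' split of positive wells); slightly active otherwise.
#'
#' @param positive Logical positivity flag.
#' @param max_css Maximum baseline-subtracted CSS over the trace.
#' @param thresholds A [threshold_set()].
#' @return One of `"silent"`, `"slightly_active"`, `"hyperactive"`.
#' @export
classify_activity <- function(positive, max_css, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  dplyr::case_when(
    !positive ~ "silent",
    max_css >= thresholds$hyper ~ "hyperactive",
    .default = "slightly_active"
  )
}

#' Call and classify secretion for a table of wells
#'
#' Runs the positivity state machine per (well, channel) and classifies each
#' well. A well is active if positive in either channel; its class is taken
#' from the channel with the largest `max_css / sigma` ratio, so hyperactive
#' in one channel dominates.
#'
#' @param css_tbl Tibble with `well_id`, `channel`, `frame`, `time`, `css`.
#' @param thresholds Either a single [threshold_set()] applied to every
#'   channel or a named list keyed by channel.
#' @param min_run,max_gap See [call_positive()].
#' @return A `qlcis_calls` tibble, one row per (well, channel): `well_id`,
#'   `channel`, `positive`, `onset_frame`, `onset_time`, `max_css`,
#'   `n_episodes`, `class` (the combined per-well class, repeated across the
#'   well's channels).
#' @export
call_secretion <- function(css_tbl, thresholds, min_run = 2, max_gap = 3) {
  stopifnot(all(c("well_id", "channel", "frame", "css") %in% names(css_tbl)))
  if (inherits(thresholds, "threshold_set")) {
    thresholds <- setNames(
      rep(list(thresholds), length(unique(css_tbl$channel))),
      unique(css_tbl$channel)
    )
  }
  has_time <- "time" %in% names(css_tbl)
  per <- css_tbl |>
    dplyr::arrange(.data$well_id, .data$channel, .data$frame) |>
    dplyr::group_by(.data$well_id, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      th <- thresholds[[key$channel]]
      if (is.null(th)) abort(sprintf("no thresholds for channel '%s'", key$channel))
      cp <- call_positive(d$css, th$detect, min_run = min_run, max_gap = max_gap)
      tibble::tibble(
        positive = cp$positive,
        onset_frame = if (cp$positive) d$frame[cp$onset] else NA_integer_,
        onset_time = if (has_time && cp$positive) d$time[cp$onset] else NA_real_,
        max_css = max(d$css),
        n_episodes = nrow(cp$episodes),
        sigma_ratio = max(d$css) / th$sigma,
        class_channel = classify_activity(cp$positive, max(d$css), th)
      )
    }) |>
    dplyr::ungroup()

  combined <- per |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(
      class = if (!any(.data$positive)) "silent"
              else .data$class_channel[.data$positive][
                which.max(.data$sigma_ratio[.data$positive])],
      .groups = "drop"
    )
  out <- per |>
    dplyr::select(-"class_channel", -"sigma_ratio") |>
    dplyr::left_join(combined, by = "well_id")
  class(out) <- c("qlcis_calls", class(out))
  out
}

#' k-means concordance check for the hyperactive threshold
#'
#' Splits the positive wells into two groups by k-means (k = 2, best of 10
#' restarts) on log10 maximum CSS and reports the concordance of that split
#' with the 50-sigma rule. The 50-sigma threshold remains authoritative; this
#' is a reported consistency check only.
#'
#' @param calls A `qlcis_calls` tibble from [call_secretion()].
#' @param thresholds A [threshold_set()].
#' @return A list: `concordance` (fraction of positive wells on which the two
#'   rules agree), `centers` (k-means centers on the log10 scale), `boundary`
#'   (midpoint between centers, back-transformed).
#' @export
kmeans_activity_check <- function(calls, thresholds) {
  pos <- calls |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(max_css = max(.data$max_css), class = .data$class[1],
                     .groups = "drop") |>
    dplyr::filter(.data$class != "silent", .data$max_css > 0)
  if (nrow(pos) < 4) abort("need >= 4 positive wells for a 2-group split")
  lx <- log10(pos$max_css)
  km <- kmeans(lx, centers = 2, nstart = 10)
  hi_cluster <- which.max(km$centers)
  km_hyper <- km$cluster == hi_cluster
  rule_hyper <- pos$class == "hyperactive"
  list(concordance = mean(km_hyper == rule_hyper),
       centers = sort(as.numeric(km$centers)),
       boundary = 10^mean(km$centers))
}

#' Cumulative activation curve
#'
#' Fraction of wells that have started secreting as a function of time, with
#' right-censoring of never-positive wells at the observation horizon;
#' bookkeeping (numbers at risk, events) supports log-rank comparisons.
#'
#' @param calls A `qlcis_calls` tibble (or any tibble with `well_id`,
#'   `positive`, `onset_time`); per-well onset is the earliest across
#'   channels.
#' @param horizon Censoring time for non-positive wells.
#' @return A `qlcis_activation` tibble: `time`, `n_risk`, `n_event`,
#'   `fraction_active`. Attribute `surv_data` holds the per-well
#'   (time, event) frame used.
#' @export
activation_curve <- function(calls, horizon) {
  if (!nrow(calls)) abort("no calls supplied")
  per_well <- calls |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(
      event = any(.data$positive),
      time = if (any(.data$positive)) min(.data$onset_time[.data$positive], na.rm = TRUE)
             else .env$horizon,
      .groups = "drop"
    )
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = per_well)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    fraction_active = 1 - fit$surv
  )
  attr(out, "surv_data") <- per_well
  class(out) <- c("qlcis_activation", class(out))
  out
}

#' Compare groups of wells
#'
#' Pairwise comparisons between groups with either the Mann-Whitney test (on
#' a per-well value such as maximum CSS) or the log-rank test (on activation
#' times with censoring), with Benjamini-Hochberg control of the false
#' discovery rate across the family of pairwise comparisons.
#'
#' @param data A data frame with a grouping column and either a value column
#'   (Mann-Whitney) or time + event columns (log-rank).
#' @param group Name of the grouping column.
#' @param value Name of the value column (Mann-Whitney).
#' @param time,event Names of the time and event-indicator columns (log-rank).
#' @param method `"mannwhitney"` or `"logrank"`.
#' @return A tibble with one row per pairwise comparison: `group1`, `group2`,
#'   `n1`, `n2`, `statistic`, `p.value`, `p.adjust` (BH), `signif`
#'   (`***` < 0.001, `**` < 0.01, `*` < 0.05, `ns`).
#' @export
compare_groups <- function(data, group, value = NULL, time = NULL, event = NULL,
                           method = c("mannwhitney", "logrank")) {
  method <- match.arg(method)
  g <- factor(data[[group]])
  levs <- levels(g)
  if (length(levs) < 2) abort("need at least two groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    sub <- data[g %in% pr, , drop = FALSE]
    gs <- droplevels(factor(sub[[group]], levels = pr))
    n1 <- sum(gs == pr[1]); n2 <- sum(gs == pr[2])
    if (n1 < 2 || n2 < 2) abort("need >= 2 observations per group")
    if (method == "mannwhitney") {
      x <- sub[[value]][gs == pr[1]]
      y <- sub[[value]][gs == pr[2]]
      if (length(unique(c(x, y))) == 1) {
        warn("all observations tied; p = 1")
        stat <- n1 * n2 / 2
        p <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
        stat <- unname(wt$statistic)
        p <- wt$p.value
      }
    } else {
      sd_fit <- survival::survdiff(
        survival::Surv(sub[[time]], sub[[event]]) ~ gs
      )
      stat <- sd_fit$chisq
      p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
      if (stat < 1e-12) p <- 1
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2], n1 = n1, n2 = n2,
                   statistic = stat, p.value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p.adjust <- p.adjust(out$p.value, method = "BH")
  out$signif <- dplyr::case_when(
    out$p.adjust < 0.001 ~ "***",
    out$p.adjust < 0.01 ~ "**",
    out$p.adjust < 0.05 ~ "*",
    .default = "ns"
  )
  out
}
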