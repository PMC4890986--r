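#' Convert absorbance at 400 nm to turbidity
#'
#' Gel-formation kinetics are recorded as absorbance at 400 nm; turbidity is
#' obtained by multiplying raw absorbance by the conventional factor 2.303
#' (the base-10 to natural-log conversion, used verbatim as the printed
#' constant).
#'
#' @param absorbance numeric vector of raw absorbance readings.
#' @return numeric vector of turbidity values, `2.303 * absorbance`.
#' @examples
#' absorbance_to_turbidity(1.0)   # 2.303
#' @export
absorbance_to_turbidity <- function(absorbance) {
  stopifnot(is.numeric(absorbance), all(is.finite(absorbance)))
  2.303 * absorbance
}

#' Build a turbidity curve from time/absorbance records
#'
#' @param data data frame with columns `time_min` and `absorbance` (and
#'   optionally `turbidity`, which is recomputed).
#' @return a `turbidity_curve` tibble with `time_min`, `absorbance`,
#'   `turbidity`.
#' @export
as_turbidity_curve <- function(data) {
  stopifnot(all(c("time_min", "absorbance") %in% names(data)))
  if (is.unsorted(data$time_min, strictly = TRUE)) {
    abort("time_min must be strictly increasing")
  }
  out <- tibble(
    time_min = as.numeric(data$time_min),
    absorbance = as.numeric(data$absorbance),
    turbidity = absorbance_to_turbidity(as.numeric(data$absorbance))
  )
  class(out) <- c("turbidity_curve", class(out))
  out
}

logistic_tau <- function(t, tau_max, rate, t_half) {
  tau_max / (1 + exp(-rate * (t - t_half)))
}

#' Fit the logistic gelation model to a turbidity curve
#'
#' Collagen fibrillogenesis monitored by turbidity follows a sigmoid with a
#' lag phase, an exponential growth phase and a plateau. This fits
#' \deqn{\tau(t) = \tau_{max} / (1 + e^{-r (t - t_{1/2})})}
#' by nonlinear least squares (Levenberg–Marquardt, up to 5 jittered
#' restarts) and derives the phase descriptors:
#'
#' * `lag_time` — earliest observed time with \eqn{\tau \ge 0.10\,\hat\tau_{max}};
#' * `time_to_plateau` — earliest observed time with \eqn{\tau \ge 0.95\,\hat\tau_{max}}
#'   (`NA` when the plateau is not reached);
#' * `plateau_reached` — `TRUE` iff the mean slope over the final 10 min is
#'   below 0.001 min^-1 *and* `time_to_plateau` falls within the record.
#'
#' The 10% / 95% cutoffs and the 10-min terminal window are operational
#' definitions of the descriptive phase boundaries; see the methods vignette.
#'
#' @param curve a [as_turbidity_curve()] tibble (or any data frame with
#'   `time_min` and `turbidity`).
#' @return a `kinetics_fit` object; use [tidy()] for parameters, [glance()]
#'   for the one-row summary.
#' @export
fit_logistic <- function(curve) {
  if (!"turbidity" %in% names(curve) && "absorbance" %in% names(curve)) {
    curve <- as_turbidity_curve(curve)
  }
  t <- as.numeric(curve$time_min)
  tau <- as.numeric(curve$turbidity)
  if (length(t) < 10) abort("need at least 10 time points to fit the logistic model")
  if (sd(tau) == 0) abort("constant turbidity series: logistic fit is undefined")

  tau_max0 <- max(tau)
  t_half0 <- t[which.min(abs(tau - tau_max0 / 2))]
  slopes <- diff(tau) / diff(t)
  r0 <- max(4 * max(slopes) / tau_max0, 1e-3)
  # fixed jitter grid: deterministic restarts, no RNG state touched
  jit <- list(c(1, 1, 0), c(0.8, 0.5, -5), c(1.2, 2, 5), c(0.9, 4, 2), c(1.1, 0.25, -2))
  starts <- lapply(jit, function(j) c(tau_max0 * j[1], r0 * j[2], t_half0 + j[3]))

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nlsLM(
      tau ~ tau_max / (1 + exp(-rate * (t - t_half))),
      start = list(tau_max = s[1], rate = s[2], t_half = s[3]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
    ), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) abort("logistic fit failed to converge after 5 restarts")

  cf <- coef(best$fit)
  tau_max <- unname(cf["tau_max"])
  rate <- unname(cf["rate"])
  t_half <- unname(cf["t_half"])

  lag_idx <- which(tau >= 0.10 * tau_max)
  lag_time <- if (length(lag_idx)) t[lag_idx[1]] else NA_real_
  pl_idx <- which(tau >= 0.95 * tau_max)
  time_to_plateau <- if (length(pl_idx)) t[pl_idx[1]] else NA_real_
  win <- t >= max(t) - 10
  terminal_slope <- unname(coef(lm(tau[win] ~ t[win]))[2])
  plateau_reached <- is.finite(terminal_slope) && abs(terminal_slope) < 0.001 &&
    !is.na(time_to_plateau) && time_to_plateau <= max(t)
  if (!plateau_reached) time_to_plateau <- NA_real_

  structure(
    list(
      tau_max = tau_max, rate = rate, t_half = t_half,
      lag_time = lag_time, time_to_plateau = time_to_plateau,
      plateau_reached = plateau_reached,
      terminal_slope = terminal_slope,
      final_turbidity = tau[length(tau)],
      residual = sqrt(best$rss),
      data = tibble(time_min = t, turbidity = tau,
                    fitted = logistic_tau(t, tau_max, rate, t_half))
    ),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("Logistic gelation kinetics fit\n")
  cat(sprintf("  tau_max  %.4f   rate %.4f min^-1   t_half %.2f min\n",
              x$tau_max, x$rate, x$t_half))
  cat(sprintf("  lag %.0f min   plateau %s   final turbidity %.4f\n",
              x$lag_time,
              if (x$plateau_reached) sprintf("at %.0f min", x$time_to_plateau) else "not reached",
              x$final_turbidity))
  invisible(x)
}

#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(
    term = c("tau_max", "rate", "t_half"),
    estimate = c(x$tau_max, x$rate, x$t_half)
  )
}

#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(
    tau_max = x$tau_max, rate = x$rate, t_half = x$t_half,
    lag_time = x$lag_time, time_to_plateau = x$time_to_plateau,
    plateau_reached = x$plateau_reached,
    final_turbidity = x$final_turbidity,
    residual = x$residual
  )
}

#' @export
autoplot.kinetics_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$turbidity), size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "turbidity",
                  title = "Collagen gelation kinetics")
}

#' Compare gelation kinetics across age conditions
#'
#' Reports pairwise differences in fitted plateau turbidity, lag time and
#' time-to-plateau, and flags the expected aging pattern (the old-adult gel
#' forming faster but reaching a lower plateau than the young-adult one) when
#' both of those conditions are present.
#'
#' @param fits named list of `kinetics_fit` objects, names being age labels.
#' @return tibble of pairwise differences (`a` minus `b`), with the
#'   `old_faster_lower_plateau` flag carried in the `"pattern"` attribute.
#' @export
compare_ages <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2, !is.null(names(fits)))
  g <- purrr::map_dfr(fits, glance, .id = "age")
  pairs <- utils::combn(g$age, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    a <- g[g$age == p[1], ]; b <- g[g$age == p[2], ]
    tibble(
      age_a = p[1], age_b = p[2],
      d_tau_max = a$tau_max - b$tau_max,
      d_lag_time = a$lag_time - b$lag_time,
      d_time_to_plateau = a$time_to_plateau - b$time_to_plateau
    )
  })
  if (all(c("young_adult", "old_adult") %in% g$age)) {
    y <- g[g$age == "young_adult", ]; o <- g[g$age == "old_adult", ]
    attr(out, "pattern") <- list(
      old_faster_lower_plateau =
        isTRUE(o$tau_max < y$tau_max) &&
        isTRUE(o$plateau_reached) &&
        (is.na(y$time_to_plateau) || isTRUE(o$time_to_plateau <= y$time_to_plateau))
    )
  }
  out
}
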