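#' One-site specific binding prediction
#'
#' The saturation binding model `Y = Bmax * X / (Kd + X)`: at `X = Kd` the
#' response is half of `Bmax`, which is exactly how the dissociation
#' constant is read off a saturation curve.
#'
#' @param kd dissociation constant, nM (> 0).
#' @param bmax saturating response (response units, > 0).
#' @param x concentrations, nM (>= 0).
#' @return predicted responses, same length as `x`.
#' @export
predict_one_site <- function(kd, bmax, x) {
  if (kd <= 0 || bmax <= 0) stop("kd and bmax must be positive",
                                 call. = FALSE)
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  bmax * x / (kd + x)
}

#' Fit the one-site specific binding equation
#'
#' Unweighted nonlinear least squares of `response ~ bmax * conc /
#' (kd + conc)` via Levenberg-Marquardt. Initial values follow the
#' half-saturation reading of the curve: `kd0` is the concentration whose
#' response is nearest half the maximum response, `bmax0` the maximum
#' response. Standard errors come from the local curvature of the
#' least-squares objective at the optimum.
#'
#' @param data data frame with concentration and response columns.
#' @param concentration,response column names (tidy-eval), defaulting to
#'   `concentration_nM` and `response`.
#' @return object of class `one_site_fit`; see [tidy.one_site_fit()] /
#'   [glance.one_site_fit()] / [autoplot.one_site_fit()]. Key fields:
#'   `kd`, `bmax`, `kd_se`, `bmax_se`, `rss`, `converged`, `data`, `fit`.
#' @examples
#' curve <- make_binding_curve(kd = 6, bmax = 150, noise_sd = 0)
#' fit <- fit_one_site(curve)
#' glance(fit)
#' @export
fit_one_site <- function(data, concentration = "concentration_nM",
                         response = "response") {
  data <- tibble::as_tibble(data)
  if (!concentration %in% names(data) || !response %in% names(data)) {
    stop("data must have columns '", concentration, "' and '", response,
         "'", call. = FALSE)
  }
  x <- data[[concentration]]
  y <- data[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct concentrations to fit", call. = FALSE)
  }
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (all(y == 0)) stop("all responses are zero: nothing to fit",
                        call. = FALSE)
  if (length(unique(y)) == 1L) {
    stop("responses are constant: saturation curve undefined",
         call. = FALSE)
  }
  bmax0 <- max(y)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bmax * x / (kd + x), data = df,
      start = list(kd = kd0, bmax = bmax0),
      lower = c(kd = 1e-12, bmax = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(kd = NA_real_, bmax = NA_real_, kd_se = NA_real_,
                bmax_se = NA_real_, rss = NA_real_, converged = FALSE,
                message = conditionMessage(fit), data = data,
                cols = c(concentration, response), fit = NULL)
    class(out) <- "one_site_fit"
    return(out)
  }
  co <- summary(fit)$coefficients
  est <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  out <- list(
    kd = unname(est["kd"]), bmax = unname(est["bmax"]),
    kd_se = unname(co["kd", "Std. Error"]),
    bmax_se = unname(co["bmax", "Std. Error"]),
    rss = sum(stats::resid(fit)^2),
    converged = isTRUE(conv), message = NULL,
    data = data, cols = c(concentration, response), fit = fit
  )
  class(out) <- "one_site_fit"
  out
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site specific binding fit  Y = Bmax * X / (Kd + X)\n")
  if (!x$converged) cat("  (fit did not converge)\n")
  cat(sprintf("  Kd   = %.4g nM (se %.3g)\n", x$kd, x$kd_se))
  cat(sprintf("  Bmax = %.4g (se %.3g)\n", x$bmax, x$bmax_se))
  cat(sprintf("  RSS  = %.4g over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' Tidy a one-site binding fit
#' @param x a `one_site_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "bmax"),
                 estimate = c(x$kd, x$bmax),
                 std.error = c(x$kd_se, x$bmax_se))
}

#' One-row summary of a one-site binding fit
#' @param x a `one_site_fit`.
#' @param ... unused.
#' @return tibble with `kd`, `bmax`, `kd_se`, `bmax_se`, `rss`, `converged`,
#'   `nobs`.
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, bmax = x$bmax, kd_se = x$kd_se,
                 bmax_se = x$bmax_se, rss = x$rss,
                 converged = x$converged, nobs = nrow(x$data))
}

#' Back-predict responses from a fit
#' @param object a `one_site_fit`.
#' @param newdata optional data frame with a concentration column (same
#'   name used at fit time); defaults to the fitted data.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  conc <- object$cols[1]
  x <- if (is.null(newdata)) object$data[[conc]] else newdata[[conc]]
  predict_one_site(object$kd, object$bmax, x)
}

#' Plot a saturation binding fit
#'
#' Points are the measured responses; the line is the fitted one-site curve
#' on a log-scaled concentration axis, with the fitted Kd marked at
#' half-saturation.
#'
#' @param object a `one_site_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.one_site_fit <- function(object, ...) {
  conc <- object$cols[1]; resp <- object$cols[2]
  d <- object$data
  xs <- exp(seq(log(min(d[[conc]])), log(max(d[[conc]])), length.out = 200))
  curve <- tibble::tibble(x = xs,
                          y = predict_one_site(object$kd, object$bmax, xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[conc]], y = .data[[resp]])) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (nM)", y = "response",
      title = sprintf("one-site fit: Kd = %.3g nM, Bmax = %.3g",
                      object$kd, object$bmax)) +
    ggplot2::theme_minimal()
}
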