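# Hyperbolic (Michaelis-Menten) fitting used for ATPase-vs-actin and
# velocity-vs-MgATP curves, with broom-style accessors.

#' Fit a hyperbola y = V_max x / (K + x)
#'
#' Unweighted least squares via Levenberg-Marquardt; 95 percent confidence
#' intervals from the parameter covariance at the optimum.  A fit is flagged
#' non-identifiable when the estimated \code{K} falls outside the sampled
#' range by more than a factor of five on either side (all x far below or
#' far above K).
#'
#' @param x Abscissa (concentration), non-negative, length >= 4.
#' @param y Observed rates/velocities.
#' @return An object of class \code{hyperbolic_fit} with elements
#'   \code{V_max}, \code{K}, \code{ci} (2x2 matrix of 95 percent limits),
#'   \code{rss}, \code{flag} (\code{"ok"} or \code{"non_identifiable"}) and
#'   the underlying \code{nls} fit.
#' @examples
#' f <- fit_hyperbola(c(0.1, 0.3, 1, 3), 2 * c(0.1, 0.3, 1, 3) /
#'                    (1 + c(0.1, 0.3, 1, 3)))
#' tidy(f)
#' @export
fit_hyperbola <- function(x, y) {
  if (length(x) < 4) stop("need >= 4 points")
  if (any(x < 0)) stop("x must be >= 0")
  if (length(x) != length(y)) stop("x and y lengths differ")
  dat <- data.frame(x = x, y = y)
  # coarse grid over K for a robust start (conditionally linear in V_max)
  kgrid <- 10^seq(log10(max(min(x[x > 0]), 1e-6) / 10),
                  log10(max(x) * 10), length.out = 40)
  score <- vapply(kgrid, function(k) {
    b <- x / (k + x)
    v <- sum(b * y) / sum(b * b)
    sum((y - v * b)^2)
  }, numeric(1))
  k0 <- kgrid[which.min(score)]
  v0 <- sum(y * x / (k0 + x)) / sum((x / (k0 + x))^2)
  fit <- minpack.lm::nlsLM(y ~ Vmax * x / (K + x), data = dat,
                           start = list(Vmax = v0, K = k0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  flag <- if (est["K"] > max(x) * 5 || est["K"] < min(x[x > 0]) / 5)
    "non_identifiable" else "ok"
  if (flag != "ok")
    warning("hyperbolic fit poorly identified: K = ", signif(est["K"], 3),
            " outside the sampled range")
  structure(list(V_max = unname(est["Vmax"]), K = unname(est["K"]),
                 se = unname(se), ci = ci,
                 rss = sum(stats::residuals(fit)^2),
                 flag = flag, fit = fit, data = dat),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat("Hyperbolic fit y = V_max x / (K + x)\n")
  cat(sprintf("  V_max = %.4g  (95%% CI %.4g - %.4g)\n",
              x$V_max, x$ci[1, 1], x$ci[1, 2]))
  cat(sprintf("  K     = %.4g  (95%% CI %.4g - %.4g)\n",
              x$K, x$ci[2, 1], x$ci[2, 2]))
  cat("  RSS =", signif(x$rss, 4), " flag:", x$flag, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hyperbolic fit
#'
#' @param x A \code{hyperbolic_fit}.
#' @param ... Unused.
#' @return One row per parameter: term, estimate, std.error, conf.low,
#'   conf.high.
#' @export
tidy.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("V_max", "K"),
    estimate = c(x$V_max, x$K),
    std.error = x$se,
    conf.low = x$ci[, "lower"],
    conf.high = x$ci[, "upper"]
  )
}

#' @rdname tidy.hyperbolic_fit
#' @export
glance.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), flag = x$flag)
}

#' @export
autoplot.hyperbolic_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(0, max(object$data$x), length.out = 200))
  grid$y <- object$V_max * grid$x / (object$K + grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "concentration", y = "rate",
                  subtitle = sprintf("V_max = %.3g, K = %.3g",
                                     object$V_max, object$K)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# single-exponential rise fit, F(t) = F_inf (1 - exp(-r t)), used for the
# rate of rise of isometric force
fit_exponential_rise <- function(time, value) {
  dat <- data.frame(t = time, y = value)
  f_inf0 <- stats::median(tail(dat$y, max(3, round(nrow(dat) / 5))))
  if (f_inf0 <= 0) f_inf0 <- max(dat$y)
  r0 <- 1 / max(time[which(value >= 0.63 * f_inf0)][1], time[2])
  if (!is.finite(r0) || r0 <= 0) r0 <- 2 / max(time)
  fit <- minpack.lm::nlsLM(y ~ Finf * (1 - exp(-r * t)), data = dat,
                           start = list(Finf = f_inf0, r = r0),
                           lower = c(0, 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  list(F_inf = unname(est["Finf"]), rate = unname(est["r"]),
       rss = sum(stats::residuals(fit)^2))
}
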