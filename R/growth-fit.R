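#' Fit a growth model to a cell-count time series
#'
#' Fits the Verhulst (logistic), Richards (generalized logistic) or Gompertz
#' growth law to observed counts by nonlinear least squares on the model's
#' closed-form trajectory, minimizing `sum (N_obs - N_model(t))^2` over
#' `(r, K, N0)` and, for Richards, the contact-inhibition exponent `v`.
#' Because logistic-type fits are sensitive to initialization, optimization
#' is multi-started from a heuristic grid: `K` from \{1, 2, 5\} times the
#' maximum count, `r` from a log-linear fit of the early (sub-half-maximum)
#' counts, `N0` from the first count, and `v` from \{0.5, 1, 2\}.
#' Parameters are optimized on the log scale.
#'
#' Non-convergence from every start yields a `growth_fit` with
#' `converged = FALSE`, never an error. Constant (zero-variance) counts are
#' flagged `degenerate`.
#'
#' @param curve a [growth_curve()] (or data frame with `time_days`, `count`)
#'   with at least 5 observations.
#' @param model one of `"verhulst"`, `"richards"`, `"gompertz"`.
#' @param init optional [growth_params()] used as an additional start.
#' @return an object of class `growth_fit` with components `model`, `params`
#'   (a [growth_params()]), `rss`, `r2`, `adj_r2`, `logLik`, `aic`,
#'   `converged`, `degenerate`, `n`, `k` (number of growth parameters) and
#'   the data. Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `logLik`, `AIC`, `plot`, `simulate` and [profile()].
#' @examples
#' p <- growth_params(r = 0.8, K = 1e6, N0 = 1e4)
#' curve <- growth_curve(0:21, verhulst_solution(p, 0:21))
#' fit <- fit_growth(curve, "verhulst")
#' coef(fit)
#' @seealso [rank_growth_models()], [profile.growth_fit()],
#'   [stopping_criterion()]
#' @export
fit_growth <- function(curve, model = c("verhulst", "richards", "gompertz"),
                       init = NULL) {
  model <- match.arg(model)
  curve <- as_growth_curve(curve)
  t <- curve$time_days
  y <- curve$count
  n <- length(y)
  if (n < 5L) stop("at least 5 observations are required for fitting")
  k <- if (model == "richards") 4L else 3L

  tss <- sum((y - mean(y))^2)
  degenerate <- tss < .Machine$double.eps * n * mean(y)^2

  obj <- function(theta) {
    p <- theta_to_params(theta, model)
    mu <- growth_solution(model, p, t)
    if (any(!is.finite(mu))) return(1e300)
    sum((y - mu)^2)
  }

  starts <- fit_starts(t, y, model, init)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(s, obj, control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  if (is.null(best)) {
    fit <- list(model = model, params = NULL, coefficients = NULL,
                rss = NA_real_, n = n, k = k, r2 = NA_real_,
                adj_r2 = NA_real_, logLik = NA_real_, aic = NA_real_,
                converged = FALSE, degenerate = degenerate, data = curve,
                fitted = rep(NA_real_, n))
    class(fit) <- "growth_fit"
    return(fit)
  }

  params <- theta_to_params(best$par, model)
  mu <- growth_solution(model, params, t)
  rss <- sum((y - mu)^2)
  # guard against exact interpolation: log(0) in the Gaussian likelihood
  rss_ll <- max(rss, .Machine$double.eps * max(tss, 1))
  r2 <- if (degenerate) NA_real_ else 1 - rss / tss
  ll <- -n / 2 * (log(2 * pi) + log(rss_ll / n) + 1)
  fit <- list(model = model, params = params,
              coefficients = unlist(params)[c("r", "K", "v", "N0")],
              rss = rss, n = n, k = k, r2 = r2,
              adj_r2 = if (degenerate) NA_real_ else adjusted_r2(r2, n, k),
              logLik = ll, aic = -2 * ll + 2 * (k + 1),
              converged = best$convergence == 0 || rss <= rss_ll,
              degenerate = degenerate, data = curve, fitted = mu)
  class(fit) <- "growth_fit"
  fit
}

as_growth_curve <- function(curve) {
  if (inherits(curve, "growth_curve")) return(curve)
  if (is.data.frame(curve) && all(c("time_days", "count") %in% names(curve))) {
    id <- if ("population_id" %in% names(curve)) curve$population_id[1] else "population"
    return(growth_curve(curve$time_days, curve$count, id))
  }
  stop("`curve` must be a growth_curve or data frame with time_days/count")
}

theta_to_params <- function(theta, model) {
  if (model == "richards") {
    growth_params(r = exp(theta[1]), K = exp(theta[2]), N0 = exp(theta[3]),
                  v = exp(theta[4]))
  } else {
    growth_params(r = exp(theta[1]), K = exp(theta[2]), N0 = exp(theta[3]),
                  v = 1)
  }
}

fit_starts <- function(t, y, model, init = NULL) {
  ymax <- max(y)
  # log-linear growth rate from early, sub-half-maximum counts
  early <- which(y < ymax / 2)
  if (length(early) < 3L) early <- seq_len(min(5L, length(y)))
  sl <- tryCatch(stats::coef(stats::lm(log(y[early]) ~ t[early]))[2],
                 error = function(e) NA_real_)
  r0 <- if (is.finite(sl) && sl > 0.01) min(sl, 5) else 0.5
  n00 <- max(y[1], 1e-6)
  starts <- list()
  for (kmul in c(1.000001, 2, 5)) {
    base <- c(log(r0), log(kmul * ymax), log(n00))
    if (model == "richards") {
      for (v0 in c(0.5, 1, 2)) starts[[length(starts) + 1L]] <- c(base, log(v0))
    } else {
      starts[[length(starts) + 1L]] <- base
    }
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "growth_params"))
    th <- log(c(init$r, init$K, init$N0))
    if (model == "richards") th <- c(th, log(init$v))
    starts[[length(starts) + 1L]] <- th
  }
  starts
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)`, penalizing the plain `R^2 = 1 -
#' RSS/TSS` for the `k` fitted parameters.
#'
#' @param r2 the unadjusted R-squared.
#' @param n number of observations (`n > k + 1`).
#' @param k number of fitted parameters.
#' @return the adjusted R-squared (`<= 1`; can be negative).
#' @examples
#' adjusted_r2(0.99, n = 20, k = 3)  # 0.988125
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("`n` must exceed k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth fit (%s)\n", x$model, x$data$population_id[1]))
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  print(x$params)
  cat(sprintf("  n = %d, RSS = %.6g, adj-R2 = %s, AIC = %.4g\n", x$n, x$rss,
              if (is.na(x$adj_r2)) "NA (degenerate)" else sprintf("%.4f", x$adj_r2),
              x$aic))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$converged) {
    sigma <- sqrt(f$rss / (f$n - f$k))
    cat(sprintf("  residual sd = %.4g, logLik = %.4g, df = %d\n",
                sigma, f$logLik, f$k + 1L))
    if (f$degenerate) cat("  WARNING: zero-variance counts; fit degenerate\n")
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
fitted.growth_fit <- function(object, ...) object$fitted

#' @export
residuals.growth_fit <- function(object, ...) object$data$count - object$fitted

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$logLik, df = object$k + 1L, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.growth_fit <- function(object, ...) object$n

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  t <- if (is.null(newdata)) object$data$time_days else {
    if (is.data.frame(newdata)) newdata$time_days else newdata
  }
  growth_solution(object$model, object$params, t)
}

#' @export
plot.growth_fit <- function(x, ...) {
  tt <- seq(min(x$data$time_days), max(x$data$time_days), length.out = 200)
  plot(x$data$time_days, x$data$count, xlab = "time (days)",
       ylab = "cell count",
       main = sprintf("%s fit: %s", x$model, x$data$population_id[1]), ...)
  if (x$converged) graphics::lines(tt, predict(x, tt), col = "firebrick")
  invisible(x)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  sigma <- sqrt(object$rss / max(object$n - object$k, 1))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, pmax(mu + stats::rnorm(object$n, 0, sigma),
                                            .Machine$double.eps)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Rank candidate growth models by AIC
#'
#' Compares fits of different growth laws to the same curve by the Gaussian
#' AIC (`-2 logLik + 2 df`, where `df` counts growth parameters plus the
#' noise variance); lower is better. AIC ties are broken in favor of fewer
#' parameters.
#'
#' @param fits list of [fit_growth()] results on the same curve.
#' @return data frame with one row per model, ordered best first, with
#'   columns `model`, `k`, `rss`, `adj_r2`, `aic`.
#' @export
rank_growth_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "growth_fit")))
  ns <- vapply(fits, function(f) f$n, 0L)
  if (length(unique(ns)) != 1L) stop("fits must be on the same curve")
  df <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    k = vapply(fits, function(f) f$k, 0L),
    rss = vapply(fits, function(f) f$rss, 0),
    adj_r2 = vapply(fits, function(f) f$adj_r2, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$aic, df$k), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Carrying-capacity stability stopping criterion
#'
#' Decides whether a growth experiment can be stopped: the curve is refit
#' with each contiguous truncation of the last `tail_fraction` of time points
#' removed, and the criterion is met when every truncated estimate of the
#' carrying capacity is within `threshold` (default 4%) fold change of the
#' full-curve estimate. A curve still in its exponential phase fails, since
#' the inferred `K` keeps drifting as points are dropped.
#'
#' @param curve a [growth_curve()].
#' @param model growth law used for the fits (default Verhulst).
#' @param tail_fraction fraction of trailing points subject to removal.
#' @param threshold maximal tolerated relative change in the inferred `K`.
#' @return logical; `TRUE` when the inferred carrying capacity is stable.
#'   Attributes `K_full` and `K_truncated` carry the estimates.
#' @export
stopping_criterion <- function(curve, model = "verhulst",
                               tail_fraction = 0.2, threshold = 0.04) {
  curve <- as_growth_curve(curve)
  n <- nrow(curve)
  m <- max(1L, floor(tail_fraction * n))
  if (n - m < 5L) stop("too few points to evaluate the stopping criterion")
  full <- fit_growth(curve, model)
  if (!full$converged || full$degenerate) {
    return(structure(FALSE, K_full = NA_real_, K_truncated = numeric(0)))
  }
  K_full <- full$params$K
  K_trunc <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    sub <- growth_curve(curve$time_days[1:(n - j)], curve$count[1:(n - j)],
                        curve$population_id[1])
    fj <- tryCatch(fit_growth(sub, model), error = function(e) NULL)
    if (is.null(fj) || !fj$converged || fj$degenerate) {
      return(structure(FALSE, K_full = K_full, K_truncated = K_trunc))
    }
    K_trunc[j] <- fj$params$K
  }
  ok <- max(abs(K_trunc - K_full) / K_full) < threshold
  structure(ok, K_full = K_full, K_truncated = K_trunc)
}
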