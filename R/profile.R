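#' Profile likelihood and practical identifiability
#'
#' For a fitted growth model, fixes one parameter at each value of a grid and
#' re-optimizes the remaining parameters, giving the profile log-likelihood.
#' The 95% confidence region is the set of grid values whose profile
#' log-likelihood lies within `qchisq(level, 1)/2` (about 1.92 for 95%) of
#' the maximum. A parameter is *practically identifiable* when that region is
#' bounded inside the searched grid; noisy or truncated data typically leave
#' the carrying capacity `K` or the shape `v` with an unbounded upper profile
#' — e.g. counts from a purely exponential phase constrain only `r`, so any
#' sufficiently large `K` fits equally well.
#'
#' Default grids have 41 points: log-spaced over `[estimate/100,
#' 100*estimate]` for `K`, `v` and `N0`, and linear over `[estimate/3,
#' 3*estimate]` for `r`. Re-optimizations walk outward from the estimate,
#' warm-starting each grid point at the previous solution, so the profile
#' maximum matches the unconstrained maximum.
#'
#' @param fitted a converged [fit_growth()] result.
#' @param which parameter to profile: `"r"`, `"K"`, `"N0"` or (Richards)
#'   `"v"`.
#' @param grid optional numeric vector of values at which to fix the
#'   parameter; must bracket the estimate for a two-sided interval.
#' @param level confidence level of the reported interval.
#' @param ... unused.
#' @return an object of class `growth_profile`: the grid, profile
#'   log-likelihoods, the confidence interval (`-Inf`/`Inf` when the region
#'   touches the grid boundary) and the `identifiable` flag.
#' @examples
#' p <- growth_params(r = 0.8, K = 1e6, N0 = 1e4)
#' curve <- growth_curve(0:14, verhulst_solution(p, 0:14) *
#'                        exp(rnorm(15, 0, 0.02)))
#' fit <- fit_growth(curve, "verhulst")
#' prof <- profile(fit, "K")
#' prof$identifiable
#' @export
profile.growth_fit <- function(fitted, which = "K", grid = NULL,
                               level = 0.95, ...) {
  fit <- fitted
  if (!fit$converged) stop("profiling requires a converged fit")
  pnames <- if (fit$model == "richards") c("r", "K", "N0", "v") else c("r", "K", "N0")
  which <- match.arg(which, pnames)
  est <- fit$params[[which]]
  if (is.null(grid)) {
    grid <- if (which == "r") {
      seq(est / 3, 3 * est, length.out = 41L)
    } else {
      exp(seq(log(est / 100), log(est * 100), length.out = 41L))
    }
  }
  grid <- sort(unique(as.numeric(grid)))
  if (min(grid) > est || max(grid) < est) {
    warning("profile grid does not bracket the estimate; interval may be one-sided")
  }

  t <- fit$data$time_days
  y <- fit$data$count
  n <- fit$n
  free <- setdiff(pnames, which)
  model <- fit$model

  rss_at <- function(value, start_free) {
    obj <- function(theta) {
      p <- free_theta_to_params(theta, free, which, value, model)
      mu <- growth_solution(model, p, t)
      if (any(!is.finite(mu))) return(1e300)
      sum((y - mu)^2)
    }
    res <- tryCatch(
      stats::nlminb(start_free, obj,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective)) {
      list(rss = Inf, par = start_free)
    } else {
      list(rss = res$objective, par = res$par)
    }
  }

  start0 <- log(unlist(fit$params)[free])
  prof_rss <- rep(NA_real_, length(grid))
  # walk outward from the grid point nearest the estimate, warm-starting
  i0 <- which.min(abs(log(grid) - log(est)))
  par <- start0
  for (i in i0:length(grid)) {
    res <- rss_at(grid[i], par)
    prof_rss[i] <- res$rss; par <- res$par
  }
  par <- start0
  for (i in rev(seq_len(i0))) {
    res <- rss_at(grid[i], par)
    prof_rss[i] <- res$rss; par <- res$par
  }

  rss_floor <- .Machine$double.eps * max(sum((y - mean(y))^2), 1)
  ll <- -n / 2 * (log(2 * pi) + log(pmax(prof_rss, rss_floor) / n) + 1)
  ll_max <- max(fit$logLik, max(ll, na.rm = TRUE))
  cutoff <- ll_max - stats::qchisq(level, 1) / 2
  inside <- is.finite(ll) & ll >= cutoff

  if (!any(inside)) {
    ci <- c(NA_real_, NA_real_); identifiable <- FALSE
  } else {
    lo_idx <- min(which(inside)); hi_idx <- max(which(inside))
    # interpolate the cutoff crossing between adjacent grid points
    cross <- function(i_out, i_in) {
      if (!is.finite(ll[i_out])) return(grid[i_in])
      frac <- (cutoff - ll[i_out]) / (ll[i_in] - ll[i_out])
      grid[i_out] + frac * (grid[i_in] - grid[i_out])
    }
    lower <- if (lo_idx == 1L) -Inf else cross(lo_idx - 1L, lo_idx)
    upper <- if (hi_idx == length(grid)) Inf else cross(hi_idx + 1L, hi_idx)
    ci <- c(lower, upper)
    identifiable <- is.finite(lower) && is.finite(upper)
  }

  structure(list(parameter = which, estimate = est, grid = grid,
                 profile_logLik = ll, max_logLik = ll_max, cutoff = cutoff,
                 level = level, ci = ci, identifiable = identifiable),
            class = "growth_profile")
}

free_theta_to_params <- function(theta, free, fixed_name, fixed_value, model) {
  vals <- stats::setNames(exp(theta), free)
  vals[[fixed_name]] <- fixed_value
  growth_params(r = vals[["r"]], K = vals[["K"]], N0 = vals[["N0"]],
                v = if (model == "richards") vals[["v"]] else 1)
}

#' @export
print.growth_profile <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s (estimate %.4g)\n",
              x$parameter, x$estimate))
  cat(sprintf("  %d%% CI: [%.4g, %.4g] — %s\n", round(100 * x$level),
              x$ci[1], x$ci[2],
              if (isTRUE(x$identifiable)) "practically identifiable"
              else "NOT identifiable within the searched grid"))
  invisible(x)
}

#' @export
plot.growth_profile <- function(x, ...) {
  logx <- x$parameter != "r"
  plot(x$grid, x$profile_logLik, type = "b", log = if (logx) "x" else "",
       xlab = x$parameter, ylab = "profile log-likelihood",
       main = sprintf("Profile: %s", x$parameter), ...)
  graphics::abline(h = x$cutoff, lty = 2, col = "firebrick")
  graphics::abline(v = x$estimate, lty = 3)
  invisible(x)
}
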