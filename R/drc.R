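#' Three-parameter exponential decay dose-response model
#'
#' `response = c + (d - c) * exp(-dose / e)`: upper asymptote `d` at dose 0,
#' decaying toward the lower asymptote `c` with rate scale `e` (> 0).
#'
#' @param dose dose vector (>= 0).
#' @param c,d lower and upper asymptotes.
#' @param e rate scale (dose units, > 0).
#' @return predicted response vector.
#' @export
exd3 <- function(dose, c, d, e) {
  if (any(e <= 0)) stop("rate scale e must be positive", call. = FALSE)
  c + (d - c) * exp(-dose / e)
}

#' Four-parameter log-logistic dose-response model
#'
#' `response = c + (d - c) / (1 + exp(b * (log(dose) - log(e))))`: slope `b`,
#' lower asymptote `c`, upper asymptote `d`, inflection dose `e` (> 0), where
#' the response is exactly midway between `c` and `d` at `dose = e`.  Dose 0
#' is handled by the analytic limit: `d` for `b > 0`, `c` for `b < 0`,
#' `(c + d) / 2` for `b = 0`.
#'
#' @param dose dose vector (>= 0).
#' @param b slope.
#' @param c,d lower and upper asymptotes.
#' @param e inflection dose (> 0).
#' @return predicted response vector.
#' @export
ll4 <- function(dose, b, c, d, e) {
  if (any(e <= 0)) stop("inflection dose e must be positive", call. = FALSE)
  out <- numeric(length(dose))
  pos <- dose > 0
  out[pos] <- c + (d - c) / (1 + exp(b * (log(dose[pos]) - log(e))))
  if (any(!pos)) {
    lim0 <- if (b > 0) d else if (b < 0) c else (c + d) / 2
    out[!pos] <- lim0
  }
  out
}

drc_predict <- function(model, par, dose) {
  if (model == "EXD3") {
    exd3(dose, par[["c"]], par[["d"]], par[["e"]])
  } else {
    ll4(dose, par[["b"]], par[["c"]], par[["d"]], par[["e"]])
  }
}

drc_start <- function(model, dose, response) {
  d0 <- max(response)
  c0 <- min(response)
  half <- (c0 + d0) / 2
  posd <- dose[dose > 0]
  e0 <- if (length(posd) > 0) {
    # positive dose whose mean response is nearest the half-range
    m <- tapply(response[dose > 0], posd, mean)
    as.numeric(names(m))[which.min(abs(m - half))]
  } else {
    1
  }
  if (!is.finite(e0) || e0 <= 0) e0 <- max(median(posd), 1e-3)
  if (model == "EXD3") c(c = c0, d = d0, e = e0)
  else c(b = 1, c = c0, d = d0, e = e0)
}

drc_bounds <- function(model) {
  if (model == "EXD3") {
    list(lower = c(c = -Inf, d = -Inf, e = 1e-9),
         upper = c(c = Inf, d = Inf, e = Inf))
  } else {
    list(lower = c(b = -Inf, c = -Inf, d = -Inf, e = 1e-9),
         upper = c(b = Inf, c = Inf, d = Inf, e = Inf))
  }
}

# One Levenberg-Marquardt run; returns NULL on hard failure.
drc_lm_once <- function(model, dose, response, start, maxiter = 200) {
  bounds <- drc_bounds(model)
  # convergence is judged from the returned info code, so the optimizer's
  # own maxiter warning is redundant noise
  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = as.list(start),
      lower = bounds$lower[names(start)],
      upper = bounds$upper[names(start)],
      fn = function(p) response - drc_predict(model, p, dose),
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    )),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  conv <- res$info %in% 1:4 && is.finite(res$deviance)
  list(par = unlist(res$par), rss = res$deviance, converged = conv, fit = res)
}

#' Fit a dose-response model by nonlinear least squares
#'
#' Fits EXD3 or LL4 by Levenberg-Marquardt from data-driven starts
#' (`d` = max response, `c` = min response, `e` = dose nearest the half-range
#' response, `b` = 1), with three additional multiplicatively jittered
#' restarts (factors in \[0.8, 1.2\], seeded); the converged run with the
#' lowest residual sum of squares wins.  The AIC uses the Gaussian
#' log-likelihood convention `n * log(RSS / n) + 2 * (k + 1)`, counting the
#' error variance as a parameter.
#'
#' @param data data frame with columns `dose` and `response` (an optional
#'   `replicate` column is carried along for bootstrap resampling).
#' @param model `"EXD3"` or `"LL4"`.
#' @param seed seed for the start jitter.
#' @param n_restarts number of jittered restarts.
#' @return an object of class `dose_response_fit`: estimates, standard
#'   errors, RSS, n, AIC and an honest `converged` flag.
#' @export
fit_drc <- function(data, model = c("EXD3", "LL4"), seed = 1L,
                    n_restarts = 3L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), all(c("dose", "response") %in% names(data)))
  dose <- as.numeric(data$dose); response <- as.numeric(data$response)
  stopifnot(all(is.finite(dose)), all(is.finite(response)), all(dose >= 0))
  k <- if (model == "EXD3") 3L else 4L
  if (length(unique(dose)) < k + 1L) {
    stop(sprintf("%s needs at least %d distinct doses, got %d", model, k + 1L,
                 length(unique(dose))), call. = FALSE)
  }
  start0 <- drc_start(model, dose, response)
  starts <- list(start0)
  for (r in seq_len(n_restarts)) {
    jit <- with_seed(child_seed(seed, r),
                     runif(length(start0), 0.8, 1.2))
    starts[[r + 1L]] <- setNames(start0 * jit, names(start0))
  }
  best <- NULL
  for (st in starts) {
    cand <- drc_lm_once(model, dose, response, st)
    if (is.null(cand) || !cand$converged) next
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  n <- length(response)
  if (is.null(best)) {
    fit <- list(model = model, coefficients = start0,
                se = setNames(rep(NA_real_, k), names(start0)),
                rss = NA_real_, n = n, k = k, aic = NA_real_,
                converged = FALSE, data = data, seed = as.integer(seed))
    class(fit) <- "dose_response_fit"
    return(fit)
  }
  rss <- max(best$rss, 1e-300)
  aic <- n * log(rss / n) + 2 * (k + 1)
  se <- drc_se(best$fit, n, k)
  fit <- list(model = model, coefficients = best$par, se = se,
              rss = best$rss, n = n, k = k, aic = aic,
              converged = TRUE, data = data, seed = as.integer(seed))
  class(fit) <- "dose_response_fit"
  fit
}

# standard errors from the LM Jacobian: sigma^2 * (J'J)^-1
drc_se <- function(lmfit, n, k) {
  par_names <- names(unlist(lmfit$par))
  se <- setNames(rep(NA_real_, k), par_names)
  if (n <= k) return(se)
  s2 <- lmfit$deviance / (n - k)
  cv <- tryCatch(s2 * solve(lmfit$hessian / 2), error = function(e) NULL)
  if (!is.null(cv)) {
    dg <- diag(cv)
    dg[dg < 0] <- NA_real_
    se <- setNames(sqrt(dg), par_names)
  }
  se
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s, n = %d, %s\n", x$model, x$n,
              if (x$converged) "converged" else "NOT converged"))
  est <- data.frame(estimate = x$coefficients, std_error = x$se)
  print(round(est, 5))
  cat(sprintf("RSS = %.6g, AIC = %.4f\n", x$rss, x$aic))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  drc_predict(object$model, object$coefficients, dose)
}

#' Fit both dose-response families and select by AIC
#'
#' Fits EXD3 and LL4 with [fit_drc()] and returns the converged fit with the
#' lower AIC.  Near-ties (|delta AIC| < 1e-9) go to the smaller model (EXD3).
#' The AICs of both families are attached as attribute `"aic_both"`.
#'
#' @inheritParams fit_drc
#' @return the selected `dose_response_fit`.
#' @export
select_model <- function(data, seed = 1L) {
  f_exd <- fit_drc(data, "EXD3", seed = seed)
  f_ll4 <- fit_drc(data, "LL4", seed = seed)
  aics <- c(EXD3 = f_exd$aic, LL4 = f_ll4$aic)
  if (!f_exd$converged && !f_ll4$converged) {
    stop("both dose-response fits failed to converge (EXD3 RSS: ",
         format(f_exd$rss), ", LL4 RSS: ", format(f_ll4$rss), ")",
         call. = FALSE)
  }
  sel <- if (!f_ll4$converged) {
    f_exd
  } else if (!f_exd$converged) {
    f_ll4
  } else if (f_ll4$aic < f_exd$aic - 1e-9) {
    f_ll4
  } else {
    f_exd
  }
  attr(sel, "aic_both") <- aics
  sel
}

ed50_point <- function(fit) {
  cf <- fit$coefficients
  if (fit$model == "EXD3") {
    if (cf[["c"]] >= cf[["d"]]) {
      stop("degenerate EXD3 fit (c >= d): ED50 undefined", call. = FALSE)
    }
    # solve c + (d - c) exp(-x/e) = (c + d)/2  =>  x = e ln 2
    unname(cf[["e"]] * log(2))
  } else {
    unname(cf[["e"]])
  }
}

#' Median effective dose with confidence interval
#'
#' The ED50 is the dose at which the fitted response is midway between the
#' fitted asymptotes: the inflection dose `e` for LL4 (exactly), and
#' `e * ln 2` for EXD3 (analytic solution of the half-decay equation).  The
#' 95% confidence interval is a nonparametric bootstrap percentile interval
#' (replicates resampled with replacement within each dose, the same family
#' refitted from the point estimates); a delta-method interval is reported
#' alongside for comparison.
#'
#' @param fit a converged [fit_drc()] result.
#' @param B number of bootstrap resamples.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @param ci `"bootstrap"` (default), or `"delta"` to skip resampling.
#' @return list with `ed50`, `ci` (`lo`, `hi`), `ci_method`, `delta_ci`,
#'   `n_boot_converged`.
#' @export
ed50 <- function(fit, B = 999L, seed = 1L, level = 0.95,
                 ci = c("bootstrap", "delta")) {
  stopifnot(inherits(fit, "dose_response_fit"))
  ci <- match.arg(ci)
  if (!fit$converged) stop("cannot compute ED50 from a non-converged fit",
                           call. = FALSE)
  est <- ed50_point(fit)
  alpha <- 1 - level

  # delta method: ED50 is e (LL4) or e * ln2 (EXD3), so se scales directly
  se_e <- fit$se[["e"]]
  mult <- if (fit$model == "EXD3") log(2) else 1
  delta_ci <- if (is.finite(se_e)) {
    tq <- qt(1 - alpha / 2, df = fit$n - fit$k)
    c(lo = est - tq * mult * se_e, hi = est + tq * mult * se_e)
  } else {
    c(lo = NA_real_, hi = NA_real_)
  }

  if (ci == "delta") {
    return(list(ed50 = est, ci = delta_ci, ci_method = "delta",
                delta_ci = delta_ci, n_boot_converged = NA_integer_))
  }

  dose <- as.numeric(fit$data$dose)
  response <- as.numeric(fit$data$response)
  groups <- split(seq_along(dose), dose)
  boots <- with_seed(child_seed(seed, 77L), {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      refit <- drc_lm_once(fit$model, dose[idx], response[idx],
                           fit$coefficients, maxiter = 100)
      if (is.null(refit) || !refit$converged) return(NA_real_)
      cf <- refit$par
      if (fit$model == "EXD3") {
        if (cf[["c"]] >= cf[["d"]]) return(NA_real_)
        cf[["e"]] * log(2)
      } else {
        cf[["e"]]
      }
    }, numeric(1))
  })
  ok <- boots[is.finite(boots)]
  if (length(ok) < B / 2) {
    warning(sprintf("only %d of %d bootstrap refits converged", length(ok), B),
            call. = FALSE)
  }
  bci <- if (length(ok) >= 2) {
    setNames(quantile(ok, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                      type = 7), c("lo", "hi"))
  } else {
    c(lo = NA_real_, hi = NA_real_)
  }
  list(ed50 = est, ci = bci, ci_method = "bootstrap", delta_ci = delta_ci,
       n_boot_converged = length(ok))
}

#' Plot a fitted dose-response curve
#'
#' Dose on a log axis, observed responses as points, the fitted curve as a
#' line, and the ED50 marked with a triangle on the dose axis.
#'
#' @param x a converged `dose_response_fit`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.dose_response_fit <- function(x, ...) {
  dose <- x$data$dose
  pos <- dose[dose > 0]
  xgrid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 200))
  plot(pmax(dose, min(pos) / 2), x$data$response, log = "x",
       xlab = "dose (uM)", ylab = "response (survival fraction)",
       main = sprintf("%s fit (AIC %.2f)", x$model, x$aic), ...)
  graphics::lines(xgrid, drc_predict(x$model, x$coefficients, xgrid),
                  col = "steelblue", lwd = 2)
  e50 <- tryCatch(ed50_point(x), error = function(e) NA_real_)
  if (is.finite(e50)) {
    graphics::points(e50, min(x$data$response), pch = 17, cex = 1.5,
                     col = "firebrick")
  }
  invisible(x)
}
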