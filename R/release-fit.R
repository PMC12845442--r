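#' In vitro cumulative release data
#'
#' A time series of observed cumulative released fractions, the input to
#' [fit_release()] and [select_model()]. Fractions slightly above 1 (up to
#' 1.05) are tolerated as experimental overshoot.
#'
#' @param times sampling times [min], strictly increasing, >= 0
#' @param fractions observed cumulative fractions, in [0, 1.05]
#' @return object of class \code{release_data}
#' @export
release_data <- function(times, fractions) {
  stopifnot(is.numeric(times), is.numeric(fractions),
            length(times) == length(fractions))
  if (length(times) < 3L) stop("need at least 3 observations")
  if (any(times < 0)) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions < 0) || any(fractions > 1.05))
    stop("fractions must lie in [0, 1.05]")
  structure(list(times = as.numeric(times),
                 fractions = as.numeric(fractions)),
            class = "release_data")
}

#' Read / write release data as two-column delimited text
#'
#' Plain CSV with header \code{time_min, fraction_released}.
#'
#' @param path file path
#' @return [release_data()] for the reader; the writer returns \code{path}
#'   invisibly
#' @export
read_release_data <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "fraction_released") %in% names(d)))
    stop("expected columns 'time_min' and 'fraction_released' in ", path)
  release_data(d$time_min, d$fraction_released)
}

#' @rdname read_release_data
#' @param data a [release_data()]
#' @export
write_release_data <- function(data, path) {
  stopifnot(inherits(data, "release_data"))
  utils::write.csv(
    data.frame(time_min = data$times, fraction_released = data$fractions),
    path, row.names = FALSE)
  invisible(path)
}

# Coefficients actually estimated per family. W0 of Hixson-Crowell only
# scales k_HC when the data are fractions, so it is fixed at 1 and k_HC
# absorbs the scale; t_end of the biphasic form is pinned to the data span.
.fit_par_info <- function(family, data) {
  t <- data$times; f <- data$fractions
  pos <- f > 1e-6 & t > 0
  loglog <- function() {
    if (sum(pos) >= 2) stats::coef(stats::lm(log(f[pos]) ~ log(t[pos])))
    else c(`(Intercept)` = log(0.05), x = 0.5)
  }
  switch(family,
    higuchi = list(
      start = c(k_H = max(1e-6, sum(f * sqrt(t)) / max(sum(t), 1e-12))),
      lower = c(k_H = 1e-12), upper = c(k_H = Inf)),
    korsmeyer_peppas = {
      cf <- loglog()
      list(start = c(k = max(min(exp(cf[[1]]), 10), 1e-6),
                     n = max(min(cf[[2]], 1.4), 0.05)),
           lower = c(k = 1e-12, n = 1e-6), upper = c(k = Inf, n = 1.5))
    },
    peppas_sahlin = {
      k0 <- max(1e-6, sum(f * sqrt(t)) / max(sum(t), 1e-12))
      list(start = c(k1 = k0, k2 = k0 / 10, m = 0.45),
           lower = c(k1 = 1e-12, k2 = 0, m = 1e-6),
           upper = c(k1 = Inf, k2 = Inf, m = 1.5))
    },
    hixson_crowell = {
      i <- which(f < 0.99)
      k0 <- if (length(i)) {
        j <- max(i)
        (1 - (1 - f[j])^(1 / 3)) / max(t[j], 1e-12)
      } else 1 / max(t[1], 1e-12)
      list(start = c(k_HC = max(k0, 1e-8)),
           lower = c(k_HC = 1e-12), upper = c(k_HC = Inf),
           fixed = c(W0 = 1))
    },
    baker_lonsdale = {
      j <- length(t)
      g <- 1.5 * (1 - (1 - min(f[j], 0.999))^(2 / 3)) - min(f[j], 0.999)
      list(start = c(k_BL = max(g / max(t[j], 1e-12), 1e-10)),
           lower = c(k_BL = 1e-12), upper = c(k_BL = Inf))
    },
    weibull = {
      ok <- f > 1e-6 & f < 0.999 & t > 0
      cf <- if (sum(ok) >= 2)
        stats::coef(stats::lm(log(-log(1 - f[ok])) ~ log(t[ok])))
      else c(log(0.05), 0.8)
      list(start = c(a = max(min(exp(cf[[1]]), 100), 1e-8),
                     b = max(min(cf[[2]], 4.5), 0.05)),
           lower = c(a = 1e-12, b = 1e-6), upper = c(a = Inf, b = 5))
    },
    biphasic_burst_zero_order = {
      te <- max(t)
      list(start = c(burst_fraction = 0.4,
                     burst_rate = 5 / max(te, 1e-12),
                     zero_order_rate = 0.5 / max(te, 1e-12)),
           lower = c(burst_fraction = 1e-6, burst_rate = 1e-9,
                     zero_order_rate = 0),
           upper = c(burst_fraction = 1, burst_rate = Inf,
                     zero_order_rate = Inf),
           fixed = c(t_end = te))
    })
}

#' Fit a release model to observed data by nonlinear least squares
#'
#' Levenberg-Marquardt least squares on the cumulative fraction, with
#' coefficients constrained positive (and the shape exponents bounded:
#' n, m in (0, 1.5], Weibull b in (0, 5]). Information criteria use the
#' Gaussian profile log-likelihood:
#' AIC = n ln(RSS/n) + 2p, BIC = n ln(RSS/n) + p ln(n).
#'
#' A fit is refused when the number of observations does not exceed the
#' number of estimated coefficients. For \code{hixson_crowell} the mass
#' scale \code{W0} is fixed at 1 (only the ratio is identifiable from
#' fraction data); for \code{biphasic_burst_zero_order} the phase end
#' \code{t_end} is pinned to the last observation time.
#'
#' @param data a [release_data()]
#' @param family release model family to fit
#' @param M_inf total dose attached to the returned model [ug]
#' @return object of class \code{release_fit}: fields \code{family},
#'   \code{coefficients}, \code{model} (a [release_model()]), \code{rss},
#'   \code{aic}, \code{bic}, \code{n_obs}, \code{n_par}, \code{converged},
#'   \code{message}
#' @export
fit_release <- function(data, family, M_inf = 1) {
  stopifnot(inherits(data, "release_data"))
  family <- match.arg(family, release_families())
  info <- .fit_par_info(family, data)
  n_par <- length(info$start)
  n_obs <- length(data$times)
  if (n_obs < n_par + 1L)
    stop("under-determined fit: ", n_obs, " observations for ", n_par,
         " coefficient(s); need at least ", n_par + 1L)

  build <- function(par) {
    co <- as.list(c(par, info$fixed))
    release_model(family, co, M_inf = M_inf)
  }
  resid_fn <- function(par) {
    m <- try(build(par), silent = TRUE)
    if (inherits(m, "try-error")) return(rep(1e6, n_obs))
    r <- cumulative_fraction(m, data$times) - data$fractions
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(
    par = info$start, lower = info$lower, upper = info$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  converged <- fit$info %in% 1:4
  rss <- sum(fit$fvec^2)
  if (!converged)
    warning("fit_release(", family, ") did not converge (", fit$message,
            "); final RSS = ", signif(rss, 6))
  # Guard RSS = 0 (noise-free data): the Gaussian log-likelihood degenerates,
  # so floor at machine-level residual variance for finite AIC/BIC.
  rss_ic <- max(rss, n_obs * .Machine$double.eps^2)
  aic <- n_obs * log(rss_ic / n_obs) + 2 * n_par
  bic <- n_obs * log(rss_ic / n_obs) + n_par * log(n_obs)
  structure(list(family = family,
                 coefficients = as.list(c(fit$par, info$fixed)),
                 model = build(fit$par),
                 rss = rss, aic = aic, bic = bic,
                 n_obs = n_obs, n_par = n_par,
                 converged = converged, message = fit$message),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat("<release_fit> ", x$family, "\n", sep = "")
  co <- unlist(x$coefficients)
  cat("  coefficients:",
      paste(names(co), signif(co, 6), sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  RSS = %.6g  AIC = %.4g  BIC = %.4g  (n = %d, p = %d)\n",
              x$rss, x$aic, x$bic, x$n_obs, x$n_par))
  if (!x$converged) cat("  ! not converged:", x$message, "\n")
  invisible(x)
}

#' Serialize a fitted release model to structured text
#'
#' @param fit a [fit_release()] result
#' @param path output file (YAML)
#' @export
write_release_fit <- function(fit, path) {
  stopifnot(inherits(fit, "release_fit"))
  yaml::write_yaml(list(
    family = fit$family,
    coefficients = lapply(fit$coefficients, as.numeric),
    rss = fit$rss, aic = fit$aic, bic = fit$bic,
    n_obs = fit$n_obs, n_par = fit$n_par, converged = fit$converged), path)
  invisible(path)
}

#' Fit several release families and rank them by AIC
#'
#' Each family in turn is fitted with [fit_release()]; families whose fit
#' fails (e.g. under-determined) are skipped and reported. Results are
#' sorted by ascending AIC, ties broken by fewer estimated parameters, then
#' by family name.
#'
#' @param data a [release_data()]
#' @param families character vector of >= 2 family names (default: all)
#' @param M_inf total dose attached to the fitted models [ug]
#' @return list of class \code{release_selection}: \code{fits} (ranked
#'   list of \code{release_fit}), \code{skipped} (named character vector of
#'   failure reasons)
#' @export
select_model <- function(data, families = release_families(), M_inf = 1) {
  stopifnot(inherits(data, "release_data"))
  if (length(families) < 2L)
    stop("select_model() needs at least 2 candidate families")
  families <- vapply(families, match.arg, "", choices = release_families())
  fits <- list(); skipped <- character(0)
  for (fam in families) {
    res <- tryCatch(suppressWarnings(fit_release(data, fam, M_inf = M_inf)),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "release_fit")) fits[[fam]] <- res
    else skipped[fam] <- res
  }
  if (length(fits)) {
    ord <- order(vapply(fits, `[[`, 0, "aic"),
                 vapply(fits, `[[`, 0L, "n_par"),
                 names(fits))
    fits <- fits[ord]
  }
  structure(list(fits = fits, skipped = skipped),
            class = "release_selection")
}

#' @export
print.release_selection <- function(x, ...) {
  cat("<release_selection> ranked by AIC\n")
  for (f in x$fits)
    cat(sprintf("  %-26s AIC = %9.3f  BIC = %9.3f  RSS = %.4g\n",
                f$family, f$aic, f$bic, f$rss))
  if (length(x$skipped))
    for (nm in names(x$skipped))
      cat("  skipped ", nm, ": ", x$skipped[[nm]], "\n", sep = "")
  invisible(x)
}
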