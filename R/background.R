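#' Select the background density sample
#'
#' The background is the lower `fraction` of the normalized cell densities
#' (default 80%), taken as all values at or below the nearest-rank empirical
#' quantile — the ceiling(fraction * n)-th order statistic. Cells above the
#' cutoff are treated as candidate cluster members, not background.
#'
#' @param densities Numeric vector of normalized densities (bounded cells).
#' @param fraction Fraction of the sample to keep, in (0, 1]; default 0.8.
#' @return List with `values` (the background sample) and `cutoff` (the
#'   nearest-rank quantile bounding it).
#' @export
select_background <- function(densities, fraction = 0.8) {
  densities <- densities[!is.na(densities)]
  if (length(densities) == 0L) stop("empty density sample", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  s <- sort(densities)
  cutoff <- s[ceiling(fraction * length(s))]
  list(values = densities[densities <= cutoff], cutoff = cutoff)
}

# model CDF F(t) = P(X <= t) with X s.t. c * X^b ~ chi-square(a)
chisq_model_cdf <- function(t, a, b, c) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::pchisq(c * t[pos]^b, df = a)
  out
}

#' Fit the chi-square background model
#'
#' Fits the three-parameter family F(t) = ChiSqCDF(c * t^b; df = a) to the
#' empirical CDF of the background densities by least squares: parameters
#' minimize the summed squared difference between F and the empirical CDF
#' (Hazen plotting positions (i - 0.5)/n) at the sorted background values.
#' Optimization is bounded L-BFGS-B from a small deterministic grid of
#' starting values; the best achieved objective is reported.
#'
#' @param background Numeric vector of background densities (at least 10
#'   distinct values).
#' @param integer_b If TRUE, profile the fit over integer exponents b = 1..6
#'   instead of fitting b continuously.
#' @return List with `a`, `b`, `c` and `objective` (sum of squared CDF
#'   differences at the optimum).
#' @export
fit_background <- function(background, integer_b = FALSE) {
  background <- background[!is.na(background)]
  if (length(unique(background)) < 10L) {
    stop("need at least 10 distinct background values to fit", call. = FALSE)
  }
  if (any(background <= 0)) stop("densities must be positive", call. = FALSE)
  x_full <- sort(background)
  n <- length(x_full)
  emp_full <- (seq_len(n) - 0.5) / n
  # multi-start stage runs on <= 512 evenly spaced order statistics (the
  # empirical CDF shape is pinned down at that resolution); the winner is
  # then polished against the full sorted sample
  if (n > 512L) {
    keep <- unique(round(seq(1L, n, length.out = 512L)))
    x <- x_full[keep]
    emp <- emp_full[keep]
  } else {
    x <- x_full
    emp <- emp_full
  }

  lower <- c(a = 0.01, b = 0.2, c = 1e-6)
  upper <- c(a = 50, b = 10, c = 10)
  obj <- function(p, b_fixed = NULL) {
    b <- if (is.null(b_fixed)) p[2] else b_fixed
    cc <- if (is.null(b_fixed)) p[3] else p[2]
    sum((chisq_model_cdf(x, p[1], b, cc) - emp)^2)
  }

  starts_a <- c(0.25, 0.5, 1, 2, 5)
  starts_b <- c(0.5, 1, 2, 3, 4, 6)
  # scale start so the model median roughly matches the sample median
  c_for <- function(a, b) stats::qchisq(0.5, a) / stats::median(x)^b

  best <- NULL
  top <- list()   # best few multi-start winners, kept for full-sample polish
  run <- function(par, lo, up, fn) {
    tryCatch(stats::optim(par, fn, method = "L-BFGS-B", lower = lo, upper = up,
                          control = list(maxit = 500)),
             error = function(e) NULL)
  }
  if (integer_b) {
    for (b in 1:6) for (a0 in starts_a) {
      c0 <- min(max(c_for(a0, b), lower["c"]), upper["c"])
      fit <- run(c(a0, c0), lower[c("a", "c")], upper[c("a", "c")],
                 function(p) obj(p, b_fixed = b))
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- list(a = fit$par[1], b = b, c = fit$par[2], value = fit$value)
      }
    }
  } else {
    for (a0 in starts_a) for (b0 in starts_b) {
      c0 <- min(max(c_for(a0, b0), lower["c"]), upper["c"])
      fit <- run(c(a0, b0, c0), lower, upper, obj)
      if (is.null(fit)) next
      top <- c(top, list(list(par = fit$par, value = fit$value)))
      if (is.null(best) || fit$value < best$value) {
        best <- list(a = fit$par[1], b = fit$par[2], c = fit$par[3],
                     value = fit$value)
      }
    }
  }
  if (is.null(best)) stop("background fit failed from every start", call. = FALSE)
  if (!integer_b) {
    # polish the leading basins against the full sorted sample
    obj_full <- function(p) sum((chisq_model_cdf(x_full, p[1], p[2], p[3]) - emp_full)^2)
    top <- top[order(vapply(top, `[[`, numeric(1), "value"))]
    best$value <- obj_full(c(best$a, best$b, best$c))
    for (cand in top[seq_len(min(3, length(top)))]) {
      pol <- run(cand$par, lower, upper, obj_full)
      if (!is.null(pol) && pol$value < best$value) {
        best <- list(a = pol$par[1], b = pol$par[2], c = pol$par[3], value = pol$value)
      }
    }
  } else if (length(x_full) > length(x)) {
    obj_full_b <- function(p) sum((chisq_model_cdf(x_full, p[1], best$b, p[2]) - emp_full)^2)
    pol <- run(c(best$a, best$c), lower[c("a", "c")], upper[c("a", "c")], obj_full_b)
    if (!is.null(pol)) {
      best <- list(a = pol$par[1], b = best$b, c = pol$par[2], value = pol$value)
    }
  }
  list(a = unname(best$a), b = unname(best$b), c = unname(best$c),
       objective = unname(best$value))
}

#' Clustering threshold from a fitted background model
#'
#' Solves F(t*) = significance for the fitted CDF
#' F(t) = ChiSqCDF(c * t^b; df = a) by bracketed root-finding; the returned
#' t* satisfies |F(t*) - significance| <= 1e-8.
#'
#' @param fit List (or `background_fit`) with elements `a`, `b`, `c`.
#' @param significance Significance level in (0, 1); default 0.9.
#' @return The clustering threshold t* on the normalized-density scale.
#' @export
threshold_at <- function(fit, significance = 0.9) {
  if (significance <= 0 || significance >= 1) {
    stop("significance must lie strictly between 0 and 1", call. = FALSE)
  }
  a <- fit$a; b <- fit$b; cc <- fit$c
  stopifnot(a > 0, b > 0, cc > 0)
  f <- function(t) chisq_model_cdf(t, a, b, cc) - significance
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Background fit and clustering threshold in one call
#'
#' Runs [select_background()], [fit_background()] and [threshold_at()] on a
#' tessellation's normalized densities.
#'
#' @param tess A `voronoi_tessellation` with normalized densities, or a bare
#'   numeric vector of densities.
#' @param fraction Background fraction; default 0.8.
#' @param significance Significance level for the threshold; default 0.9.
#' @param integer_b Passed to [fit_background()].
#' @return A `background_fit` object: `a`, `b`, `c`, `background_fraction`,
#'   `background_cutoff`, `significance`, `threshold`, `objective`,
#'   `n_background`.
#' @export
background_fit <- function(tess, fraction = 0.8, significance = 0.9,
                           integer_b = FALSE) {
  densities <- if (inherits(tess, "voronoi_tessellation")) {
    tess$cells$normalized_density[tess$cells$bounded]
  } else {
    tess
  }
  bg <- select_background(densities, fraction)
  fit <- fit_background(bg$values, integer_b = integer_b)
  out <- list(
    a = fit$a, b = fit$b, c = fit$c,
    background_fraction = fraction,
    background_cutoff = bg$cutoff,
    significance = significance,
    threshold = threshold_at(fit, significance),
    objective = fit$objective,
    n_background = length(bg$values)
  )
  class(out) <- "background_fit"
  out
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Chi-square background fit\n",
           "  a = %.4g, b = %.4g, c = %.4g (objective %.3g)\n",
           "  background: lower %.0f%% (n = %d, cutoff %.4g)\n",
           "  clustering threshold at %.0f%% significance: %.4g\n"),
    x$a, x$b, x$c, x$objective,
    100 * x$background_fraction, x$n_background, x$background_cutoff,
    100 * x$significance, x$threshold))
  invisible(x)
}

#' Write a background-fit report as JSON
#'
#' @param fit A `background_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
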