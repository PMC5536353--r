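#' Two-Gaussian fit of a psoralen gel lane profile
#'
#' Psoralen crosslinking separates nucleosome-free ("active", low mobility)
#' from nucleosomal ("inactive", high mobility) rDNA on a gel. This fits the
#' 1-D lane intensity profile with an optional linear baseline plus two
#' Gaussian components by constrained nonlinear least squares and labels the
#' component at the smaller migration coordinate (lower mobility) as the
#' active one. Component areas are `amplitude * sigma * sqrt(2*pi)`; areas,
#' not amplitudes, quantify each fraction.
#'
#' Initialization mimics automatic peak picking: the two largest local maxima
#' of a lightly smoothed profile seed the centers, and the half-width at
#' half-maximum seeds the widths. If only one peak is detectable the fit
#' falls back to a flagged single-component fit with the other area set to 0.
#'
#' @param position Monotone migration coordinate (arbitrary units).
#' @param intensity Non-negative intensities (residual noise may dip below 0
#'   after baseline subtraction).
#' @param baseline `"linear"` (default; gels have sloping background) or
#'   `"none"`.
#' @param components `"auto"` (default: one or two components depending on
#'   how many peaks are detectable), or `"one"`/`"two"` to force the model
#'   structure (used by the bootstrap, which must refit the same model).
#' @return An object of class `gel_fit`: per-component centers `mu`, widths
#'   `sigma`, amplitudes and areas (named `a` = active/low mobility, `i` =
#'   inactive/high mobility), baseline coefficients, `residual_rms`,
#'   `single_component` flag, the data, and the underlying `nls` fit.
#' @examples
#' x <- seq(0, 1, length.out = 300)
#' y <- 0.64 * dnorm(x, 0.40, 0.05) + 0.36 * dnorm(x, 0.60, 0.05)
#' fit <- fit_gel_profile(x, y, baseline = "none")
#' active_fraction(fit)
#' @export
fit_gel_profile <- function(position, intensity, baseline = c("linear", "none"),
                            components = c("auto", "one", "two")) {
  baseline <- match.arg(baseline)
  components <- match.arg(components)
  stopifnot(length(position) == length(intensity))
  if (length(position) < 20L)
    stop("need at least 20 sample points to fit a lane profile")
  if (is.unsorted(position))
    stop("position must be a monotone migration coordinate")
  x <- as.numeric(position); y <- as.numeric(intensity)

  # light smoothing for peak picking only
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  ismax <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n], FALSE)
  pk <- which(ismax)
  pk <- pk[order(-ys[pk])]
  # enforce some separation between the two seeds
  sep <- (max(x) - min(x)) / 20
  if (length(pk) > 1L) {
    pk2 <- pk[abs(x[pk] - x[pk[1L]]) > sep]
    pk <- if (length(pk2)) c(pk[1L], pk2[1L]) else pk[1L]
  }
  single <- switch(components,
    auto = length(pk) < 2L,
    one = TRUE,
    two = FALSE)
  if (!single && length(pk) < 2L) {
    # forced two-component fit with one detectable peak: seed the second
    # component at the strongest signal away from the first
    far <- which(abs(x - x[pk[1L]]) > sep)
    if (!length(far)) stop("cannot seed a second component on this trace")
    pk <- c(pk[1L], far[which.max(ys[far])])
  }

  hwhm <- function(idx) {
    half <- ys[idx] / 2
    r <- idx; while (r < n && ys[r] > half) r <- r + 1L
    l <- idx; while (l > 1L && ys[l] > half) l <- l - 1L
    w <- min(abs(x[r] - x[idx]), abs(x[idx] - x[l]))
    max(w / sqrt(2 * log(2)), (max(x) - min(x)) / 100)
  }

  gauss <- function(x, h, mu, s) h * exp(-(x - mu)^2 / (2 * s^2))
  rng <- max(x) - min(x)
  has_base <- baseline == "linear"
  n_gauss <- if (single) 1L else 2L
  model <- function(p, x) {
    y <- if (has_base) p[["c0"]] + p[["c1"]] * x else 0
    y <- y + gauss(x, p[["h1"]], p[["mu1"]], p[["s1"]])
    if (n_gauss == 2L) y <- y + gauss(x, p[["h2"]], p[["mu2"]], p[["s2"]])
    y
  }

  if (single) {
    par <- c(h1 = max(ys[pk[1L]], 1e-12), mu1 = x[pk[1L]], s1 = hwhm(pk[1L]))
    lower <- c(h1 = 0, mu1 = min(x), s1 = 1e-9)
    upper <- c(h1 = Inf, mu1 = max(x), s1 = rng)
  } else {
    mu0 <- sort(x[pk[1:2]])
    i1 <- pk[which(x[pk] == mu0[1L])][1L]
    i2 <- pk[which(x[pk] == mu0[2L])][1L]
    par <- c(h1 = max(ys[i1], 1e-12), mu1 = mu0[1L], s1 = hwhm(i1),
             h2 = max(ys[i2], 1e-12), mu2 = mu0[2L], s2 = hwhm(i2))
    lower <- c(h1 = 0, mu1 = min(x), s1 = 1e-9,
               h2 = 0, mu2 = min(x), s2 = 1e-9)
    upper <- c(h1 = Inf, mu1 = max(x), s1 = rng,
               h2 = Inf, mu2 = max(x), s2 = rng)
  }
  if (has_base) {
    par <- c(c0 = min(y), c1 = 0, par)
    lower <- c(c0 = -Inf, c1 = -Inf, lower)
    upper <- c(c0 = Inf, c1 = Inf, upper)
  }
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper,
    fn = function(p, x, y) model(p, x) - y, x = x, y = y,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0L || fit$info == 5L)
    stop("gel fit did not converge: ", fit$message)
  cf <- fit$par

  if (single) {
    comp <- data.frame(
      component = c("a", "i"),
      mu = c(cf[["mu1"]], NA),
      sigma = c(cf[["s1"]], NA),
      amplitude = c(cf[["h1"]], 0),
      area = c(cf[["h1"]] * cf[["s1"]] * sqrt(2 * pi), 0))
  } else {
    # label by migration order: smaller mu = lower mobility = active
    ord <- order(c(cf[["mu1"]], cf[["mu2"]]))
    h <- c(cf[["h1"]], cf[["h2"]])[ord]
    mu <- c(cf[["mu1"]], cf[["mu2"]])[ord]
    s <- c(cf[["s1"]], cf[["s2"]])[ord]
    comp <- data.frame(
      component = c("a", "i"), mu = mu, sigma = s, amplitude = h,
      area = h * s * sqrt(2 * pi))
  }
  structure(list(
    components = comp,
    baseline = baseline,
    baseline_coef = if (has_base)
      c(intercept = cf[["c0"]], slope = cf[["c1"]])
      else c(intercept = 0, slope = 0),
    residual_rms = sqrt(mean(fit$fvec^2)),
    single_component = single,
    data = data.frame(position = x, intensity = y),
    fitted_values = model(cf, x),
    optim = fit), class = "gel_fit")
}

#' @export
print.gel_fit <- function(x, ...) {
  cat("Two-Gaussian gel lane fit",
      if (x$single_component) " (flagged: single detectable peak)", "\n", sep = "")
  comp <- x$components
  tot <- sum(comp$area)
  for (k in seq_len(nrow(comp))) {
    lab <- if (comp$component[k] == "a") "active  (low mobility) " else "inactive (high mobility)"
    if (is.na(comp$mu[k])) {
      cat(sprintf("  %s: area 0\n", lab))
    } else {
      cat(sprintf("  %s: mu = %.4g, sigma = %.4g, area = %.4g (%.1f%%)\n",
                  lab, comp$mu[k], comp$sigma[k], comp$area[k],
                  100 * comp$area[k] / tot))
    }
  }
  cat(sprintf("  baseline: %s; residual RMS = %.4g\n", x$baseline, x$residual_rms))
  invisible(x)
}

#' @export
summary.gel_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying Levenberg-Marquardt fit:\n")
  print(summary(object$optim))
  invisible(object)
}

#' @export
coef.gel_fit <- function(object, ...) object$optim$par

#' @export
fitted.gel_fit <- function(object, ...) object$fitted_values

#' @export
residuals.gel_fit <- function(object, ...) {
  object$data$intensity - object$fitted_values
}

#' @export
predict.gel_fit <- function(object, position = NULL, ...) {
  if (is.null(position)) return(stats::fitted(object$nls))
  comp <- object$components
  b <- object$baseline_coef
  y <- b[["intercept"]] + b[["slope"]] * position
  for (k in seq_len(nrow(comp))) {
    if (!is.na(comp$mu[k]))
      y <- y + comp$amplitude[k] *
        exp(-(position - comp$mu[k])^2 / (2 * comp$sigma[k]^2))
  }
  y
}

#' @export
plot.gel_fit <- function(x, ...) {
  plot(x$data$position, x$data$intensity, type = "l", col = "grey50",
       xlab = "migration (a.u.)", ylab = "intensity", ...)
  xs <- seq(min(x$data$position), max(x$data$position), length.out = 400)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  invisible(x)
}

#' Active rDNA fraction from a gel fit
#'
#' The active fraction is the area of the low-mobility component over the
#' total fitted Gaussian area, `A_a / (A_a + A_i)`. Its standard error is
#' estimated by a seeded residual-resampling bootstrap: residuals of the fit
#' are resampled with replacement, added back to the fitted curve, and the
#' profile refit.
#'
#' @param fit A `gel_fit`.
#' @param n_bootstrap Number of bootstrap replicates (0 = no SE).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `active_fraction`: list with `value`, `se`
#'   (NA when `n_bootstrap = 0`), `n_bootstrap`.
#' @export
active_fraction <- function(fit, n_bootstrap = 0L, seed = NULL) {
  stopifnot(inherits(fit, "gel_fit"))
  areas <- fit$components$area
  if (sum(areas) <= 0) stop("both component areas are zero")
  value <- areas[fit$components$component == "a"] / sum(areas)
  se <- NA_real_
  if (n_bootstrap > 0L) {
    res <- fit$data$intensity - fit$fitted_values
    fitv <- fit$fitted_values
    x <- fit$data$position
    structure_arg <- if (fit$single_component) "one" else "two"
    reps <- with_seed(seed, vapply(seq_len(n_bootstrap), function(b) {
      ystar <- fitv + sample(res, length(res), replace = TRUE)
      f <- try(fit_gel_profile(x, ystar, baseline = fit$baseline,
                               components = structure_arg), silent = TRUE)
      if (inherits(f, "try-error")) return(NA_real_)
      a <- f$components$area
      a[f$components$component == "a"] / sum(a)
    }, numeric(1L)))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  structure(list(value = value, se = se, n_bootstrap = n_bootstrap),
            class = "active_fraction")
}

#' @export
print.active_fraction <- function(x, ...) {
  cat(sprintf("active rDNA fraction: %.3f", x$value))
  if (!is.na(x$se))
    cat(sprintf(" +/- %.3f (bootstrap SE, %d replicates)", x$se, x$n_bootstrap))
  cat("\n")
  invisible(x)
}

#' Read and write gel lane traces
#'
#' Traces are two-column TSVs with a header: `position` (monotone migration
#' coordinate) and `intensity`.
#'
#' @param position,intensity Trace vectors.
#' @param file Path.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_lane_tsv <- function(position, intensity, file) {
  utils::write.table(data.frame(position = position, intensity = intensity),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname trace_io
#' @export
read_lane_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
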