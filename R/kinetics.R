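#' A single-well fluorescence kinetic curve
#'
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric fluorescence intensities (arbitrary units),
#'   same length as `times`.
#' @param well_id Optional well label.
#' @return An object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(times, intensities, well_id = NA_character_) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities) || length(times) < 2L)
    stop("times and intensities must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, intensities = intensities,
                 well_id = as.character(well_id)),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> %s: %d points, t = [%g, %g] s, I = [%g, %g]\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' A replicate set of kinetic curves sharing a blank
#'
#' Bundles the replicate wells of one (variant, pH) condition with the
#' negative-control (blank) curve measured on the same time grid.  When
#' several blank wells are supplied they are averaged pointwise into a
#' single blank.
#'
#' @param curves List of [kinetic_curve()] objects on a common time grid.
#' @param blank A [kinetic_curve()], or list of them, on the same grid.
#' @param variant,pH Condition labels.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(curves, blank, variant = NA_character_, pH = NA_real_) {
  if (inherits(curves, "kinetic_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "kinetic_curve")))
  if (is.list(blank) && !inherits(blank, "kinetic_curve")) {
    stopifnot(all(vapply(blank, inherits, TRUE, "kinetic_curve")))
    for (b in blank) check_same_grid(blank[[1]]$times, b$times)
    blank <- kinetic_curve(blank[[1]]$times,
                           rowMeans(vapply(blank, `[[`, numeric(length(blank[[1]]$times)),
                                           "intensities")),
                           well_id = "blank(avg)")
  }
  stopifnot(inherits(blank, "kinetic_curve"))
  for (cv in curves) check_same_grid(blank$times, cv$times)
  structure(list(curves = curves, blank = blank,
                 variant = as.character(variant), pH = as.numeric(pH)),
            class = "replicate_set")
}

check_same_grid <- function(t1, t2) {
  if (length(t1) != length(t2) || any(abs(t1 - t2) > 1e-9 * (1 + abs(t1))))
    stop("curves are not on a common time grid")
  invisible(TRUE)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %s @ pH %s: %d curves x %d points\n",
              x$variant, format(x$pH), length(x$curves), length(x$blank$times)))
  invisible(x)
}

#' Subtract the blank signal from every replicate
#'
#' Pointwise subtraction of the blank curve (the ThT signal of the
#' peptide-free negative control) from each replicate; times are unchanged.
#'
#' @param set A [replicate_set()].
#' @return A `replicate_set` with corrected intensities and a zeroed blank.
#' @export
subtract_blank <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  b <- set$blank$intensities
  set$curves <- lapply(set$curves, function(cv) {
    cv$intensities <- cv$intensities - b
    cv
  })
  set$blank$intensities <- set$blank$intensities - b
  attr(set, "blank_subtracted") <- TRUE
  set
}

#' Normalise a curve to its end-point plateau
#'
#' Divides the intensities by the mean of the final `plateau_fraction` of
#' points, so the plateau of the normalised curve averages exactly 1.  The
#' extent of "the end point (plateau)" is a processing choice: the default
#' uses the final 10% of samples, which is robust to plateau drift while
#' still averaging several points.
#'
#' @param curve A [kinetic_curve()] (blank-subtracted).
#' @param plateau_fraction Fraction of trailing points defining the plateau
#'   (default 0.1; at least one point is always used).
#' @return Normalised `kinetic_curve`.
#' @export
normalize_to_plateau <- function(curve, plateau_fraction = 0.1) {
  stopifnot(inherits(curve, "kinetic_curve"),
            plateau_fraction > 0, plateau_fraction <= 1)
  n <- length(curve$intensities)
  k <- max(1L, ceiling(plateau_fraction * n))
  m <- mean(curve$intensities[(n - k + 1L):n])
  if (!is.finite(m) || m <= 0)
    stop("plateau mean is not positive; curve looks like a non-aggregator ",
         "(route it through classify_assembly instead)")
  curve$intensities <- curve$intensities / m
  curve
}

#' Interpolated half-time of a normalised aggregation curve
#'
#' Finds the first upward crossing of 0.5 (after the curve's global
#' minimum, to avoid counting transient downward noise spikes as a
#' crossing) and linearly interpolates between the bracketing samples:
#' `t50 = t1 + (t2 - t1) * (0.5 - y1) / (y2 - y1)`, where `t1`/`t2` are the
#' sample times below and above the crossing and `y1`/`y2` the normalised
#' intensities there.
#'
#' @param curve A normalised [kinetic_curve()].
#' @return Object of class `t50_estimate`: list with `t50` (seconds) and the
#'   bracketing `t1`, `t2`, `y1`, `y2`.
#' @examples
#' cv <- kinetic_curve(c(4, 6), c(0, 1))
#' compute_t50(cv)$t50 # 5
#' @export
compute_t50 <- function(curve) {
  stopifnot(inherits(curve, "kinetic_curve"))
  y <- curve$intensities; t <- curve$times
  i0 <- which.min(y)
  if (y[i0] >= 0.5)
    stop("degenerate start: curve never falls below 0.5, no upward crossing exists")
  idx <- seq(i0, length(y))
  above <- which(y[idx] >= 0.5)
  if (!length(above))
    stop("no crossing: curve never reaches 0.5 of its plateau (no-fibrils candidate)")
  i2 <- idx[above[1]]
  i1 <- i2 - 1L
  t1 <- t[i1]; t2 <- t[i2]; y1 <- y[i1]; y2 <- y[i2]
  t50 <- t1 + (t2 - t1) * (0.5 - y1) / (y2 - y1)
  structure(list(t50 = t50, t1 = t1, t2 = t2, y1 = y1, y2 = y2),
            class = "t50_estimate")
}

#' @export
print.t50_estimate <- function(x, ...) {
  cat(sprintf("<t50_estimate> t50 = %.4g s (bracket [%g, %g] s, y [%.3f, %.3f])\n",
              x$t50, x$t1, x$t2, x$y1, x$y2))
  invisible(x)
}

#' Histogram/Gaussian summary of replicate half-times
#'
#' Reproduces the plate-level summary statistic: the replicate t50 values
#' are binned into `n_bins` equal-width bins over their range, a Gaussian
#' `a * exp(-(x - mu)^2 / (2 sigma^2))` is least-squares fitted to the bin
#' centres and counts, and `mu` / `|sigma|` are reported as the mean and SD.
#' The fit is initialised at the sample mean/SD with amplitude equal to the
#' tallest bin.  If the fit fails to converge, explains less than half the
#' count variance (R^2 < 0.5), or returns a sigma wider than the data
#' range, the summary falls back to the sample mean and SD and flags the
#' poor fit with a warning.  Identical values are returned directly with
#' SD 0 (no fit is attempted on a degenerate histogram).
#'
#' @param t50s Numeric vector of half-times in seconds (>= 5 finite values,
#'   unless all values are identical).
#' @param n_bins Number of histogram bins (default 10).
#' @return Object of class `t50_summary`: `mean_t50`, `sd_t50`, `n_curves`,
#'   `n_bins`, `breaks`, `counts`, `method` (`"gaussian_fit"` or
#'   `"sample_moments"`).
#' @export
summarize_t50 <- function(t50s, n_bins = 10) {
  t50s <- t50s[is.finite(t50s)]
  stopifnot(n_bins >= 2)
  if (length(t50s) && max(t50s) == min(t50s))
    return(structure(list(mean_t50 = t50s[1], sd_t50 = 0,
                          n_curves = length(t50s), n_bins = n_bins,
                          breaks = NULL, counts = NULL,
                          method = "degenerate"),
                     class = "t50_summary"))
  if (length(t50s) < 5L) stop("need at least 5 finite t50 values")
  breaks <- seq(min(t50s), max(t50s), length.out = n_bins + 1L)
  h <- graphics::hist(t50s, breaks = breaks, plot = FALSE)
  centers <- h$mids; counts <- h$counts
  m0 <- mean(t50s); s0 <- stats::sd(t50s); a0 <- max(counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ a * exp(-(centers - mu)^2 / (2 * sigma^2)),
                      start = list(a = a0, mu = m0, sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- FALSE
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    ss_res <- sum(stats::resid(fit)^2)
    ss_tot <- sum((counts - mean(counts))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
    ok <- r2 >= 0.5 && abs(cf[["sigma"]]) <= diff(range(t50s))
  }
  if (ok) {
    mean_t50 <- cf[["mu"]]; sd_t50 <- abs(cf[["sigma"]]); method <- "gaussian_fit"
  } else {
    warning("Gaussian fit to the t50 histogram was poor; ",
            "falling back to sample mean/SD")
    mean_t50 <- m0; sd_t50 <- s0; method <- "sample_moments"
  }
  structure(list(mean_t50 = mean_t50, sd_t50 = sd_t50,
                 n_curves = length(t50s), n_bins = n_bins,
                 breaks = breaks, counts = counts, method = method),
            class = "t50_summary")
}

#' @export
print.t50_summary <- function(x, ...) {
  cat(sprintf("<t50_summary> mean t50 = %.4g s, SD = %.4g s (n = %d, %s)\n",
              x$mean_t50, x$sd_t50, x$n_curves, x$method))
  invisible(x)
}

#' Call a replicate set as fibril-forming or not
#'
#' Operationalises the end-point reading of the plate: the set is called
#' `fibrils` when the median final-plateau signal of the blank-subtracted
#' replicates exceeds `noise_k` times the noise scale of the early
#' baseline; otherwise `no_fibrils`, right-censored at the last observed
#' time point (peptides with no visible fibrils at the end of the
#' incubation are reported as "t50 greater than the incubation time"
#' rather than with a numeric t50).
#'
#' @param set A blank-subtracted [replicate_set()] with >= 3 curves.
#' @param noise_k Multiplier on the baseline SD (default 5).
#' @param baseline_fraction,plateau_fraction Fractions of leading/trailing
#'   points defining baseline and plateau windows (default 0.1 each).
#' @return Object of class `assembly_call`: `outcome` (`"fibrils"` or
#'   `"no_fibrils"`), `censored_at` (seconds; `NA` when fibrils),
#'   `plateau_median`, `baseline_sd`.
#' @export
classify_assembly <- function(set, noise_k = 5, baseline_fraction = 0.1,
                              plateau_fraction = 0.1) {
  stopifnot(inherits(set, "replicate_set"))
  if (length(set$curves) < 3L)
    stop("insufficient replicates: need at least 3 curves for an assembly call")
  n <- length(set$blank$times)
  kb <- max(2L, ceiling(baseline_fraction * n))
  kp <- max(1L, ceiling(plateau_fraction * n))
  base_sd <- stats::median(vapply(set$curves, function(cv)
    stats::sd(cv$intensities[1:kb]), 1))
  plateau <- stats::median(vapply(set$curves, function(cv)
    mean(cv$intensities[(n - kp + 1L):n]), 1))
  fib <- plateau > noise_k * max(base_sd, .Machine$double.eps)
  structure(list(outcome = if (fib) "fibrils" else "no_fibrils",
                 censored_at = if (fib) NA_real_ else max(set$blank$times),
                 plateau_median = plateau, baseline_sd = base_sd),
            class = "assembly_call")
}

#' @export
print.assembly_call <- function(x, ...) {
  if (x$outcome == "fibrils")
    cat(sprintf("<assembly_call> fibrils (plateau %.3g, baseline SD %.3g)\n",
                x$plateau_median, x$baseline_sd))
  else
    cat(sprintf("<assembly_call> no fibrils, censored at %g s\n", x$censored_at))
  invisible(x)
}

#' Full plate pipeline: blank correction to t50 summary
#'
#' Convenience wrapper chaining [subtract_blank()], [classify_assembly()],
#' per-curve [normalize_to_plateau()] + [compute_t50()] and
#' [summarize_t50()].  Sets whose curves never rise above the noise floor
#' are returned as censored assembly calls with no t50 summary.
#'
#' @param set A [replicate_set()].
#' @param n_bins Histogram bins for [summarize_t50()].
#' @param plateau_fraction Passed to [normalize_to_plateau()].
#' @param noise_k Passed to [classify_assembly()].
#' @return List with `call` (an `assembly_call`), `summary` (a
#'   `t50_summary` or `NULL`), and `t50s` (per-curve values).
#' @export
process_replicates <- function(set, n_bins = 10, plateau_fraction = 0.1,
                               noise_k = 5) {
  set <- subtract_blank(set)
  call <- classify_assembly(set, noise_k = noise_k,
                            plateau_fraction = plateau_fraction)
  if (call$outcome == "no_fibrils")
    return(list(call = call, summary = NULL, t50s = numeric()))
  t50s <- vapply(set$curves, function(cv)
    compute_t50(normalize_to_plateau(cv, plateau_fraction))$t50, 1)
  list(call = call, summary = summarize_t50(t50s, n_bins), t50s = t50s)
}
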