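#' FRAP bleach-recovery trace
#'
#' Container for a raw fluorescence-recovery-after-photobleaching series:
#' timestamps (possibly non-uniform, as acquired with adaptive intervals),
#' the bleached-ROI intensity, a background ROI, and an optional unbleached
#' reference ROI used for acquisition-photobleach correction. The first
#' `n_pre` frames precede the laser fire (typically 3 before and 25 after).
#'
#' @param time_s strictly increasing timestamps in seconds.
#' @param roi bleached-ROI intensity.
#' @param background background-ROI intensity (scalar or per-frame).
#' @param reference unbleached reference-ROI intensity, or `NULL`.
#' @param n_pre number of pre-bleach frames (>= 1).
#' @return a data frame of class `frap_trace`.
#' @export
frap_trace <- function(time_s, roi, background = 0, reference = NULL,
                       n_pre = 3L) {
  n <- length(time_s)
  stopifnot(n >= n_pre + 2L, length(roi) == n, n_pre >= 1L)
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (length(background) == 1L) background <- rep(background, n)
  if (!is.null(reference) && length(reference) != n)
    stop("reference must match the trace length")
  stopifnot(all(is.finite(roi)), all(is.finite(background)))
  out <- data.frame(time_s = time_s, roi = roi, background = background)
  if (!is.null(reference)) out$reference <- reference
  attr(out, "n_pre") <- as.integer(n_pre)
  class(out) <- c("frap_trace", class(out))
  out
}

#' Simulate a FRAP trace with known ground truth
#'
#' Generates a raw bleach-recovery series whose normalised form follows the
#' one-phase association model exactly: pre-bleach frames at a constant
#' level, an instantaneous bleach removing `bleach_depth` of the signal,
#' then recovery of the mobile fraction with half-time `t_half_true_s`.
#' Acquisition photobleaching decays both the ROI and the reference ROI
#' multiplicatively per frame; Gaussian noise is added last.
#'
#' @param mobile_fraction_true true mobile fraction, in % of bleached signal.
#' @param t_half_true_s true recovery half-time, seconds.
#' @param bleach_depth fraction of the pre-bleach signal removed by the
#'   laser (default 0.5, i.e. ~50% bleaching efficiency).
#' @param n_pre,n_post frames before/after the bleach (defaults 3 and 25).
#' @param dt_s frame interval (scalar), a length-`n_pre + n_post` vector of
#'   strictly increasing timestamps, or `NULL` (default) for adaptive
#'   intervals: pre-bleach frames 0.5 s apart, then post-bleach intervals
#'   starting at 0.25 s and growing by 22% per frame, so slow recoveries
#'   still reach their plateau within the series.
#' @param pre_level pre-bleach ROI intensity (arbitrary units).
#' @param background_level constant background added to all ROIs.
#' @param acquisition_bleach_rate per-frame multiplicative decay (0 = none).
#' @param noise_sd Gaussian noise sd as a fraction of `pre_level`.
#' @param seed RNG seed.
#' @return a [frap_trace()] with the truth recorded in attribute `"truth"`.
#' @export
simulate_frap_trace <- function(mobile_fraction_true, t_half_true_s,
                                bleach_depth = 0.5, n_pre = 3L, n_post = 25L,
                                dt_s = NULL, pre_level = 1000,
                                background_level = 50,
                                acquisition_bleach_rate = 0,
                                noise_sd = 0, seed = 1L) {
  stopifnot(mobile_fraction_true >= 0, mobile_fraction_true <= 100,
            t_half_true_s > 0, bleach_depth > 0, bleach_depth <= 1,
            n_pre >= 1L, n_post >= 2L)
  n <- n_pre + n_post
  time_s <- if (is.null(dt_s)) {
    cumsum(c(0, rep(0.5, n_pre), 0.25 * 1.22^(0:(n_post - 2L))))
  } else if (length(dt_s) == 1L) (seq_len(n) - 1L) * dt_s else dt_s
  if (length(time_s) != n || any(diff(time_s) <= 0))
    stop("dt_s must be NULL, a scalar interval or strictly increasing timestamps")
  t_post <- time_s[(n_pre + 1L):n] - time_s[n_pre + 1L]
  k <- log(2) / t_half_true_s
  rel <- c(rep(1, n_pre),
           (1 - bleach_depth) +
             bleach_depth * (mobile_fraction_true / 100) * (1 - exp(-k * t_post)))
  decay <- (1 - acquisition_bleach_rate)^(seq_len(n) - 1L)
  roi <- background_level + pre_level * rel * decay
  ref <- background_level + pre_level * decay
  # noise applies to the point ROI only: background and reference ROIs
  # average many pixels, so their per-frame noise is negligible by comparison
  with_seed(derive_seed(seed, "frap-noise"), {
    if (noise_sd > 0) roi <- roi + stats::rnorm(n, 0, noise_sd * pre_level)
  })
  tr <- frap_trace(time_s, roi, background = background_level,
                   reference = ref, n_pre = n_pre)
  attr(tr, "truth") <- list(mobile_fraction = mobile_fraction_true,
                            t_half_s = t_half_true_s,
                            bleach_depth = bleach_depth)
  tr
}

#' Background-correct, photobleach-correct and normalise a FRAP trace
#'
#' Subtracts the background ROI, divides by the background-corrected
#' reference ROI scaled to its pre-bleach mean (double normalisation; the
#' correction is skipped with a flag when no reference is present), then
#' maps intensities linearly so that the first post-bleach value is exactly
#' 0% and the highest pre-bleach value exactly 100%.
#'
#' @param trace a [frap_trace()].
#' @return a data frame of class `frap_norm` with columns `x` (seconds from
#'   the first post-bleach frame; negative for pre-bleach frames) and `y`
#'   (relative fluorescence, %). Attributes: `n_pre`, `corrections`
#'   (character), `bleach_depth_raw` and `qc_flags` (flags insufficient
#'   bleach when the first post-bleach raw value exceeds 80% of the
#'   pre-bleach mean).
#' @export
correct_and_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  n_pre <- attr(trace, "n_pre")
  n <- nrow(trace)
  v <- trace$roi - trace$background
  corrections <- "background"
  if (!is.null(trace$reference)) {
    ref <- trace$reference - trace$background
    if (any(ref <= 0)) stop("reference ROI does not exceed background")
    ref <- ref / mean(ref[seq_len(n_pre)])
    v <- v / ref
    corrections <- c(corrections, "photobleach")
  } else {
    corrections <- c(corrections, "photobleach-skipped")
  }
  pre <- v[seq_len(n_pre)]
  first_post <- v[n_pre + 1L]
  top <- max(pre)
  if (top == first_post) stop("no bleach detected: first post-bleach value equals the pre-bleach maximum")
  # grouping makes the anchors exact in floating point: x/x = 1
  y <- 100 * ((v - first_post) / (top - first_post))
  x <- trace$time_s - trace$time_s[n_pre + 1L]
  raw_pre_mean <- mean(trace$roi[seq_len(n_pre)] - trace$background[seq_len(n_pre)])
  raw_first_post <- trace$roi[n_pre + 1L] - trace$background[n_pre + 1L]
  depth_raw <- 1 - raw_first_post / raw_pre_mean
  qc <- character()
  if (raw_first_post > 0.8 * raw_pre_mean) qc <- c(qc, "insufficient_bleach")
  out <- data.frame(x = x, y = y)
  attr(out, "n_pre") <- n_pre
  attr(out, "corrections") <- corrections
  attr(out, "bleach_depth_raw") <- depth_raw
  attr(out, "qc_flags") <- qc
  class(out) <- c("frap_norm", class(out))
  out
}

#' Fit the one-phase association model to a normalised FRAP trace
#'
#' Nonlinear least squares of \deqn{Y = Y_0 + (plateau - Y_0)(1 - e^{-Kx})}
#' on the post-bleach points only, with x = 0 at the first post-bleach
#' frame. Reports the mobile fraction (plateau - Y0, %) and half-time of
#' recovery (ln 2 / K, seconds). Non-convergence yields a flagged result,
#' never a silent number.
#'
#' @param norm a `frap_norm` from [correct_and_normalize()], or any data
#'   frame with columns `x`, `y` (post-bleach points at `x >= 0`).
#' @param bounds list with elements `Y0`, `plateau`, `K`, each a length-2
#'   numeric range used as box constraints.
#' @return an object of class `frap_fit`: list with `coefficients`
#'   (`Y0, plateau, K`), `mobile_fraction`, `t_half_s`, `r_squared`,
#'   `converged`, `flags`, and the fitted points.
#' @seealso [summarize_frap_group()]
#' @examples
#' x <- seq(0, 12, by = 0.5)
#' y <- 60 * (1 - exp(-0.3466 * x))
#' fit <- fit_one_phase(data.frame(x = x, y = y))
#' coef(fit)
#' fit$t_half_s
#' @export
fit_one_phase <- function(norm,
                          bounds = list(Y0 = c(-20, 20), plateau = c(0, 150),
                                        K = c(1e-6, 10))) {
  df <- data.frame(x = norm$x, y = norm$y)
  df <- df[df$x >= 0, ]
  if (nrow(df) < 5L) stop("need at least 5 post-bleach points")
  flags <- attr(norm, "qc_flags") %||% character()

  if (all(abs(df$y) < 1e-9)) {
    return(new_frap_fit(c(Y0 = 0, plateau = 0, K = NA_real_),
                        r_squared = 1, converged = TRUE,
                        flags = c(flags, "no_recovery_K_undefined"), data = df))
  }

  # crude scan for the time to half of the apparent plateau
  plateau0 <- mean(utils::tail(df$y, 3L))
  y00 <- df$y[1L]
  half_level <- y00 + (plateau0 - y00) / 2
  idx <- which(df$y >= half_level)
  t_half0 <- if (length(idx) && df$x[min(idx)] > 0) df$x[min(idx)] else
    max(df$x) / 4
  start <- list(Y0 = min(max(y00, bounds$Y0[1L]), bounds$Y0[2L]),
                plateau = min(max(plateau0, bounds$plateau[1L]), bounds$plateau[2L]),
                K = min(max(log(2) / t_half0, bounds$K[1L]), bounds$K[2L]))

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Y0 + (plateau - Y0) * (1 - exp(-K * x)),
                      data = df, start = start,
                      lower = c(bounds$Y0[1L], bounds$plateau[1L], bounds$K[1L]),
                      upper = c(bounds$Y0[2L], bounds$plateau[2L], bounds$K[2L]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_frap_fit(c(Y0 = NA_real_, plateau = NA_real_, K = NA_real_),
                        r_squared = NA_real_, converged = FALSE,
                        flags = c(flags, paste0("fit_failed: ", conditionMessage(fit))),
                        data = df))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$y - mean(df$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  converged <- is.finite(cf[["K"]]) && cf[["K"]] > 0
  if (!converged) flags <- c(flags, "nonpositive_rate")
  new_frap_fit(cf, r_squared = r2, converged = converged, flags = flags,
               data = df)
}

new_frap_fit <- function(cf, r_squared, converged, flags, data) {
  k <- cf[["K"]]
  structure(list(coefficients = cf,
                 mobile_fraction = unname(cf[["plateau"]] - cf[["Y0"]]),
                 t_half_s = if (is.finite(k) && k > 0) log(2) / k else NA_real_,
                 r_squared = r_squared, converged = converged,
                 flags = flags, data = data),
            class = "frap_fit")
}

#' @exportS3Method coef frap_fit
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
print.frap_fit <- function(x, digits = 4, ...) {
  cat("One-phase association FRAP fit\n")
  cat(sprintf("  Y = Y0 + (plateau - Y0) * (1 - exp(-K x)), %d post-bleach points\n",
              nrow(x$data)))
  cat(sprintf("  Y0 = %s %%, plateau = %s %%, K = %s /s\n",
              format(x$coefficients[["Y0"]], digits = digits),
              format(x$coefficients[["plateau"]], digits = digits),
              format(x$coefficients[["K"]], digits = digits)))
  cat(sprintf("  mobile fraction = %s %%, t1/2 = %s s, R^2 = %s\n",
              format(x$mobile_fraction, digits = digits),
              format(x$t_half_s, digits = digits),
              format(x$r_squared, digits = digits)))
  if (!x$converged) cat("  NOT CONVERGED\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method summary frap_fit
summary.frap_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  cf <- object$coefficients
  cf[["Y0"]] + (cf[["plateau"]] - cf[["Y0"]]) * (1 - exp(-cf[["K"]] * x))
}

#' @exportS3Method residuals frap_fit
residuals.frap_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @exportS3Method plot frap_fit
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = "time after bleach (s)",
                 ylab = "relative fluorescence (%)", ...)
  xx <- seq(0, max(x$data$x), length.out = 200L)
  graphics::lines(xx, predict(x, data.frame(x = xx)))
  invisible(x)
}

#' Summarise a group of FRAP fits
#'
#' Mean, sd and coefficient of variation of mobile fraction and half-time
#' across converged fits, with a normality verdict from the
#' D'Agostino-Pearson K2 test. Fits that failed to converge or have
#' R^2 < `r2_min` are excluded and listed with reasons.
#'
#' @param fits list of `frap_fit` objects.
#' @param r2_min minimum R^2 for inclusion (default 0.5).
#' @return list with `n`, `mobile_fraction` and `t_half_s` summaries
#'   (mean, sd, cv_percent, normality p where computable), and `excluded`
#'   (data frame of index + reason). Fewer than 3 usable fits sets the
#'   `variance_undefined` flag.
#' @export
summarize_frap_group <- function(fits, r2_min = 0.5) {
  stopifnot(length(fits) >= 1L)
  reasons <- character()
  keep <- logical(length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!f$converged) {
      reasons[length(reasons) + 1L] <- sprintf("%d: not converged", i)
    } else if (is.finite(f$r_squared) && f$r_squared < r2_min) {
      reasons[length(reasons) + 1L] <- sprintf("%d: R^2 %.2f < %.2f", i, f$r_squared, r2_min)
    } else keep[i] <- TRUE
  }
  used <- fits[keep]
  summarise_vec <- function(v) {
    v <- v[is.finite(v)]
    out <- list(n = length(v), mean = mean(v), sd = stats::sd(v),
                cv_percent = if (length(v) >= 2L && mean(v) > 0)
                  coefficient_of_variation(v) else NA_real_)
    out$normality_p <- if (length(v) >= 8L)
      dagostino_pearson_k2(v)$p_value else NA_real_
    out
  }
  res <- list(n = length(used),
              mobile_fraction = summarise_vec(vapply(used, function(f) f$mobile_fraction, 0)),
              t_half_s = summarise_vec(vapply(used, function(f) f$t_half_s, 0)),
              excluded = reasons,
              variance_undefined = length(used) < 3L)
  res
}
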