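#' Simulate per-cell stress-granule count trajectories
#'
#' Generates a cohort of time-lapse SG-count series with known kinetics:
#' each cell's expected count is 0 before its formation onset, rises
#' linearly to a plateau, and (optionally) decays to 0 after a dispersal
#' onset; observed counts are Poisson draws around the expected curve.
#' Onsets are drawn per cell from normal distributions truncated at zero.
#'
#' @param n_cells number of cells.
#' @param t_max_min duration of the series, minutes.
#' @param dt_min frame interval, minutes (>= 3 by default acquisition).
#' @param onset_mean_min,onset_sd_min formation onset distribution.
#' @param rate_per_min expected SG appearance rate after onset.
#' @param plateau expected plateau count.
#' @param dispersal_mean_min,dispersal_sd_min dispersal onset distribution;
#'   `NULL` disables dispersal.
#' @param decay_per_min expected SG disappearance rate after dispersal onset.
#' @param condition condition label attached to every series.
#' @param seed RNG seed.
#' @return data frame of class `timelapse_series` with columns `cell_id,
#'   time_min, sg_count, condition`; attribute `"truth"` holds each cell's
#'   drawn onset/dispersal parameters and the realised formation time
#'   (first frame with count >= 5, `NA` if censored) and dispersal time
#'   (first return to 0 after the dispersal onset, `NA` if censored).
#' @export
simulate_timelapse_counts <- function(n_cells = 25L, t_max_min = 90,
                                      dt_min = 3, onset_mean_min = 20,
                                      onset_sd_min = 5, rate_per_min = 1,
                                      plateau = 8,
                                      dispersal_mean_min = NULL,
                                      dispersal_sd_min = 5,
                                      decay_per_min = 0.5,
                                      condition = "control", seed = 1L) {
  stopifnot(n_cells >= 1L, dt_min > 0, t_max_min > 0)
  times <- seq(0, t_max_min, by = dt_min)
  with_seed(derive_seed(seed, "timelapse"), {
    rows <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      # negative onsets model recovery-phase series that begin with SGs present
      onset <- stats::rnorm(1, onset_mean_min, onset_sd_min)
      disp <- if (is.null(dispersal_mean_min)) Inf else
        max(onset, stats::rnorm(1, dispersal_mean_min, dispersal_sd_min))
      mu <- pmin(pmax((times - onset) * rate_per_min, 0), plateau)
      falling <- times >= disp
      mu[falling] <- pmax(plateau - (times[falling] - disp) * decay_per_min, 0)
      counts <- stats::rpois(length(times), mu)
      counts[times < onset] <- 0L
      rows[[i]] <- data.frame(cell_id = i, time_min = times, sg_count = counts,
                              condition = condition)
      ft <- times[counts >= 5L][1L]
      dt_obs <- if (is.finite(disp)) {
        after <- times >= disp & counts == 0L
        times[after][1L]
      } else NA_real_
      truth[[i]] <- data.frame(cell_id = i, onset_min = onset,
                               dispersal_onset_min = if (is.finite(disp)) disp else NA_real_,
                               formation_time_min = if (length(ft)) ft else NA_real_,
                               dispersal_time_min = dt_obs)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  class(out) <- c("timelapse_series", class(out))
  out
}

#' Stress-granule formation time of one cell
#'
#' The formation time is the earliest time point at which at least
#' `threshold_count` SGs are detected. Cells that never reach the threshold
#' are censored, not reported as 0.
#'
#' @param time_min timestamps, minutes (strictly increasing).
#' @param sg_count non-negative integer SG counts per frame.
#' @param threshold_count detection threshold (default 5).
#' @return list with `time_min` (`NA` when censored) and `censored`.
#' @export
formation_time <- function(time_min, sg_count, threshold_count = 5L) {
  check_series(time_min, sg_count)
  hit <- which(sg_count >= threshold_count)
  if (length(hit) == 0L) list(time_min = NA_real_, censored = TRUE)
  else list(time_min = time_min[hit[1L]], censored = FALSE)
}

#' Stress-granule dispersal time of one cell
#'
#' The dispersal time is the first time point at which no SGs are detected
#' (count 0). The series must begin with SGs present (recovery experiments
#' start from induced cells); a transient return to zero counts as
#' dispersal even if SGs later recur (first zero wins).
#'
#' @inheritParams formation_time
#' @return list with `time_min` (`NA` when censored) and `censored`.
#' @export
dispersal_time <- function(time_min, sg_count) {
  check_series(time_min, sg_count)
  if (sg_count[1L] == 0L) stop("no SGs at recovery start")
  hit <- which(sg_count == 0L)
  if (length(hit) == 0L) list(time_min = NA_real_, censored = TRUE)
  else list(time_min = time_min[hit[1L]], censored = FALSE)
}

check_series <- function(time_min, sg_count) {
  stopifnot(length(time_min) >= 1L, length(sg_count) == length(time_min))
  if (any(diff(time_min) <= 0)) stop("timestamps must be strictly increasing")
  if (!is_count(sg_count)) stop("sg_count must be non-negative integers")
  invisible(TRUE)
}

#' Fraction of cells containing stress granules over time
#'
#' Per time point, the proportion of cells whose SG count meets the
#' presence threshold. All cells must share the timestamp grid (frames are
#' used as recorded; no interpolation).
#'
#' @param series a `timelapse_series` data frame (columns `cell_id,
#'   time_min, sg_count`).
#' @param presence_threshold minimum count for "contains SGs" (default 1).
#' @return data frame `time_min, fraction, n_cells`.
#' @export
fraction_with_sgs <- function(series, presence_threshold = 1L) {
  stopifnot(nrow(series) > 0L)
  grids <- split(series$time_min, series$cell_id)
  if (length(unique(lapply(grids, as.numeric))) != 1L)
    stop("all cells must share a common timestamp grid")
  pres <- series$sg_count >= presence_threshold
  agg <- stats::aggregate(pres, by = list(time_min = series$time_min), FUN = mean)
  n <- length(unique(series$cell_id))
  data.frame(time_min = agg$time_min, fraction = agg$x, n_cells = n)
}

#' Normalise values to the control-group mean
#'
#' Expresses each value as a percentage of the control mean (control group
#' mean maps to exactly 100%).
#'
#' @param values numeric vector to normalise.
#' @param control_values numeric vector defining the 100% level.
#' @return `values * 100 / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values * 100 / m
}
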