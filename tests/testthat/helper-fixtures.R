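# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures on disk.

# small noiseless scene: clean rendering for exact metric checks
noiseless_spec <- function(seed = 1L, ...) {
  scene_spec(noise = list(gaussian_sd = 0, poisson = FALSE), seed = seed, ...)
}

# single large cell carrying only well-separated stress granules, used for
# colocalisation calibration (big objects so per-object r is stable)
coloc_spec <- function(seed, n_sg = 5L) {
  scene_spec(
    image_shape = c(1L, 180L, 180L), n_cells = 1L,
    nucleus = list(semi_axes_um = c(1.2, 1.0, 1.0), intensity = 600),
    cytoplasm = list(semi_axes_um = c(1.8, 5.5, 5.5),
                     intensity = c(dapi = 5, gfp = 60, stain = 60)),
    condensate_specs = list(
      condensate_class("sg", "cytoplasmic", count = n_sg,
                       radius_um = c(0.6, 0.7), peak = c(gfp = 800))),
    noise = list(gaussian_sd = 0, poisson = FALSE),
    min_sep_um = 1.0, seed = seed)
}

# half-maximum-style threshold for noiseless default scenes: cytoplasm
# baseline 60, condensate peak 800 -> masks extend to about the nominal radius
HALF_MAX_THRESHOLD <- 460

# greedy centroid matching of detected objects against ground truth;
# returns c(tp, n_detected, n_truth)
match_detections <- function(object_table, truth_objects, max_dist_vox = 6) {
  used <- rep(FALSE, nrow(truth_objects))
  tp <- 0L
  for (i in seq_len(nrow(object_table))) {
    d <- sqrt((truth_objects$y - object_table$y[i])^2 +
                (truth_objects$x - object_table$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] < max_dist_vox) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(tp = tp, n_detected = nrow(object_table), n_truth = nrow(truth_objects))
}

# per-cell formation / dispersal readouts over a timelapse cohort
cohort_formation_times <- function(tl, threshold = 5L) {
  vapply(split(tl, tl$cell_id), function(df)
    formation_time(df$time_min, df$sg_count, threshold)$time_min, 0)
}

cohort_dispersal_times <- function(tl) {
  vapply(split(tl, tl$cell_id), function(df) {
    if (df$sg_count[1L] == 0L) return(NA_real_)  # excluded: no SGs at start
    dispersal_time(df$time_min, df$sg_count)$time_min
  }, 0)
}

# scipy reference for the K2 statistic (the runtime image ships python with
# scipy); returns c(statistic, p) or NULL if python is unavailable
scipy_normaltest <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(paste(sprintf("%.12g", x), collapse = ","), f)
  code <- sprintf(
    "import scipy.stats as st; x=[float(v) for v in open(%s).read().split(',')]; s,p=st.normaltest(x); print(float(s)); print(float(p))",
    shQuote(f))
  out <- tryCatch(suppressWarnings(system2("python", c("-c", shQuote(code)),
                                           stdout = TRUE, stderr = FALSE)),
                  error = function(e) NULL)
  if (is.null(out) || length(out) != 2L) return(NULL)
  as.numeric(out)
}

# independent brute-force oracle: between-class variance of the exact data
# partition, evaluated at every interior bin edge
otsu_brute_force <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  edges <- lo + (hi - lo) * seq_len(n_bins - 1L) / n_bins
  best <- -Inf; best_t <- NA_real_
  for (t in edges) {
    a <- x[x <= t]; b <- x[x > t]
    if (!length(a) || !length(b)) next
    w0 <- length(a) / length(x)
    bcv <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}
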