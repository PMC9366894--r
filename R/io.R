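#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...). Channel names, dimensions, voxel size and the intensity scale
#' used to map counts into TIFF range are stored in `<path>.json`, so a
#' stack round-trips through [read_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param bits_per_sample TIFF bit depth (default 32-bit float).
#' @return invisibly, `path`.
#' @export
write_image_stack <- function(stack, path, bits_per_sample = 32L) {
  stopifnot(inherits(stack, "image_stack"))
  dims <- dim(stack)
  offset <- min(0, vapply(stack$channels, min, 0))
  scale <- max(1, vapply(stack$channels, max, 0) - offset)
  pages <- list()
  for (ch in names(stack$channels)) {
    for (z in seq_len(dims[1L])) {
      pages[[length(pages) + 1L]] <- pmin(pmax((stack$channels[[ch]][z, , ] - offset) / scale, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  meta <- list(channels = names(stack$channels), shape_zyx = as.integer(dims),
               voxel_size_um = as.numeric(stack$voxel_size),
               intensity_scale = scale, intensity_offset = offset,
               page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- as.integer(meta$shape_zyx)
  chans <- stats::setNames(vector("list", length(meta$channels)), meta$channels)
  pg <- 0L
  for (ch in meta$channels) {
    arr <- array(0, dim = dims)
    for (z in seq_len(dims[1L])) {
      pg <- pg + 1L
      arr[z, , ] <- pages[[pg]] * meta$intensity_scale + (meta$intensity_offset %||% 0)
    }
    chans[[ch]] <- arr
  }
  image_stack(chans, voxel_size = meta$voxel_size_um)
}

#' Write / read a FRAP trace as CSV
#'
#' Columns: `time_s, roi, background, reference, pre_bleach`; the number of
#' pre-bleach frames is recovered from the `pre_bleach` flag on read.
#'
#' @param trace a [frap_trace()].
#' @param path CSV path.
#' @return invisibly `path` (write); a [frap_trace()] (read).
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  n_pre <- attr(trace, "n_pre")
  df <- as.data.frame(trace)
  if (is.null(df$reference)) df$reference <- NA_real_
  df$pre_bleach <- seq_len(nrow(df)) <= n_pre
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "roi", "background", "pre_bleach")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  n_pre <- sum(df$pre_bleach)
  if (n_pre < 1L) stop("no bleach detected: trace CSV has no pre-bleach rows")
  ref <- if ("reference" %in% names(df) && !all(is.na(df$reference)))
    df$reference else NULL
  frap_trace(df$time_s, df$roi, background = df$background,
             reference = ref, n_pre = n_pre)
}

#' Write / read a time-lapse SG-count series as CSV
#'
#' Columns: `cell_id, time_min, sg_count, condition`.
#'
#' @param series a `timelapse_series` data frame.
#' @param path CSV path.
#' @return invisibly `path` (write); a `timelapse_series` (read).
#' @export
write_timelapse <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("cell_id", "time_min", "sg_count",
                                             "condition")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timelapse
#' @export
read_timelapse <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "time_min", "sg_count")
  if (!all(need %in% names(df)))
    stop("time-lapse CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$condition)) df$condition <- "unknown"
  class(df) <- c("timelapse_series", class(df))
  df
}

#' Write scene ground truth as CSV plus JSON sidecar
#'
#' The per-object table goes to `<path>.csv`; docked pairs and scene
#' parameters to `<path>.json`.
#'
#' @param truth a `scene_truth` from [generate_scene()].
#' @param path base path (without extension).
#' @return invisibly the base path.
#' @export
write_scene_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  utils::write.csv(truth$objects, paste0(path, ".csv"), row.names = FALSE)
  spec <- truth$spec
  meta <- list(docked = truth$docked,
               cells = truth$cells,
               image_shape = spec$image_shape, voxel_size_um = spec$voxel_size,
               n_cells = spec$n_cells, docking_fraction = spec$docking_fraction,
               seed = spec$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
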