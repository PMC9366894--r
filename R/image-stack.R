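#' Multi-channel fluorescence image stack
#'
#' Container for a multi-channel, optionally 3D, fluorescence image.
#' Each channel is a numeric array in `(z, y, x)` order (a single z-plane,
#' `z = 1`, is the 2D case). Voxel size is carried in micrometres per axis so
#' that object sizes can be reported in physical units.
#'
#' @param channels named list of numeric arrays, all with identical
#'   `(z, y, x)` dimensions. 2D matrices are promoted to a single z-plane.
#' @param voxel_size numeric length-3 vector, micrometres per voxel along
#'   `(z, y, x)`. May be `NULL` when unknown; size measurements then fall
#'   back to voxel units with a warning.
#' @return an object of class `image_stack`.
#' @examples
#' im <- image_stack(list(gfp = matrix(rpois(64, 5), 8, 8)),
#'                   voxel_size = c(0.5, 0.1, 0.1))
#' dim(im$channels$gfp)
#' @export
image_stack <- function(channels, voxel_size = c(0.5, 0.1, 0.1)) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(1L, dim(ch)))
    if (length(dim(ch)) != 3L) stop("each channel must be a 2D or 3D array")
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  if (!is.null(voxel_size)) {
    stopifnot(is.numeric(voxel_size), length(voxel_size) == 3L, all(voxel_size > 0))
    voxel_size <- stats::setNames(as.numeric(voxel_size), c("z", "y", "x"))
  }
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], d[3L]))
  if (!is.null(x$voxel_size))
    cat(sprintf("  voxel size (um): z=%.3g y=%.3g x=%.3g\n",
                x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

# logical/numeric array of zeros matching the stack geometry
blank_like <- function(stack) array(0, dim = dim(stack))

# ellipsoid mask on a (z,y,x) grid; center and semi-axes in voxel units
ellipsoid_mask <- function(dims, center, semi) {
  zc <- ((seq_len(dims[1L]) - center[1L]) / max(semi[1L], .Machine$double.eps))^2
  yc <- ((seq_len(dims[2L]) - center[2L]) / max(semi[2L], .Machine$double.eps))^2
  xc <- ((seq_len(dims[3L]) - center[3L]) / max(semi[3L], .Machine$double.eps))^2
  d2 <- outer(outer(zc, yc, `+`), xc, `+`)
  array(d2 <= 1, dim = dims)
}
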