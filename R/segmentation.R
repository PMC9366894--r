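#' Otsu threshold by exact between-class variance maximisation
#'
#' Computes the classical Otsu threshold: candidate thresholds are the
#' `n_bins` - 1 interior bin edges of a uniform partition of the observed
#' intensity range, and the returned threshold maximises the between-class
#' variance \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} of the exact data partition
#' (values \eqn{\le t} against values \eqn{> t}). Ties are broken towards
#' the lowest maximising edge. The result is covariant under positive affine
#' intensity rescaling, so segmentation masks are invariant to it.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins over the observed min-max range.
#' @return the threshold (scalar); voxels strictly above it are foreground.
#' @examples
#' otsu_threshold(c(rep(0, 100), rep(200, 100)))
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) stop("degenerate histogram: fewer than 2 distinct intensities")
  lo <- min(x); hi <- max(x)
  edges <- lo + (hi - lo) * seq_len(n_bins - 1L) / n_bins
  xs <- sort(x)
  cs <- cumsum(xs)
  n <- length(xs)
  tot <- cs[n]
  k <- findInterval(edges, xs)            # count of values <= edge
  valid <- k > 0L & k < n
  if (!any(valid)) stop("degenerate histogram: no separating bin edge")
  k <- k[valid]; edges <- edges[valid]
  w0 <- k / n
  mu0 <- cs[k] / k
  mu1 <- (tot - cs[k]) / (n - k)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  edges[which.max(bcv)]                   # which.max returns the first (lowest) maximiser
}

# neighbour offsets for connected components, (z,y,x) rows
conn_offsets <- function(dims, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  zr <- if (dims[1L] > 1L) -1:1 else 0L
  g <- as.matrix(expand.grid(dz = zr, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == "face") g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  # keep one of each +/- pair (undirected edges)
  keep <- g[, 1L] > 0L | (g[, 1L] == 0L & g[, 2L] > 0L) |
    (g[, 1L] == 0L & g[, 2L] == 0L & g[, 3L] > 0L)
  g[keep, , drop = FALSE]
}

# label connected components of a logical array; returns integer array
label_components <- function(mask, connectivity = "full") {
  dims <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dim = dims)
  if (length(fg) == 0L) return(lab)
  rank <- array(0L, dim = dims)
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, dims)
  offs <- conn_offsets(dims, connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nz <- co[, 1L] + offs[r, 1L]
    ny <- co[, 2L] + offs[r, 2L]
    nx <- co[, 3L] + offs[r, 3L]
    ok <- nz >= 1L & nz <= dims[1L] & ny >= 1L & ny <= dims[2L] & nx >= 1L & nx <= dims[3L]
    if (!any(ok)) next
    nidx <- (nx[ok] - 1L) * dims[1L] * dims[2L] + (ny[ok] - 1L) * dims[1L] + nz[ok]
    nb <- rank[nidx]
    src <- seq_along(fg)[ok]
    hit <- nb > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(src[hit], nb[hit])
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # renumber consecutively in first-voxel order
  first <- tapply(seq_along(fg), memb, min)
  newid <- integer(max(memb))
  newid[as.integer(names(sort(first)))] <- seq_along(first)
  lab[fg] <- newid[memb]
  lab
}

#' Identify and label supra-threshold objects
#'
#' Connected-component labelling of voxels strictly above a threshold,
#' followed by minimum-size filtering and consecutive renumbering. This is
#' the object-identification step applied to every punctate channel
#' (nuclear RNA foci, stress granules, P-bodies).
#'
#' @param channel numeric array (2D matrix or `(z, y, x)` array) or an
#'   [image_stack()] channel.
#' @param threshold intensity threshold; defaults to [otsu_threshold()] of
#'   the channel.
#' @param min_size_voxels components smaller than this are discarded;
#'   defaults to 4 in 2D and 8 in 3D.
#' @param connectivity `"full"` (8-connectivity in 2D / 26 in 3D) or
#'   `"face"` (4 / 6).
#' @return an integer label array of class `label_map`; label 0 is
#'   background, labels are consecutive positive integers. Provenance
#'   (threshold, min size, connectivity) is attached as attributes.
#' @export
label_objects <- function(channel, threshold = NULL, min_size_voxels = NULL,
                          connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  if (is.matrix(channel)) channel <- array(channel, dim = c(1L, dim(channel)))
  stopifnot(length(dim(channel)) == 3L)
  if (is.null(threshold)) threshold <- otsu_threshold(channel)
  if (is.null(min_size_voxels)) min_size_voxels <- if (dim(channel)[1L] == 1L) 4L else 8L
  lab <- label_components(channel > threshold, connectivity)
  lab <- filter_min_size(lab, min_size_voxels)
  structure(lab, class = c("label_map", class(lab)),
            threshold = threshold, min_size_voxels = min_size_voxels,
            connectivity = connectivity)
}

# drop labels below min size, renumber consecutively preserving order
filter_min_size <- function(lab, min_size) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Segment nuclei from a DAPI channel
#'
#' Otsu threshold on the DAPI channel, hole filling (per z-plane), and
#' removal of components below a minimum nuclear size. The resulting binary
#' mask defines "DAPI-labelled regions" used to exclude nuclear objects from
#' cytoplasmic analyses.
#'
#' @param dapi numeric array or matrix, the DAPI channel.
#' @param min_nuclear_voxels minimum component size kept (default 200).
#' @return logical array, `TRUE` inside nuclei. An empty or constant DAPI
#'   channel yields an empty mask with a warning, never an error.
#' @export
segment_nuclei <- function(dapi, min_nuclear_voxels = 200L) {
  if (is.matrix(dapi)) dapi <- array(dapi, dim = c(1L, dim(dapi)))
  thr <- tryCatch(otsu_threshold(dapi), error = function(e) NULL)
  if (is.null(thr)) {
    warning("no nucleus found: DAPI channel is constant; returning empty mask")
    return(array(FALSE, dim = dim(dapi)))
  }
  mask <- dapi > thr
  for (z in seq_len(dim(dapi)[1L]))
    mask[z, , ] <- fill_holes_2d(mask[z, , ])
  lab <- filter_min_size(label_components(mask, "full"), min_nuclear_voxels)
  if (max(lab) == 0L)
    warning("no nucleus found: no DAPI component reached the minimum nuclear size")
  lab > 0L
}

# fill holes in a 2D logical matrix: background components not touching the
# border are interior holes
fill_holes_2d <- function(m) {
  bg <- array(!m, dim = c(1L, dim(m)))
  lab <- label_components(bg, "face")
  border <- unique(c(lab[1L, 1L, ], lab[1L, nrow(m), ], lab[1L, , 1L], lab[1L, , ncol(m)]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  m | hole[1L, , ]
}

#' Remove objects intersecting the nuclear mask
#'
#' Any labelled object with at least one voxel inside the nuclear mask is
#' removed entirely (any-overlap rule); remaining labels are renumbered
#' consecutively. Idempotent.
#'
#' @param labels a `label_map` from [label_objects()].
#' @param nuclear_mask logical array from [segment_nuclei()], same geometry.
#' @return a `label_map` containing only extranuclear objects.
#' @export
exclude_nuclear_objects <- function(labels, nuclear_mask) {
  stopifnot(identical(dim(labels), dim(nuclear_mask)))
  if (max(labels) > 0L) {
    inside <- unique(labels[nuclear_mask & labels > 0L])
    if (length(inside)) {
      sizes <- max(labels)
      map <- seq_len(sizes)
      map[inside] <- 0L
      keep <- map[map > 0L]
      map[keep] <- seq_along(keep)
      newlab <- as.integer(labels)
      newlab[newlab > 0L] <- map[newlab[newlab > 0L]]
      at <- attributes(labels)
      labels <- array(newlab, dim = dim(labels))
      attributes(labels) <- modifyList(at, list(dim = dim(labels)))
    }
  }
  labels
}

#' Measure labelled objects
#'
#' Per-object voxel count, physical size, centroid, per-channel mean and
#' integrated intensity, compartment flag, and nearest-nucleus cell
#' assignment. Integrated intensity equals mean times voxel count exactly.
#'
#' @param labels a `label_map`.
#' @param stack an [image_stack()] aligned to the labels.
#' @param nuclear_mask optional logical array; objects overlapping it are
#'   flagged `nuclear`.
#' @param nuclei_centroids optional data frame with columns `cell, z, y, x`
#'   (voxel coordinates); objects are assigned to the nearest nucleus.
#' @return a data frame of class `object_table`, one row per label, with
#'   columns `label, n_voxels, size` (um^3, or um^2 for single-plane data;
#'   voxels when the stack has no voxel size, with a warning),
#'   `z, y, x, compartment, cell`, and `mean_<channel>`,
#'   `integrated_<channel>` per channel.
#' @export
measure_objects <- function(labels, stack, nuclear_mask = NULL,
                            nuclei_centroids = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            identical(dim(labels), dim(stack)))
  nlab <- max(labels)
  dims <- dim(labels)
  fg <- which(labels > 0L)
  lv <- labels[fg]
  n_vox <- tabulate(lv, nlab)
  co <- arrayInd(fg, dims)
  cz <- as.numeric(tapply(co[, 1L], lv, mean))
  cy <- as.numeric(tapply(co[, 2L], lv, mean))
  cx <- as.numeric(tapply(co[, 3L], lv, mean))
  vs <- stack$voxel_size
  if (is.null(vs)) {
    warning("stack has no voxel size; sizes reported in voxels")
    size <- as.numeric(n_vox)
    size_unit <- "voxel"
  } else if (dims[1L] == 1L) {
    size <- n_vox * vs[2L] * vs[3L]
    size_unit <- "um2"
  } else {
    size <- n_vox * prod(vs)
    size_unit <- "um3"
  }
  out <- data.frame(label = seq_len(nlab), n_voxels = n_vox, size = size,
                    z = if (nlab) cz else numeric(), y = if (nlab) cy else numeric(),
                    x = if (nlab) cx else numeric())
  out$compartment <- "cytoplasmic"
  if (!is.null(nuclear_mask) && nlab > 0L) {
    nuc <- unique(labels[nuclear_mask & labels > 0L])
    out$compartment[out$label %in% nuc] <- "nuclear"
  }
  out$cell <- NA_integer_
  if (!is.null(nuclei_centroids) && nlab > 0L) {
    for (i in seq_len(nlab)) {
      d2 <- (nuclei_centroids$z - out$z[i])^2 + (nuclei_centroids$y - out$y[i])^2 +
        (nuclei_centroids$x - out$x[i])^2
      out$cell[i] <- nuclei_centroids$cell[which.min(d2)]
    }
  }
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]][fg]
    tot <- if (nlab) as.numeric(tapply(v, lv, sum)) else numeric()
    out[[paste0("integrated_", ch)]] <- tot
    out[[paste0("mean_", ch)]] <- if (nlab) tot / n_vox else numeric()
  }
  attr(out, "size_unit") <- size_unit
  class(out) <- c("object_table", class(out))
  out
}
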