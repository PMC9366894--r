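#' Percentage of total cellular signal inside labelled objects
#'
#' The fraction (in %) of a channel's background-corrected signal that lies
#' in segmented condensates, relative to the whole cell mask — e.g. the
#' percentage of total cellular GFP-tagged protein localised to nuclear
#' foci, or of poly(A) RNA in stress granules.
#'
#' @param channel numeric array (or matrix).
#' @param labels a `label_map` of the objects.
#' @param cell_mask logical array delimiting the cell(s).
#' @param background `"modal"` (default: subtract the modal intensity of
#'   non-object voxels inside the cell mask), `"none"`, or a numeric level.
#'   Corrected intensities are clamped at zero before summation.
#' @return percentage in `[0, 100]`.
#' @export
percent_signal_in_objects <- function(channel, labels, cell_mask,
                                      background = "modal") {
  if (is.matrix(channel)) channel <- array(channel, dim = c(1L, dim(channel)))
  stopifnot(identical(dim(channel), dim(cell_mask)),
            identical(dim(channel), dim(labels)))
  bg <- resolve_background(channel, labels, cell_mask, background)
  corr <- pmax(channel - bg, 0)
  total <- sum(corr[cell_mask])
  if (total <= 0) stop("zero total cell signal after background correction")
  100 * sum(corr[cell_mask & labels > 0L]) / total
}

# modal (histogram-mode), none, or fixed numeric background level
resolve_background <- function(channel, labels, cell_mask, background) {
  if (is.numeric(background)) return(background)
  switch(background,
         none = 0,
         modal = {
           v <- channel[cell_mask & labels == 0L]
           if (length(v) == 0L) 0 else hist_mode(v)
         },
         stop("background must be 'modal', 'none' or a number"))
}

hist_mode <- function(v, n_bins = 256L) {
  if (length(unique(v)) == 1L) return(v[1L])
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = n_bins + 1L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Cytoplasmic fraction of total cellular signal
#'
#' The nucleocytoplasmic partition of a channel: the percentage of its total
#' cellular signal outside the nucleus.
#'
#' @param channel numeric array (or matrix).
#' @param nuclear_mask logical array, must lie within `cell_mask`.
#' @param cell_mask logical array delimiting the cell(s).
#' @param background as in [percent_signal_in_objects()]; the modal level is
#'   taken over cytoplasmic (non-nuclear) voxels here.
#' @return cytoplasmic percentage in `[0, 100]`.
#' @export
nucleocytoplasmic_partition <- function(channel, nuclear_mask, cell_mask,
                                        background = "none") {
  if (is.matrix(channel)) channel <- array(channel, dim = c(1L, dim(channel)))
  stopifnot(identical(dim(channel), dim(cell_mask)),
            identical(dim(channel), dim(nuclear_mask)))
  if (any(nuclear_mask & !cell_mask)) stop("nuclear_mask must lie within cell_mask")
  bg <- resolve_background(channel, array(as.integer(nuclear_mask), dim = dim(channel)),
                           cell_mask, background)
  corr <- pmax(channel - bg, 0)
  total <- sum(corr[cell_mask])
  if (total <= 0) stop("zero total cell signal after background correction")
  100 * sum(corr[cell_mask & !nuclear_mask]) / total
}

#' Per-object Pearson colocalisation between two channels
#'
#' For each labelled object, the Pearson correlation coefficient between the
#' two channels' intensities over that object's voxels — the object-based
#' colocalisation measurement applied to cytoplasmic structures after
#' nuclear exclusion. The coefficient is invariant under positive affine
#' rescaling of either channel.
#'
#' @param labels a `label_map`.
#' @param chA,chB numeric arrays aligned with the labels.
#' @return data frame with columns `label`, `n_voxels`, `r`, `undefined`
#'   (`TRUE`, with `r = NA`, when either channel is constant within the
#'   object).
#' @export
per_object_pearson <- function(labels, chA, chB) {
  if (is.matrix(chA)) chA <- array(chA, dim = c(1L, dim(chA)))
  if (is.matrix(chB)) chB <- array(chB, dim = c(1L, dim(chB)))
  stopifnot(identical(dim(chA), dim(chB)), identical(dim(chA), dim(labels)))
  nlab <- max(labels)
  out <- data.frame(label = seq_len(nlab), n_voxels = NA_integer_,
                    r = NA_real_, undefined = FALSE)
  if (nlab == 0L) return(out)
  fg <- which(labels > 0L)
  lv <- labels[fg]
  a <- split(chA[fg], lv)
  b <- split(chB[fg], lv)
  for (i in seq_len(nlab)) {
    ai <- a[[as.character(i)]]
    bi <- b[[as.character(i)]]
    out$n_voxels[i] <- length(ai)
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) {
      out$undefined[i] <- TRUE
    } else {
      out$r[i] <- stats::cor(ai, bi)
    }
  }
  out
}

#' Classify objects as containing a protein by local enrichment
#'
#' An object "contains" a protein when its mean intensity in that channel
#' exceeds `enrichment_factor` times the median cytoplasmic (non-object)
#' intensity of the cell mask — used, e.g., to score the fraction of
#' P-bodies positive for a given RNA-binding protein.
#'
#' @param labels a `label_map` of the bodies.
#' @param channel numeric array of the protein stain.
#' @param cell_mask logical array; non-object voxels inside it estimate the
#'   local background.
#' @param enrichment_factor positivity threshold multiplier (default 1.5).
#' @return list with `fraction_positive` (in %, `NA` with a warning when no
#'   objects exist), `n_objects`, `background`, and a per-object data frame.
#' @export
classify_body_content <- function(labels, channel, cell_mask,
                                  enrichment_factor = 1.5) {
  if (is.matrix(channel)) channel <- array(channel, dim = c(1L, dim(channel)))
  stopifnot(identical(dim(channel), dim(labels)),
            identical(dim(channel), dim(cell_mask)))
  nlab <- max(labels)
  if (nlab == 0L) {
    warning("no objects to classify")
    return(list(fraction_positive = NA_real_, n_objects = 0L,
                background = NA_real_, objects = data.frame()))
  }
  bgv <- channel[cell_mask & labels == 0L]
  bg <- stats::median(bgv)
  fg <- which(labels > 0L)
  mean_int <- as.numeric(tapply(channel[fg], labels[fg], mean))
  pos <- mean_int > enrichment_factor * bg
  list(fraction_positive = 100 * mean(pos), n_objects = nlab, background = bg,
       objects = data.frame(label = seq_len(nlab), mean_intensity = mean_int,
                            positive = pos))
}

#' Count docking events between stress granules and P-bodies
#'
#' An (SG, P-body) pair is a docking event when the minimum
#' surface-to-surface separation between the two objects is at most
#' `max_gap_voxels` (Chebyshev metric; the default 1 means "touching after
#' one dilation"). Each pair is counted once; the relation is symmetric in
#' its two arguments.
#'
#' @param sg_labels,pb_labels `label_map`s with identical geometry.
#' @param max_gap_voxels maximum background gap between surfaces (default 1).
#' @return list with `events` (data frame `sg, pb`), `n_events`, `n_sg`,
#'   and `events_per_sg` (`n_events / n_sg`; `NA` when there are no SGs).
#' @export
docking_events <- function(sg_labels, pb_labels, max_gap_voxels = 1L) {
  stopifnot(identical(dim(sg_labels), dim(pb_labels)), max_gap_voxels >= 0L)
  dims <- dim(sg_labels)
  n_sg <- max(sg_labels)
  n_pb <- max(pb_labels)
  events <- data.frame(sg = integer(), pb = integer())
  if (n_sg > 0L && n_pb > 0L) {
    sg_co <- split_coords(sg_labels, dims)
    pb_co <- split_coords(pb_labels, dims)
    reach <- max_gap_voxels + 1L
    for (i in seq_len(n_sg)) {
      for (j in seq_len(n_pb)) {
        if (bbox_gap(sg_co[[i]], pb_co[[j]]) > reach) next
        if (min_chebyshev(sg_co[[i]], pb_co[[j]]) <= reach)
          events <- rbind(events, data.frame(sg = i, pb = j))
      }
    }
  }
  list(events = events, n_events = nrow(events), n_sg = n_sg,
       events_per_sg = if (n_sg > 0L) nrow(events) / n_sg else NA_real_)
}

split_coords <- function(labels, dims) {
  fg <- which(labels > 0L)
  co <- arrayInd(fg, dims)
  lapply(split(seq_along(fg), labels[fg]), function(ix) co[ix, , drop = FALSE])
}

# cheap lower bound on the chebyshev distance via bounding boxes
bbox_gap <- function(a, b) {
  g <- 0
  for (ax in 1:3) {
    lo <- max(min(a[, ax]), min(b[, ax]))
    hi <- min(max(a[, ax]), max(b[, ax]))
    g <- max(g, lo - hi)
  }
  g
}

min_chebyshev <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- pmax(abs(b[, 1L] - a[i, 1L]),
              pmax(abs(b[, 2L] - a[i, 2L]), abs(b[, 3L] - a[i, 3L])))
    best <- min(best, min(d))
    if (best <= 1) break
  }
  best
}

#' Per-cell object counts and sizes
#'
#' Aggregates an [measure_objects()] table to per-cell condensate counts and
#' physical sizes.
#'
#' @param objects an `object_table`.
#' @param cells optional vector of cell ids to report (cells with no objects
#'   get zero counts).
#' @return data frame with `cell`, `n_objects`, `mean_size`, `total_size`.
#' @export
count_and_size <- function(objects, cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(objects$cell))
  if (length(cells) == 0L || nrow(objects) == 0L) {
    return(data.frame(cell = cells %||% integer(), n_objects = integer(length(cells)),
                      mean_size = rep(NA_real_, length(cells)),
                      total_size = numeric(length(cells))))
  }
  do.call(rbind, lapply(cells, function(cl) {
    sel <- objects$cell %in% cl
    data.frame(cell = cl, n_objects = sum(sel),
               mean_size = if (any(sel)) mean(objects$size[sel]) else NA_real_,
               total_size = sum(objects$size[sel]))
  }))
}
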