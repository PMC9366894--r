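#' Describe one class of condensates for scene simulation
#'
#' @param class short class label, e.g. `"foci"`, `"sg"`, `"pb"`.
#' @param compartment `"nuclear"` or `"cytoplasmic"`.
#' @param count integer count per cell, or length-2 range sampled uniformly.
#' @param radius_um object radius in micrometres (nominal half-maximum
#'   radius of the rendered spot), or a length-2 range.
#' @param peak named numeric vector of peak intensities per channel.
#' @return a list of class `condensate_class`.
#' @export
condensate_class <- function(class, compartment = c("cytoplasmic", "nuclear"),
                             count = c(3L, 6L), radius_um = c(0.3, 0.5),
                             peak = c(gfp = 800)) {
  compartment <- match.arg(compartment)
  if (length(count) == 1L) count <- c(count, count)
  if (length(radius_um) == 1L) radius_um <- c(radius_um, radius_um)
  stopifnot(is_count(count), all(radius_um > 0), radius_um[1L] <= radius_um[2L],
            is.numeric(peak), !is.null(names(peak)))
  structure(list(class = class, compartment = compartment,
                 count = as.integer(count), radius_um = radius_um, peak = peak),
            class = "condensate_class")
}

#' Specification of a synthetic multi-cell fluorescence scene
#'
#' Defines the geometry, condensate content, optics and noise of a simulated
#' field of cells. Defaults emulate the imaging conditions the package's
#' analyses assume: anisotropic voxels with 0.5 um z-sectioning, elliptical
#' nuclei counterstained in a DAPI channel, cytoplasmic stress granules
#' (`sg`, GFP channel) and P-bodies (`pb`, stain channel), nuclear RNA foci
#' (`foci`, GFP channel), and a camera noise model of Poisson shot noise
#' plus Gaussian read noise.
#'
#' @param image_shape integer `(z, y, x)` voxel counts; `z = 1` gives a 2D scene.
#' @param voxel_size micrometres per voxel along `(z, y, x)`.
#' @param n_cells number of cells placed in the field.
#' @param nucleus list: `semi_axes_um` (z,y,x) and `intensity` (DAPI level).
#' @param cytoplasm list: `semi_axes_um` (z,y,x) and `intensity`, a named
#'   per-channel baseline inside the cell.
#' @param condensate_specs list of [condensate_class()] objects.
#' @param docking_fraction fraction of P-bodies placed in surface contact
#'   with a stress granule (class `"pb"` against class `"sg"`).
#' @param contact_dist_um maximum surface-to-surface gap of a docked pair.
#' @param channel_correlation optional target within-object Pearson
#'   correlation between the two non-DAPI channels, in `[-1, 1]`; `NULL`
#'   leaves channel intensities as specified per class.
#' @param psf_sigma_um isotropic Gaussian PSF sigma.
#' @param noise list: `gaussian_sd` (read noise, counts) and `poisson`
#'   (logical, shot noise).
#' @param min_sep_um minimum surface-to-surface separation enforced between
#'   non-docked objects, so rendered objects do not merge.
#' @param seed integer master seed; all placement and noise derive from it.
#' @return a validated list of class `scene_spec`.
#' @seealso [generate_scene()]
#' @export
scene_spec <- function(image_shape = c(1L, 160L, 160L),
                       voxel_size = c(0.5, 0.1, 0.1),
                       n_cells = 2L,
                       nucleus = list(semi_axes_um = c(1.2, 1.8, 1.8), intensity = 600),
                       cytoplasm = list(semi_axes_um = c(1.8, 3.4, 3.4),
                                        intensity = c(dapi = 5, gfp = 60, stain = 60)),
                       condensate_specs = list(
                         condensate_class("foci", "nuclear", count = 2L,
                                          radius_um = c(0.25, 0.35), peak = c(gfp = 900)),
                         condensate_class("sg", "cytoplasmic", count = c(2L, 3L),
                                          radius_um = c(0.3, 0.4), peak = c(gfp = 800)),
                         condensate_class("pb", "cytoplasmic", count = c(2L, 3L),
                                          radius_um = c(0.2, 0.3), peak = c(stain = 800))),
                       docking_fraction = 0,
                       contact_dist_um = 0.1,
                       channel_correlation = NULL,
                       psf_sigma_um = 0.05,
                       noise = list(gaussian_sd = 10, poisson = TRUE),
                       min_sep_um = 0.6,
                       seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), voxel_size = as.numeric(voxel_size),
               n_cells = as.integer(n_cells), nucleus = nucleus, cytoplasm = cytoplasm,
               condensate_specs = condensate_specs, docking_fraction = docking_fraction,
               contact_dist_um = contact_dist_um, channel_correlation = channel_correlation,
               psf_sigma_um = psf_sigma_um, noise = noise, min_sep_um = min_sep_um,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(length(spec$image_shape) == 3L, all(spec$image_shape >= 1L),
            length(spec$voxel_size) == 3L, all(spec$voxel_size > 0),
            spec$n_cells >= 1L,
            spec$docking_fraction >= 0, spec$docking_fraction <= 1,
            spec$contact_dist_um >= 0, spec$psf_sigma_um >= 0,
            spec$min_sep_um >= 0)
  if (!is.null(spec$channel_correlation))
    stopifnot(spec$channel_correlation >= -1, spec$channel_correlation <= 1)
  for (cs in spec$condensate_specs) {
    if (!inherits(cs, "condensate_class"))
      stop("condensate_specs must be condensate_class objects")
    if (max(cs$radius_um) >= min(spec$cytoplasm$semi_axes_um[-1L]))
      stop("condensate radius_um exceeds the cell radius (condensate_specs)")
  }
  invisible(spec)
}

# channel names a scene will render
scene_channels <- function(spec) {
  unique(c("dapi", names(spec$cytoplasm$intensity),
           unlist(lapply(spec$condensate_specs, function(cs) names(cs$peak)))))
}

# Gaussian spot sigma (um) whose half-maximum radius equals the nominal radius
spot_sigma_um <- function(radius_um) radius_um / sqrt(2 * log(2))

# Add a truncated separable Gaussian spot; returns the updated image and the
# photon sum actually deposited (exact ground-truth integrated intensity).
add_spot <- function(img, center, sigma_vox, amplitude, trunc = 3) {
  d <- dim(img)
  idx <- vector("list", 3L)
  prof1d <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, as.integer(floor(center[a] - trunc * sigma_vox[a])))
    hi <- min(d[a], as.integer(ceiling(center[a] + trunc * sigma_vox[a])))
    if (lo > hi) return(list(img = img, sum = 0))
    idx[[a]] <- seq.int(lo, hi)
    prof1d[[a]] <- exp(-((idx[[a]] - center[a])^2) / (2 * sigma_vox[a]^2))
  }
  prof <- amplitude * outer(outer(prof1d[[1L]], prof1d[[2L]]), prof1d[[3L]])
  cur <- img[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  img[idx[[1L]], idx[[2L]], idx[[3L]]] <- cur + prof
  list(img = img, sum = sum(prof))
}

# uniform point in the unit ball, scaled to ellipsoid semi-axes (voxels),
# with a fractional margin keeping a sphere of radius r_frac inside
runif_ellipsoid <- function(center, semi, shrink) {
  repeat {
    p <- stats::runif(3L, -1, 1)
    if (sum(p^2) <= 1) break
  }
  center + p * semi * shrink
}

#' Generate a synthetic multi-channel scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: elliptical nuclei in the
#' DAPI channel, per-cell cytoplasm baselines, and condensates as
#' PSF-blurred Gaussian spots placed in their compartments. Shot and read
#' noise are applied last. Placement, rendering and noise each consume a
#' dedicated sub-stream of `spec$seed`, so a fixed spec is byte-reproducible.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{image}{an [image_stack()] with the rendered channels;}
#'     \item{truth}{a `scene_truth` list: `objects` (one row per rendered
#'       condensate: class, compartment, cell, voxel centroid, radius and
#'       exact integrated intensity per channel), `docked` (true SG/P-body
#'       docked pairs), `cells`, `cell_labels` (per-voxel cell assignment),
#'       `nuclear_mask`, `cell_totals` (pre-noise photon totals per cell and
#'       channel), and the generating `spec`.}
#'   }
#' @examples
#' sc <- generate_scene(scene_spec(seed = 7))
#' sc$image
#' head(sc$truth$objects)
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  dims <- spec$image_shape
  vs <- spec$voxel_size
  chans <- scene_channels(spec)
  is2d <- dims[1L] == 1L

  nuc_semi_vox <- spec$nucleus$semi_axes_um / vs
  cyto_semi_vox <- spec$cytoplasm$semi_axes_um / vs
  if (is2d) nuc_semi_vox[1L] <- cyto_semi_vox[1L] <- 1

  ## --- cell placement ------------------------------------------------------
  with_seed(derive_seed(spec$seed, "placement"), {
    centers <- NULL
    for (restart in seq_len(100L)) {
      centers <- matrix(NA_real_, spec$n_cells, 3L)
      placed_all <- TRUE
      for (i in seq_len(spec$n_cells)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          c_i <- c(if (is2d) 1 else stats::runif(1, 1 + cyto_semi_vox[1L], dims[1L] - cyto_semi_vox[1L]),
                   stats::runif(1, 1 + cyto_semi_vox[2L], dims[2L] - cyto_semi_vox[2L]),
                   stats::runif(1, 1 + cyto_semi_vox[3L], dims[3L] - cyto_semi_vox[3L]))
          if (i == 1L ||
              all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE], 2L, c_i)^2)) >
                  2 * max(cyto_semi_vox[2:3]))) {
            centers[i, ] <- c_i
            ok <- TRUE
            break
          }
        }
        if (!ok) { placed_all <- FALSE; break }
      }
      if (placed_all) break
      centers <- NULL
    }
    if (is.null(centers))
      stop("could not place non-overlapping cells; reduce n_cells or enlarge image_shape")

    ## --- condensate placement ----------------------------------------------
    objects <- list()
    docked <- list()
    oid <- 0L
    for (cell in seq_len(spec$n_cells)) {
      cc <- centers[cell, ]
      placed <- list()  # per-object: center (vox), radius_um
      sep_ok <- function(pos, r_um, gap_min_um) {
        for (p in placed) {
          dd <- sqrt(sum(((pos - p$center) * vs)^2))
          if (dd < r_um + p$radius_um + gap_min_um) return(FALSE)
        }
        TRUE
      }
      place_class <- function(cs) {
        n <- if (cs$count[1L] == cs$count[2L]) cs$count[1L] else
          sample(cs$count[1L]:cs$count[2L], 1L)
        out <- vector("list", n)
        for (k in seq_len(n)) {
          r <- stats::runif(1, cs$radius_um[1L], cs$radius_um[2L])
          ok <- FALSE
          for (try in seq_len(500L)) {
            if (cs$compartment == "nuclear") {
              shrink <- 1 - r / min(spec$nucleus$semi_axes_um[if (is2d) 2:3 else 1:3])
              pos <- runif_ellipsoid(cc, nuc_semi_vox, max(shrink, 0.05))
            } else {
              shrink <- 1 - r / min(spec$cytoplasm$semi_axes_um[if (is2d) 2:3 else 1:3])
              pos <- runif_ellipsoid(cc, cyto_semi_vox, max(shrink, 0.05))
              # clearance so the segmented mask never touches the nucleus
              nd <- sqrt(sum(((pos - cc) / nuc_semi_vox)^2))
              if (nd < 1 + (1.6 * r + 0.1) / min(spec$nucleus$semi_axes_um[2:3])) next
            }
            if (is2d) pos[1L] <- 1
            if (!sep_ok(pos, r, spec$min_sep_um)) next
            ok <- TRUE
            break
          }
          if (!ok) stop(sprintf(
            "could not place a '%s' condensate after bounded retries (condensate_specs)", cs$class))
          out[[k]] <- list(center = pos, radius_um = r)
          placed[[length(placed) + 1L]] <<- out[[k]]
        }
        out
      }

      by_class <- list()
      for (cs in spec$condensate_specs) {
        if (cs$class == "pb" && spec$docking_fraction > 0 &&
            any(vapply(spec$condensate_specs, function(s) s$class, "") == "sg")) {
          # place P-bodies with a docked subset against already-placed SGs
          sgs <- Filter(function(o) o$class == "sg" && o$cell == cell, objects)
          n <- if (cs$count[1L] == cs$count[2L]) cs$count[1L] else
            sample(cs$count[1L]:cs$count[2L], 1L)
          n_dock <- round(spec$docking_fraction * n)
          out <- vector("list", n)
          for (k in seq_len(n)) {
            r <- stats::runif(1, cs$radius_um[1L], cs$radius_um[2L])
            ok <- FALSE
            if (k <= n_dock && length(sgs) > 0L) {
              for (try in seq_len(500L)) {
                sg <- sgs[[sample.int(length(sgs), 1L)]]
                gap <- stats::runif(1, 0, spec$contact_dist_um)
                dist_um <- sg$radius_um + r + gap
                theta <- stats::runif(1, 0, 2 * pi)
                dirv <- if (is2d) c(0, sin(theta), cos(theta)) else {
                  u <- stats::rnorm(3L); u / sqrt(sum(u^2))
                }
                pos <- sg$center + dirv * dist_um / vs
                if (is2d) pos[1L] <- 1
                ed <- sqrt(sum(((pos - cc) / cyto_semi_vox)^2))
                nd <- sqrt(sum(((pos - cc) / nuc_semi_vox)^2))
                if (ed > 0.95 || nd < 1.05) next
                # keep clear of everything except the partner SG
                clear <- TRUE
                for (p in placed) {
                  if (identical(p$center, sg$center)) next
                  dd <- sqrt(sum(((pos - p$center) * vs)^2))
                  if (dd < r + p$radius_um + spec$min_sep_um) { clear <- FALSE; break }
                }
                if (!clear) next
                out[[k]] <- list(center = pos, radius_um = r, docked_to = sg$id)
                placed[[length(placed) + 1L]] <- out[[k]]
                ok <- TRUE
                break
              }
            }
            if (!ok) {
              # undocked: enforce a clear margin from every SG
              for (try in seq_len(500L)) {
                shrink <- 1 - r / min(spec$cytoplasm$semi_axes_um[if (is2d) 2:3 else 1:3])
                pos <- runif_ellipsoid(cc, cyto_semi_vox, max(shrink, 0.05))
                if (is2d) pos[1L] <- 1
                nd <- sqrt(sum(((pos - cc) / nuc_semi_vox)^2))
                if (nd < 1 + (1.6 * r + 0.1) / min(spec$nucleus$semi_axes_um[2:3])) next
                if (!sep_ok(pos, r, spec$min_sep_um)) next
                # undocked P-bodies keep an unambiguous margin from every SG
                sg_clear <- TRUE
                for (sg in sgs) {
                  dd <- sqrt(sum(((pos - sg$center) * vs)^2))
                  if (dd < r + sg$radius_um + max(spec$min_sep_um, 0.8)) { sg_clear <- FALSE; break }
                }
                if (!sg_clear) next
                out[[k]] <- list(center = pos, radius_um = r, docked_to = NA_integer_)
                placed[[length(placed) + 1L]] <- out[[k]]
                ok <- TRUE
                break
              }
            }
            if (!ok) stop("could not place a 'pb' condensate after bounded retries (docking_fraction)")
          }
          by_class[[cs$class]] <- out
        } else {
          by_class[[cs$class]] <- place_class(cs)
        }
        for (o in by_class[[cs$class]]) {
          oid <- oid + 1L
          rec <- list(id = oid, class = cs$class,
                      compartment = cs$compartment, cell = cell,
                      center = o$center, radius_um = o$radius_um,
                      peak = cs$peak)
          objects[[oid]] <- rec
          if (!is.null(o$docked_to) && !is.na(o$docked_to))
            docked[[length(docked) + 1L]] <- c(sg_id = o$docked_to, pb_id = oid)
        }
      }
    }
  })

  ## --- rendering (noiseless) ----------------------------------------------
  imgs <- stats::setNames(lapply(chans, function(ch) array(0, dim = dims)), chans)
  cell_labels <- array(0L, dim = dims)
  nuclear_mask <- array(FALSE, dim = dims)
  for (cell in seq_len(spec$n_cells)) {
    cm <- ellipsoid_mask(dims, centers[cell, ], cyto_semi_vox)
    nm <- ellipsoid_mask(dims, centers[cell, ], nuc_semi_vox)
    cell_labels[cm] <- cell
    nuclear_mask <- nuclear_mask | nm
    for (ch in names(spec$cytoplasm$intensity))
      imgs[[ch]][cm] <- imgs[[ch]][cm] + spec$cytoplasm$intensity[[ch]]
    imgs$dapi[nm] <- imgs$dapi[nm] + spec$nucleus$intensity
  }

  integ <- matrix(0, nrow = length(objects), ncol = length(chans),
                  dimnames = list(NULL, chans))
  for (o in objects) {
    sig_um <- sqrt(spot_sigma_um(o$radius_um)^2 + spec$psf_sigma_um^2)
    sig_vox <- pmax(sig_um / vs, 1e-6)
    for (ch in names(o$peak)) {
      if (o$peak[[ch]] <= 0) next
      res <- add_spot(imgs[[ch]], o$center, sig_vox, o$peak[[ch]])
      imgs[[ch]] <- res$img
      integ[o$id, ch] <- res$sum
    }
  }

  cell_totals <- do.call(rbind, lapply(seq_len(spec$n_cells), function(cell) {
    sel <- cell_labels == cell
    data.frame(cell = cell, channel = chans,
               total = vapply(chans, function(ch) sum(imgs[[ch]][sel]), 0),
               row.names = NULL)
  }))

  ## --- noise ---------------------------------------------------------------
  with_seed(derive_seed(spec$seed, "noise"), {
    for (ch in chans) {
      v <- imgs[[ch]]
      if (isTRUE(spec$noise$poisson)) v <- array(stats::rpois(length(v), v), dim = dims)
      if (spec$noise$gaussian_sd > 0)
        v <- v + stats::rnorm(length(v), 0, spec$noise$gaussian_sd)
      imgs[[ch]] <- v
    }
  })

  obj_df <- data.frame(
    id = vapply(objects, function(o) o$id, 0L),
    class = vapply(objects, function(o) o$class, ""),
    compartment = vapply(objects, function(o) o$compartment, ""),
    cell = vapply(objects, function(o) o$cell, 0L),
    z = vapply(objects, function(o) o$center[1L], 0),
    y = vapply(objects, function(o) o$center[2L], 0),
    x = vapply(objects, function(o) o$center[3L], 0),
    radius_um = vapply(objects, function(o) o$radius_um, 0))
  for (ch in chans) obj_df[[paste0("integrated_", ch)]] <- integ[, ch]
  if (length(objects) == 0L) obj_df <- obj_df[0, , drop = FALSE]

  docked_df <- if (length(docked)) as.data.frame(do.call(rbind, docked)) else
    data.frame(sg_id = integer(), pb_id = integer())

  truth <- structure(list(objects = obj_df, docked = docked_df,
                          cells = data.frame(cell = seq_len(spec$n_cells),
                                             z = centers[, 1L], y = centers[, 2L],
                                             x = centers[, 3L]),
                          cell_labels = cell_labels, nuclear_mask = nuclear_mask,
                          cell_totals = cell_totals, spec = spec),
                     class = "scene_truth")
  list(image = image_stack(imgs, voxel_size = vs), truth = truth)
}

#' Render a two-channel stack with a known within-object correlation
#'
#' Re-renders channel A noiselessly from a scene's ground truth and builds a
#' channel B whose voxel intensities inside each object are a rho-mixture of
#' the standardised channel-A profile and independent Gaussian noise, so the
#' expected within-object Pearson correlation equals `rho` exactly. Used to
#' calibrate the object-based colocalisation measurement.
#'
#' @param truth a `scene_truth` from [generate_scene()].
#' @param rho target within-object Pearson correlation, in `[-1, 1]`.
#' @param channel ground-truth channel used as channel A (default `"gfp"`).
#' @param background constant added to channel B.
#' @param noise_sd Gaussian noise added to channel B outside objects.
#' @param footprint_scale the correlated region of each object is the
#'   ellipsoid of `footprint_scale` times its nominal radius. Channel A is
#'   rendered with peak 1000, so segmenting it at threshold
#'   `1000 * 2^(-footprint_scale^2)` yields masks that coincide with the
#'   constructed footprints, which is what the calibration assumes.
#' @param seed RNG seed for the mixture noise.
#' @return an [image_stack()] with channels `chA` and `chB`, carrying the
#'   per-object footprints as attribute `"footprints"` (list of voxel index
#'   vectors, named by object id) and the footprint-matching segmentation
#'   threshold as attribute `"matching_threshold"`.
#' @export
generate_correlated_channels <- function(truth, rho, channel = "gfp",
                                         background = 50, noise_sd = 2,
                                         footprint_scale = 1.5,
                                         seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"), rho >= -1, rho <= 1)
  spec <- truth$spec
  dims <- spec$image_shape
  vs <- spec$voxel_size
  A <- array(0, dim = dims)
  obj <- truth$objects
  keep <- which(obj[[paste0("integrated_", channel)]] > 0)
  for (i in keep) {
    sig_um <- sqrt(spot_sigma_um(obj$radius_um[i])^2 + spec$psf_sigma_um^2)
    A <- add_spot(A, c(obj$z[i], obj$y[i], obj$x[i]), pmax(sig_um / vs, 1e-6),
                  amplitude = 1000)$img
  }
  B <- array(0, dim = dims)
  fps <- list()
  with_seed(derive_seed(seed, "correlated-channels"), {
    if (noise_sd > 0) B <- B + stats::rnorm(length(B), 0, noise_sd)
    for (i in keep) {
      semi <- pmax(footprint_scale * obj$radius_um[i] / vs, 0.5)
      fp <- which(ellipsoid_mask(dims, c(obj$z[i], obj$y[i], obj$x[i]), semi))
      if (length(fp) < 4L) next
      a <- A[fp]
      sda <- stats::sd(a)
      if (sda == 0) next
      za <- (a - mean(a)) / sda
      eps <- stats::rnorm(length(fp))
      B[fp] <- background + sda * (rho * za + sqrt(1 - rho^2) * eps)
      fps[[as.character(obj$id[i])]] <- fp
    }
  })
  out <- image_stack(list(chA = A, chB = B), voxel_size = vs)
  attr(out, "footprints") <- fps
  attr(out, "matching_threshold") <- 1000 * 2^(-footprint_scale^2)
  out
}
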