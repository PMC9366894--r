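test_that("percent of signal in objects covers the limiting cases exactly", {
  dims <- c(1L, 20L, 20L)
  cell <- array(TRUE, dim = dims)
  ch <- array(0, dim = dims)
  lab <- array(0L, dim = dims)
  ch[1, 5:8, 5:8] <- 50
  lab[1, 5:8, 5:8] <- 1L

  # all signal inside objects
  expect_equal(percent_signal_in_objects(ch, lab, cell, background = "none"), 100)
  # no objects
  expect_equal(percent_signal_in_objects(ch, array(0L, dims), cell,
                                         background = "none"), 0)
  # inside + outside partition the total exactly
  ch2 <- ch; ch2[1, 15, 15] <- 30
  inside <- percent_signal_in_objects(ch2, lab, cell, background = "none")
  outside <- percent_signal_in_objects(ch2, 1L * (lab == 0L), cell,
                                       background = "none")
  expect_equal(inside + outside, 100)
  # zero signal is an error
  expect_error(percent_signal_in_objects(array(0, dims), lab, cell,
                                         background = "none"), "zero total")
})

test_that("percent of signal in condensates recovers the generator's ratio", {
  # a mostly-diffuse pool with a small condensate-bound share, measured
  # without diffuse-pool subtraction (the pool is signal for this metric)
  sc <- generate_scene(noiseless_spec(seed = 31L, condensate_specs = list(
    condensate_class("sg", "cytoplasmic", count = 2L,
                     radius_um = c(0.18, 0.22), peak = c(gfp = 400))),
    min_sep_um = 1.2))
  cell <- sc$truth$cell_labels > 0L
  lab <- label_objects(sc$image$channels$gfp, threshold = 70)
  got <- percent_signal_in_objects(sc$image$channels$gfp, lab, cell,
                                   background = "none")
  total <- sum(sc$image$channels$gfp[cell])
  # remove the known diffuse-baseline contribution of the mask voxels: the
  # remainder is the measured condensate photon share, which must match the
  # generator's deposited photons
  baseline_in_mask <- 100 * 60 * sum(lab > 0L & cell) / total
  want <- 100 * sum(sc$truth$objects$integrated_gfp) / total
  expect_lt(want, 15)  # a small bound share, as in dim-foci conditions
  expect_lt(abs((got - baseline_in_mask) - want), 0.2)

  # with the diffuse level subtracted as numeric background, essentially all
  # remaining signal is condensate-bound
  got_corr <- percent_signal_in_objects(sc$image$channels$gfp, lab, cell,
                                        background = 60)
  expect_gt(got_corr, 97)
  expect_lte(got_corr, 100)
})

test_that("nucleocytoplasmic partition handles pure cases and generator truth", {
  dims <- c(1L, 20L, 20L)
  cell <- array(TRUE, dim = dims)
  nuc <- array(FALSE, dim = dims); nuc[1, 1:10, ] <- TRUE
  ch <- array(0, dims)

  ch_nuc <- ch; ch_nuc[1, 3:6, 3:6] <- 10
  expect_equal(nucleocytoplasmic_partition(ch_nuc, nuc, cell), 0)
  ch_cyt <- ch; ch_cyt[1, 14:16, 3:6] <- 10
  expect_equal(nucleocytoplasmic_partition(ch_cyt, nuc, cell), 100)
  expect_error(nucleocytoplasmic_partition(ch_cyt, cell, nuc), "within")

  # generator truth: uniform gfp baseline partitioned by voxel counts,
  # plus compartment-resolved condensate photons
  sc <- generate_scene(noiseless_spec(seed = 17L))
  cellm <- sc$truth$cell_labels > 0L
  nucm <- sc$truth$nuclear_mask
  got <- nucleocytoplasmic_partition(sc$image$channels$gfp, nucm, cellm)
  obj <- sc$truth$objects
  cyto_spots <- sum(obj$integrated_gfp[obj$compartment == "cytoplasmic"])
  total <- sum(sc$image$channels$gfp[cellm])
  base_cyto <- 60 * sum(cellm & !nucm)
  want <- 100 * (base_cyto + cyto_spots) / total
  expect_lt(abs(got - want), 2)
})

test_that("per-object Pearson matches hand computation and affine invariance", {
  dims <- c(1L, 4L, 4L)
  lab <- array(0L, dims); lab[1, 1, 1:4] <- 1L
  a <- array(0, dims); b <- array(0, dims)
  a[1, 1, 1:4] <- c(1, 2, 3, 4)
  b[1, 1, 1:4] <- c(2, 1, 4, 3)
  r <- per_object_pearson(lab, a, b)
  expect_equal(r$r, 0.6)  # cov = 1, sd product = 5/3
  expect_equal(r$n_voxels, 4L)

  # affine identity and anti-identity
  b2 <- 2 * a + 5
  expect_equal(per_object_pearson(lab, a, b2)$r, 1)
  expect_equal(per_object_pearson(lab, a, -a)$r, -1)
  # invariance under positive affine rescaling of either channel
  expect_equal(per_object_pearson(lab, 3 * a + 7, 0.5 * b + 1)$r, 0.6)

  # constant channel within the object is flagged, not a number
  bc <- array(5, dims)
  rc <- per_object_pearson(lab, a, bc)
  expect_true(rc$undefined)
  expect_true(is.na(rc$r))
})

test_that("body-content classification recovers a known positive fraction", {
  dims <- c(1L, 60L, 60L)
  cell <- array(TRUE, dims)
  set.seed(7)
  ch <- array(stats::rnorm(prod(dims), 100, 5), dims)
  lab <- array(0L, dims)
  # 20 bodies, 12 rendered with strong channel signal (60% positive)
  centers <- expand.grid(y = seq(5, 55, by = 12), x = seq(5, 55, by = 12))[1:20, ]
  for (i in 1:20) {
    ys <- centers$y[i] + (-1:1); xs <- centers$x[i] + (-1:1)
    lab[1, ys, xs] <- i
    if (i <= 12) ch[1, ys, xs] <- 1000
  }
  res <- classify_body_content(lab, ch, cell, enrichment_factor = 1.5)
  expect_equal(res$fraction_positive, 60)
  expect_equal(res$n_objects, 20L)

  # an object sitting exactly at background is negative
  labx <- array(0L, dims); labx[1, 1:2, 1:2] <- 1L
  chb <- array(100, dims)
  expect_equal(classify_body_content(labx, chb, cell, 1.5)$fraction_positive, 0)
  expect_warning(out <- classify_body_content(array(0L, dims), ch, cell),
                 "no objects")
  expect_true(is.na(out$fraction_positive))
})

test_that("docking events follow the surface-gap rule and are symmetric", {
  dims <- c(1L, 20L, 20L)
  sg <- array(0L, dims); pb <- array(0L, dims)
  sg[1, 5:8, 5:8] <- 1L
  pb[1, 5:8, 9:10] <- 1L    # shares a face with the SG
  pb[1, 15:16, 15:16] <- 2L # >= 3 background voxels away from anything
  ev <- docking_events(sg, pb, max_gap_voxels = 1L)
  expect_equal(ev$n_events, 1L)
  expect_equal(ev$events, data.frame(sg = 1L, pb = 1L))
  expect_equal(ev$events_per_sg, 1)

  # symmetry of the pair relation
  ev2 <- docking_events(pb, sg, max_gap_voxels = 1L)
  expect_equal(ev2$n_events, ev$n_events)

  # a gap of one background voxel still docks; three does not
  pb3 <- array(0L, dims); pb3[1, 5:8, 10:11] <- 1L
  expect_equal(docking_events(sg, pb3)$n_events, 1L)
  pb4 <- array(0L, dims); pb4[1, 5:8, 12:13] <- 1L
  expect_equal(docking_events(sg, pb4)$n_events, 0L)
})

test_that("docking counts on noiseless scenes equal the generator's docked pairs", {
  for (s in c(2L, 9L, 14L)) {
    spec <- noiseless_spec(seed = s, docking_fraction = 0.5)
    sc <- generate_scene(spec)
    sg <- exclude_nuclear_objects(
      label_objects(sc$image$channels$gfp, threshold = HALF_MAX_THRESHOLD),
      sc$truth$nuclear_mask)
    pb <- label_objects(sc$image$channels$stain, threshold = HALF_MAX_THRESHOLD)
    ev <- docking_events(sg, pb)
    expect_equal(ev$n_events, nrow(sc$truth$docked))
  }
})

test_that("per-cell counts aggregate correctly and respond to single additions", {
  ot <- data.frame(label = 1:3, size = c(0.5, 0.7, 0.9), cell = c(1L, 1L, 2L))
  cs <- count_and_size(ot, cells = 1:3)
  expect_equal(cs$n_objects, c(2L, 1L, 0L))
  expect_equal(cs$mean_size[1], 0.6)
  expect_true(is.na(cs$mean_size[3]))

  # empty table
  cs0 <- count_and_size(ot[0, ], cells = 1:2)
  expect_equal(cs0$n_objects, c(0L, 0L))

  # adding one object increments exactly one cell's count
  ot2 <- rbind(ot, data.frame(label = 4L, size = 0.2, cell = 2L))
  cs2 <- count_and_size(ot2, cells = 1:3)
  expect_equal(cs2$n_objects - cs$n_objects, c(0L, 1L, 0L))
})
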