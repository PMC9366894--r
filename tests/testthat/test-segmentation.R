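test_that("Otsu threshold separates well-separated modes and rejects degenerate input", {
  x <- c(rep(0, 100), rep(200, 100))
  t <- otsu_threshold(x)
  expect_gt(t, 0)
  expect_lt(t, 200)
  expect_true(all(x[x <= t] == 0) && all(x[x > t] == 200))
  expect_error(otsu_threshold(rep(5, 10)), "degenerate histogram")
})

test_that("Otsu threshold equals exhaustive between-class variance maximisation", {
  set.seed(101)
  for (i in 1:50) {
    # random 16-bit-style mixtures of two or three intensity populations
    k <- sample(2:3, 1)
    x <- unlist(lapply(seq_len(k), function(j)
      round(stats::rnorm(sample(50:400, 1), mean = stats::runif(1, 0, 65535),
                         sd = stats::runif(1, 100, 5000)))))
    x <- pmin(pmax(x, 0), 65535)
    if (length(unique(x)) < 2) next
    expect_equal(otsu_threshold(x), otsu_brute_force(x))
  }
})

test_that("Otsu tie-break picks the lowest maximising threshold", {
  # symmetric three-level histogram: cuts left or right of the middle mass
  # give identical between-class variance; the lower edge must win
  x <- c(rep(0, 100), rep(128, 100), rep(256, 100))
  t <- otsu_threshold(x, n_bins = 256L)
  tb <- otsu_brute_force(x, n_bins = 256L)
  expect_equal(t, tb)
  expect_lt(t, 128)  # the lower of the two optimal cut regions
})

test_that("segmentation is invariant to positive affine intensity rescaling", {
  sc <- generate_scene(scene_spec(seed = 21L))
  ch <- sc$image$channels$gfp
  lab1 <- label_objects(ch)
  lab2 <- label_objects(3.7 * ch + 120)
  expect_equal(as.integer(lab1), as.integer(lab2))
  expect_equal(attr(lab2, "threshold"), 3.7 * attr(lab1, "threshold") + 120,
               tolerance = 1e-9)
})

test_that("label_objects separates, filters and renumbers components", {
  m <- matrix(0, 20, 20)
  m[3:5, 3:5] <- 10          # 9 voxels
  m[10:12, 10:12] <- 10      # 9 voxels, separated by background
  m[18, 18] <- 10            # isolated voxel, below min size
  lab <- label_objects(m, threshold = 5, min_size_voxels = 4L)
  expect_equal(max(lab), 2L)
  expect_setequal(unique(as.integer(lab)), c(0L, 1L, 2L))
  # label partition: foreground + background voxels account for every voxel
  expect_equal(sum(tabulate(lab[lab > 0])) + sum(lab == 0L), length(m))

  # below-min-size spot alone yields no labels
  m2 <- matrix(0, 10, 10); m2[5, 5] <- 10
  expect_equal(max(label_objects(m2, threshold = 5, min_size_voxels = 4L)), 0L)

  # face vs full connectivity on a diagonal pair
  d <- matrix(0, 8, 8); d[3, 3] <- 10; d[4, 4] <- 10
  expect_equal(max(label_objects(d, threshold = 5, min_size_voxels = 1L,
                                 connectivity = "full")), 1L)
  expect_equal(max(label_objects(d, threshold = 5, min_size_voxels = 1L,
                                 connectivity = "face")), 2L)
})

test_that("nuclear segmentation finds nuclei, fills holes, tolerates empty input", {
  sc <- generate_scene(scene_spec(seed = 8L, n_cells = 3L,
                                  image_shape = c(1L, 200L, 200L)))
  nuc <- segment_nuclei(sc$image$channels$dapi)
  expect_equal(max(puncta:::label_components(nuc, "full")), 3L)

  # nucleus with a dim interior: mask is simply connected after filling
  m <- matrix(0, 40, 40)
  m[10:30, 10:30] <- 500
  m[18:22, 18:22] <- 0
  nm <- segment_nuclei(m, min_nuclear_voxels = 50L)
  expect_true(all(nm[1, 18:22, 18:22]))

  expect_warning(em <- segment_nuclei(matrix(0, 30, 30)), "no nucleus")
  expect_false(any(em))
})

test_that("nuclear exclusion follows the any-overlap rule and is idempotent", {
  m <- matrix(0, 30, 30)
  m[5:8, 5:8] <- 10     # fully inside nucleus
  m[14:17, 14:16] <- 10 # one-voxel overlap (nucleus ends at row 14)
  m[24:27, 24:27] <- 10 # fully outside
  nucmask <- array(FALSE, dim = c(1L, 30L, 30L))
  nucmask[1, 1:14, 1:30] <- TRUE
  lab <- label_objects(m, threshold = 5, min_size_voxels = 4L)
  expect_equal(max(lab), 3L)
  kept <- exclude_nuclear_objects(lab, nucmask)
  expect_equal(max(kept), 1L)
  # the retained object keeps its exact voxel set
  expect_equal(which(kept == 1L), which(lab == 3L))
  expect_equal(as.integer(exclude_nuclear_objects(kept, nucmask)),
               as.integer(kept))
})

test_that("object measurement reports exact sizes and intensities", {
  arr <- array(0, dim = c(3L, 6L, 6L))
  arr[1:3, 2:4, 2:4] <- 10  # 27-voxel cube of value 10
  st <- image_stack(list(gfp = arr), voxel_size = c(0.5, 0.1, 0.1))
  lab <- label_objects(arr, threshold = 5, min_size_voxels = 8L)
  ot <- measure_objects(lab, st)
  expect_equal(ot$n_voxels, 27L)
  expect_equal(ot$integrated_gfp, 270)
  expect_equal(ot$mean_gfp, 10)
  expect_equal(ot$size, 27 * 0.5 * 0.1 * 0.1)  # 0.135 um^3
  expect_equal(ot$integrated_gfp, ot$mean_gfp * ot$n_voxels)

  st_novs <- image_stack(list(gfp = arr), voxel_size = NULL)
  expect_warning(ot2 <- measure_objects(lab, st_novs), "voxel")
  expect_equal(ot2$size, 27)
})

test_that("measured intensities track ground truth on noiseless scenes", {
  # SGs only, widely separated so a low threshold can capture ~97% of each
  # spot's photons without adjacent masks merging
  sc <- generate_scene(noiseless_spec(seed = 31L, condensate_specs = list(
    condensate_class("sg", "cytoplasmic", count = c(2L, 3L),
                     radius_um = c(0.3, 0.4), peak = c(gfp = 800))),
    min_sep_um = 1.2))
  lab <- label_objects(sc$image$channels$gfp, threshold = 70)
  # subtract the cytoplasm baseline (present only inside the cell mask)
  corr <- sc$image$channels$gfp - 60 * (sc$truth$cell_labels > 0L)
  st_corr <- image_stack(list(gfp = corr), voxel_size = sc$image$voxel_size)
  ot <- measure_objects(lab, st_corr)
  truth <- sc$truth$objects[sc$truth$objects$integrated_gfp > 0, ]
  expect_equal(nrow(ot), nrow(truth))
  for (i in seq_len(nrow(ot))) {
    d <- sqrt((truth$y - ot$y[i])^2 + (truth$x - ot$x[i])^2)
    j <- which.min(d)
    expect_lt(abs(ot$integrated_gfp[i] - truth$integrated_gfp[j]) /
                truth$integrated_gfp[j], 0.05)
  }
})
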