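test_that("normalisation pins the anchors exactly and flags degenerate traces", {
  tr <- simulate_frap_trace(70, 2, noise_sd = 0.03, seed = 2L)
  nt <- correct_and_normalize(tr)
  n_pre <- attr(nt, "n_pre")
  expect_identical(nt$y[n_pre + 1L], 0)            # first post-bleach = 0
  expect_identical(max(nt$y[seq_len(n_pre)]), 100) # max pre-bleach = 100

  # constant trace: no bleach detectable
  flat <- frap_trace(time_s = 0:9, roi = rep(500, 10), n_pre = 3L)
  expect_error(correct_and_normalize(flat), "no bleach detected")
  expect_error(frap_trace(time_s = c(0, 1, 1, 2), roi = rep(1, 4), n_pre = 1L),
               "strictly increasing")
})

test_that("normalisation is idempotent and scale invariant", {
  tr <- simulate_frap_trace(60, 2, noise_sd = 0.02, seed = 3L)
  nt <- correct_and_normalize(tr)
  renorm <- correct_and_normalize(
    frap_trace(tr$time_s, nt$y, background = 0, n_pre = attr(nt, "n_pre")))
  expect_equal(renorm$y, nt$y, tolerance = 1e-12)

  scaled <- frap_trace(tr$time_s, 7.3 * tr$roi, background = 7.3 * tr$background,
                       reference = 7.3 * tr$reference, n_pre = 3L)
  expect_equal(correct_and_normalize(scaled)$y, nt$y, tolerance = 1e-9)
})

test_that("acquisition photobleaching cancels through the reference correction", {
  tr_clean <- simulate_frap_trace(60, 2, noise_sd = 0, seed = 1L,
                                  acquisition_bleach_rate = 0)
  tr_decay <- simulate_frap_trace(60, 2, noise_sd = 0, seed = 1L,
                                  acquisition_bleach_rate = 0.01)
  expect_equal(correct_and_normalize(tr_decay)$y,
               correct_and_normalize(tr_clean)$y, tolerance = 1e-6)
})

test_that("one-phase association fit is exact on noiseless model data", {
  x <- seq(0, 12, by = 0.5)
  y <- 60 * (1 - exp(-0.3466 * x))
  fit <- fit_one_phase(data.frame(x = x, y = y))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["plateau"]], 60, tolerance = 1e-3)
  expect_equal(fit$t_half_s, 2.000, tolerance = 1e-3)
  expect_equal(fit$t_half_s * coef(fit)[["K"]], log(2), tolerance = 1e-12)
  expect_equal(fit$mobile_fraction, coef(fit)[["plateau"]] - coef(fit)[["Y0"]])

  # all-zero post-bleach: immobile, rate undefined but flagged converged
  f0 <- fit_one_phase(data.frame(x = 0:9, y = rep(0, 10)))
  expect_true(f0$converged)
  expect_equal(f0$mobile_fraction, 0)
  expect_true(is.na(f0$t_half_s))
  expect_match(paste(f0$flags, collapse = " "), "K_undefined")
  expect_error(fit_one_phase(data.frame(x = 0:2, y = c(0, 1, 2))), "5 post-bleach")
})

test_that("a 28-point trace fits quickly and satisfies the rate identity", {
  tr <- simulate_frap_trace(69.6, 1.5, noise_sd = 0.02, seed = 12L)
  t0 <- Sys.time()
  fit <- fit_one_phase(correct_and_normalize(tr))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_true(fit$converged)
  expect_equal(fit$t_half_s * coef(fit)[["K"]], log(2), tolerance = 1e-12)
})

test_that("fits recover simulated mobile fraction and half-time", {
  errF <- errT <- numeric(50)
  for (i in 1:50) {
    tr <- simulate_frap_trace(60, 2, noise_sd = 0.03, seed = 100L + i)
    f <- fit_one_phase(correct_and_normalize(tr))
    errF[i] <- f$mobile_fraction - 60
    errT[i] <- (f$t_half_s - 2) / 2
  }
  expect_lt(abs(stats::median(errF)), 5)
  expect_lt(abs(stats::median(errT)), 0.15)
})

test_that("insufficient bleach and failed fits are flagged, never silent", {
  shallow <- simulate_frap_trace(60, 2, bleach_depth = 0.1, noise_sd = 0,
                                 seed = 1L)
  nt <- correct_and_normalize(shallow)
  expect_true("insufficient_bleach" %in% attr(nt, "qc_flags"))
  fit <- fit_one_phase(nt)
  expect_true("insufficient_bleach" %in% fit$flags)
})

test_that("frap_fit behaves like a model object", {
  tr <- simulate_frap_trace(70, 2, noise_sd = 0.02, seed = 8L)
  fit <- fit_one_phase(correct_and_normalize(tr))
  expect_s3_class(fit, "frap_fit")
  expect_named(coef(fit), c("Y0", "plateau", "K"))
  expect_equal(length(residuals(fit)), nrow(fit$data))
  expect_equal(predict(fit, data.frame(x = 0)), coef(fit)[["Y0"]],
               tolerance = 1e-9)
  expect_output(print(fit), "mobile fraction")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("group summaries report spread, exclusions and normality", {
  mk <- function(fm, th, seed) fit_one_phase(correct_and_normalize(
    simulate_frap_trace(fm, th, noise_sd = 0.01, seed = seed)))
  fits <- lapply(1:10, function(i) mk(60, 2, 200L + i))
  s <- summarize_frap_group(fits)
  expect_equal(s$n, 10L)
  expect_lt(abs(s$mobile_fraction$mean - 60), 3)
  expect_false(s$variance_undefined)

  # identical fits: zero spread
  same <- lapply(1:3, function(i) mk(60, 2, 999L))
  s2 <- summarize_frap_group(same)
  expect_equal(s2$mobile_fraction$sd, 0)
  expect_equal(s2$mobile_fraction$cv_percent, 0)
  expect_true(s2$t_half_s$sd == 0)

  # fewer than 3 usable fits flags undefined variance
  s3 <- summarize_frap_group(same[1:2])
  expect_true(s3$variance_undefined)

  # bimodal half-times (two kinetic populations) fail the normality gate
  bimodal <- c(lapply(1:15, function(i) mk(60, 1, 300L + i)),
               lapply(1:15, function(i) mk(60, 5, 400L + i)))
  s4 <- summarize_frap_group(bimodal)
  expect_lt(s4$t_half_s$normality_p, 0.05)
})
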