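test_that("boundary projection is the component inner product", {
  sc <- matrix(rnorm(3 * 7), 3, 7)
  expect_equal(project_boundary_timecourse(sc, c(1, 0, 0)), sc[1, ])
  # orthogonal weights see nothing
  sc1 <- rbind(rnorm(7), 0, 0)
  expect_equal(project_boundary_timecourse(sc1, c(0, 1, 0)), rep(0, 7))
  # linearity
  x <- matrix(rnorm(21), 3); y <- matrix(rnorm(21), 3)
  w <- c(0.6, -0.64, 0.48); w <- w / sqrt(sum(w^2))
  expect_equal(project_boundary_timecourse(2 * x + 3 * y, w),
               2 * project_boundary_timecourse(x, w) +
                 3 * project_boundary_timecourse(y, w))
  # array input gives time x trials
  arr <- array(rnorm(3 * 5 * 4), dim = c(3, 5, 4))
  out <- project_boundary_timecourse(arr, w)
  expect_equal(dim(out), c(5, 4))
  expect_equal(out[, 2], as.numeric(crossprod(arr[, , 2], w)))
})

test_that("sequential segments are contiguous presentation-order blocks", {
  cfg <- tiny_config(n_subjects = 1, n_regions = 1, n_trials = 80, noise_sd = 1)
  parc <- build_synthetic_parcellation(1, 5, seed = cfg$seed)
  comp <- extract_region_components(simulate_subject(cfg, 1, parc)$epochs, parc)
  segs <- sequential_segment_average(comp, stimulus = 2, section = 1)
  expect_equal(dim(segs), c(1, 3, 81, 10))
  expect_equal(attr(segs, "segment_sizes"), rep(8L, 10))
  # first segment = mean of the 8 first-presented trials
  lab <- comp$labels
  i <- which(lab$stimulus == 2 & lab$section == 1)
  first8 <- i[order(lab$presentation_order[i])][1:8]
  manual <- apply(comp$scores[[1]][, , first8], c(1, 2), mean)
  expect_equal(array(segs[1, , , 1], dim = c(3, 81)), manual)

  # 50 trials -> ten blocks of 5
  cfg50 <- tiny_config(n_subjects = 1, n_regions = 1, n_trials = 50)
  parc50 <- build_synthetic_parcellation(1, 5, seed = cfg50$seed)
  comp50 <- extract_region_components(simulate_subject(cfg50, 1, parc50)$epochs,
                                      parc50)
  segs50 <- sequential_segment_average(comp50, stimulus = 1)
  expect_equal(attr(segs50, "segment_sizes"), rep(5L, 10))
})

test_that("under-sampled conditions are excluded from segmentation", {
  trials <- matrix(60L, 6, 2); trials[1, 1] <- 49L
  cfg <- tiny_config(n_subjects = 1, n_regions = 1, n_trials = trials)
  parc <- build_synthetic_parcellation(1, 5, seed = cfg$seed)
  comp <- extract_region_components(simulate_subject(cfg, 1, parc)$epochs, parc)
  expect_warning(res <- sequential_segment_average(comp, 1, 1), "excluded")
  expect_null(res)
})

test_that("segment amplitudes: window mean, exemplar mean, then absolute value", {
  tm <- seq(-100, 700, 10)
  win <- c(140, 170)
  seg_const <- function(val) matrix(val, length(tm), 10)
  # constant -2 for both exemplars -> amplitude 2
  amp <- repetition_amplitudes(list(seg_const(-2), seg_const(-2)), tm, win)
  expect_equal(amp, rep(2, 10))
  # exemplars +1 and +3 -> mean 2
  amp2 <- repetition_amplitudes(list(seg_const(1), seg_const(3)), tm, win)
  expect_equal(amp2, rep(2, 10))
  # exemplars +1 and -3 average before the absolute value
  amp3 <- repetition_amplitudes(list(seg_const(1), seg_const(-3)), tm, win)
  expect_equal(amp3, rep(1, 10))
  # one-bin window picks exactly that bin
  m <- seg_const(0); m[tm == 300, ] <- -4
  expect_equal(repetition_amplitudes(list(m), tm, c(300, 300)), rep(4, 10))
})

test_that("amplitudes are invariant to a global boundary sign flip", {
  withr::with_seed(3, {
    ex1 <- array(rnorm(3 * 81 * 10), dim = c(3, 81, 10))
    ex2 <- array(rnorm(3 * 81 * 10), dim = c(3, 81, 10))
  })
  w <- c(0.2, -0.5, 0.3); w <- w / sqrt(sum(w^2))
  tm <- seq(-100, 700, 10)
  ampl <- function(wv) {
    repetition_amplitudes(list(project_boundary_timecourse(ex1, wv),
                               project_boundary_timecourse(ex2, wv)),
                          tm, c(100, 200))
  }
  expect_equal(ampl(w), ampl(-w))
})

test_that("pooled regression has df (1, 10n - 2) and matches lm", {
  withr::with_seed(9, {
    amp <- tidyr::expand_grid(subject = 1:22, segment = 1:10)
    amp$amplitude <- 1 + 0.1 * amp$segment + rnorm(nrow(amp), sd = 0.3)
  })
  fit <- repetition_regression(amp)
  expect_equal(fit$df, c(1L, 218L))
  ref <- lm(amplitude ~ segment, data = amp)
  expect_equal(fit$k, unname(coef(ref)[2]))
  expect_equal(fit$F, unname(summary(ref)$fstatistic[1]))
  expect_equal(fit$p_value, anova(ref)[["Pr(>F)"]][1])
  g <- glance(fit)
  expect_equal(g$df2, 218)
})

test_that("a perfectly linear trend is recovered exactly", {
  amp <- tidyr::expand_grid(subject = 1:3, segment = 1:10)
  amp$amplitude <- 2 + 0.25 * amp$segment
  fit <- repetition_regression(amp)
  expect_equal(fit$k, 0.25)
  expect_equal(fit$F, Inf)
  expect_equal(fit$p_value, 0)
})

test_that("the slope F-test is calibrated under an i.i.d. null", {
  withr::with_seed(21, {
    pvals <- vapply(1:200, function(i) {
      amp <- tidyr::expand_grid(subject = 1:5, segment = 1:10)
      amp$amplitude <- rnorm(nrow(amp))
      repetition_regression(amp)$p_value
    }, numeric(1))
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("the full repetition path recovers an injected amplitude trend", {
  cfg <- tiny_config(
    n_subjects = 1, n_regions = 2, n_trials = 80, noise_sd = 0.3, seed = 17,
    effects = list(
      effect_spec("repetition_trend", target_regions = 1,
                  window_ms = c(140, 170), amplitude = 4, category = "face",
                  trend_slope = 0.5)))
  parc <- build_synthetic_parcellation(2, 5, seed = cfg$seed)
  comp <- extract_region_components(simulate_subject(cfg, 1, parc)$epochs, parc)
  ent <- rsa_entries()
  fn_pairs <- entry_pairs()[
    ent$group[entry_pairs()$a] == "face" & ent$group[entry_pairs()$b] == "nonsense", ]
  dec <- decode_conditions(comp, n_randomizations = 20, min_trials = 50,
                           regions = 1, pairs = fn_pairs, seed = 4)
  series <- repetition_series(comp, dec, region = 1, category = "face",
                              window_ms = c(140, 170))
  expect_equal(series$segment, 1:10)
  expect_true(all(series$amplitude >= 0))
  # amplitudes rise with segment: positive fitted slope
  series$subject <- 1
  k <- with(series, cov(segment, amplitude) / var(segment))
  expect_gt(k, 0)
  expect_gt(cor(series$segment, series$amplitude), 0.9)
})
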