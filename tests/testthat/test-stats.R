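make_z_tbl <- function(z_by_subject, region = 1, time_ms = 100) {
  tidyr::expand_grid(subject = seq_along(z_by_subject), region = region,
                     time_ms = time_ms) |>
    dplyr::mutate(z = z_by_subject[subject])
}

test_that("region-time t-test matches the closed form", {
  tt <- region_time_ttest(make_z_tbl(c(0.2, 0.4, 0.6)))
  expect_equal(tt$t, 3.464, tolerance = 1e-3)
  expect_equal(tt$n, 3)
  expect_equal(tt$p, 2 * pt(-3.4641016, df = 2), tolerance = 1e-6)

  # scale invariance
  tt2 <- region_time_ttest(make_z_tbl(7.3 * c(0.2, 0.4, 0.6)))
  expect_equal(tt2$t, tt$t)

  # all-zero input: t = 0, p = 1 (degenerate, flagged)
  expect_warning(tt0 <- region_time_ttest(make_z_tbl(c(0, 0, 0))),
                 "zero variance")
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  expect_true(tt0$degenerate)

  # zero variance around a nonzero mean -> p = 0
  expect_warning(ttc <- region_time_ttest(make_z_tbl(c(0.3, 0.3, 0.3))))
  expect_equal(ttc$p, 0)
})

test_that("one-sided testing halves the positive tail", {
  tt2s <- region_time_ttest(make_z_tbl(c(0.2, 0.4, 0.6)))
  tt1s <- region_time_ttest(make_z_tbl(c(0.2, 0.4, 0.6)), one_sided = TRUE)
  expect_equal(tt1s$p, tt2s$p / 2)
  neg <- region_time_ttest(make_z_tbl(-c(0.2, 0.4, 0.6)), one_sided = TRUE)
  expect_gt(neg$p, 0.9)
})

test_that("BH mask equals the brute-force step-up oracle", {
  p5 <- c(0.001, 0.02, 0.03, 0.04, 0.2)
  tt <- tibble::tibble(region = 1:5, time_ms = 10, p = p5)
  sig <- fdr_mask(tt, q = 0.05)
  expect_equal(sum(sig$significant), 4)
  expect_equal(sig$significant, bh_oracle(p5, 0.05))

  withr::with_seed(31, {
    for (len in c(10, 100, 5000)) {
      p <- runif(len)^2
      tt <- tibble::tibble(region = seq_len(len), time_ms = 0, p = p)
      for (q in c(0.01, 0.05, 0.2)) {
        expect_equal(fdr_mask(tt, q)$significant, bh_oracle(p, q))
      }
      # monotonicity: lowering q never adds rejections
      expect_true(all(fdr_mask(tt, 0.01)$significant <=
                        fdr_mask(tt, 0.05)$significant))
    }
  })

  # all p = 1 -> nothing significant
  tt1 <- tibble::tibble(region = 1:4, time_ms = 0, p = rep(1, 4))
  expect_equal(sum(fdr_mask(tt1, 0.05)$significant), 0)
})

test_that("per-model FDR levels follow the model-type convention", {
  tt <- tidyr::expand_grid(model = c("recognizer", "face_specific"),
                           region = 1:3, time_ms = c(0, 10))
  tt$p <- 0.5
  sig <- fdr_mask(tt)
  expect_equal(unique(sig$q[sig$model == "recognizer"]), 0.01)
  expect_equal(unique(sig$q[sig$model == "face_specific"]), 0.05)
  sig2 <- fdr_mask(tt, q = 0.2)
  expect_equal(unique(sig2$q), 0.2)
})

test_that("onsets are the first post-stimulus significant bin", {
  grid <- tibble::tibble(region = 1, time_ms = seq(-100, 700, 10),
                         significant = FALSE)
  g1 <- grid; g1$significant[g1$time_ms %in% c(140, 150)] <- TRUE
  expect_equal(onset_time(g1, 1), 140)
  # pre-stimulus significance alone gives no onset
  g2 <- grid; g2$significant[g2$time_ms == -50] <- TRUE
  expect_true(is.na(onset_time(g2, 1)))
  expect_true(is.na(onset_time(grid, 1)))
  # minimum run length skips isolated bins
  g3 <- grid; g3$significant[g3$time_ms %in% c(120, 300, 310, 320)] <- TRUE
  expect_equal(onset_time(g3, 1), 120)
  expect_equal(onset_time(g3, 1, min_run = 2), 300)
})

test_that("bootstrap of a constant is degenerate and rejects", {
  bs <- bootstrap_characteristic(rep(5, 8), seed = 2)
  expect_equal(bs$estimate, 5)
  expect_equal(bs$ci_low, 5)
  expect_equal(bs$ci_high, 5)
  expect_equal(bs$n_boot, 1000)
  expect_true(bs$reject)
  expect_true(bs$ci_low <= bs$estimate && bs$estimate <= bs$ci_high)
})

test_that("bootstrap test is roughly calibrated under a symmetric null", {
  withr::with_seed(77, {
    rejects <- vapply(1:300, function(i) {
      vals <- sample(c(-1, 1), 20, replace = TRUE)
      bootstrap_characteristic(vals, n_boot = 200, seed = i)$reject
    }, logical(1))
  })
  rate <- mean(rejects)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})

test_that("decodability characteristics summarise onset, peak and mean", {
  tm <- seq(-100, 700, 10)
  val <- exp(-((tm - 150) / 80)^2)
  map <- tibble::tibble(region = 1, time_ms = tm, value = val,
                        significant = tm >= 60 & tm <= 400)
  ch <- decodability_characteristics(map, window_ms = c(50, 700))
  expect_equal(ch$onset_ms, 60)
  expect_equal(ch$peak_ms, 150)
  expect_equal(ch$peak, 1)
  expect_equal(ch$mean_value, mean(val[tm >= 50]))
})

test_that("hemisphere averaging collapses 82 regions to 41 areas", {
  atlas <- load_region_table()
  maps <- tibble::tibble(subject = 1, region = 1:82, z = as.numeric(1:82))
  avg <- average_hemispheres(maps, atlas)
  expect_equal(nrow(avg), 41)
  # each area's value is the mean of its left/right pair (consecutive rows)
  fp <- avg$z[avg$area == "FPole"]
  expect_equal(fp, mean(c(1, 2)))
})

test_that("Bartlett dimensionality test has the printed df at full size", {
  withr::with_seed(5, {
    z <- tidyr::expand_grid(subject = 1:22, area = paste0("a", 1:41),
                            model = c("m1", "m2", "m3"))
    z$z <- rnorm(nrow(z), sd = 0.1)
  })
  res <- manova_model_specificity(z)
  expect_equal(res$df, 40)
  expect_equal(res$n_obs, 66)
  expect_equal(res$n_areas, 41)
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(glance(res)$df, 40)
})

test_that("collinear group means reject at roughly the nominal rate", {
  n_sub <- 12; n_area <- 5
  withr::with_seed(41, {
    pvals <- vapply(1:200, function(i) {
      u <- rnorm(n_area)
      z <- tidyr::expand_grid(subject = seq_len(n_sub),
                              area = paste0("a", seq_len(n_area)),
                              model = c("m1", "m2", "m3"))
      # means exactly on a line through the origin: mean_m = m * u
      m_idx <- match(z$model, c("m1", "m2", "m3"))
      a_idx <- match(z$area, paste0("a", seq_len(n_area)))
      z$z <- m_idx * u[a_idx] + rnorm(nrow(z), sd = 1)
      manova_model_specificity(z)$p_value
    }, numeric(1))
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("strongly non-collinear means yield decisive rejection", {
  n_sub <- 15; n_area <- 8
  withr::with_seed(42, {
    u <- rnorm(n_area); v <- rnorm(n_area)
    z <- tidyr::expand_grid(subject = seq_len(n_sub),
                            area = paste0("a", seq_len(n_area)),
                            model = c("m1", "m2", "m3"))
    means <- list(m1 = u, m2 = v, m3 = u + 2 * v)
    a_idx <- match(z$area, paste0("a", seq_len(n_area)))
    z$z <- mapply(function(m, a) means[[m]][a], z$model, a_idx) +
      rnorm(nrow(z), sd = 0.2)
  })
  res <- manova_model_specificity(z)
  expect_lt(res$p_value, 0.006)
})
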