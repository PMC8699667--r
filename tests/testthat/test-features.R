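test_that("basic RR statistics use the sample variance", {
  expect_equal(unname(basic_features(c(400, 400, 400))), c(400, 0))
  b <- basic_features(c(270, 270, 460))
  expect_equal(unname(b["RRmean"]), 1000 / 3, tolerance = 1e-12)
  expect_equal(unname(b["RRvar"]), var(c(270, 270, 460)))
  expect_error(basic_features(200), class = "heatrr_invalid")
})

test_that("moving windows slide with stride one", {
  expect_equal(nrow(moving_windows(22, 17)), 6)
  expect_equal(nrow(moving_windows(12, 10)), 3)
  w <- moving_windows(22, 22)
  expect_equal(nrow(w), 1)
  expect_equal(unname(w[1, ]), c(1, 22))
  w <- moving_windows(22, 17)
  expect_equal(w[, "end"] - w[, "start"], rep(16, 6))
  expect_error(moving_windows(22, 9), class = "heatrr_invalid")
  expect_error(moving_windows(12, 13), class = "heatrr_invalid")
})

test_that("heat features follow the 9-feature solution layout", {
  rr <- bt2_series(delta_a = 200, n = 22)
  f <- heat_features(rr, ctl_small())
  expect_length(f, 9)
  expect_equal(names(f)[1], "HEATobj")
  expect_equal(unname(f["HEATobj"]), 0)
  expect_equal(unname(f["delta_a"]), 200)
  expect_equal(unname(f["RRvar"]), 0)
  expect_equal(unname(f["RRmean"]), 400)
  expect_false(attr(f, "clipped"))
  ## infeasible input saturates at sqrt(n) * clip with zeroed solution
  y <- rep(c(200, 1400), 6)
  f2 <- heat_features(y, ctl_small())
  expect_equal(unname(f2["HEATobj"]), sqrt(12) * 150)
  expect_equal(unname(f2["delta_a"]), 0)
  expect_true(attr(f2, "clipped"))
})

test_that("moving-horizon series are exact on stationary noiseless data", {
  p <- mavb_params(240, list(block_level("II", list(c(3, 2)), phase = 1)),
                   blocktype_id = 2L)
  rr <- forward_simulate(p, 14)$ventricular_rr
  hs <- heat_series(rr, 10, ctl_small())
  expect_equal(nrow(hs$windows), 5)
  expect_equal(hs$HEATobj, rep(0, 5))
  expect_equal(hs$HEATfit, rep(0, 5))
  expect_equal(length(hs$HEATobj), length(hs$HEATfit))
  expect_equal(nrow(hs$HEATsol), 5)
  ## all windows agree on the atrial cycle
  expect_true(all(hs$HEATsol[, "delta_a"] == 240))
})

test_that("series averages are mean and sample sd per component", {
  p <- mavb_params(240, list(block_level("II", list(c(3, 2)))),
                   blocktype_id = 2L)
  rr <- forward_simulate(p, 14)$ventricular_rr
  hs <- heat_series(rr, 10, ctl_small())
  avg <- series_avg(hs)
  expect_length(avg, 2 * (2 + ncol(hs$HEATsol)))
  expect_equal(unname(avg["HEATobj_mean"]), 0)
  expect_equal(unname(avg["HEATobj_sd"]), 0)
  expect_equal(unname(avg["delta_a_mean"]), 240)
  avg_age <- series_avg(hs, age = 61)
  expect_equal(unname(avg_age["age"]), 61)
  expect_length(avg_age, length(avg) + 1)
  ## hand-computed mean/sd of a component
  hs$HEATobj <- c(0, 0, 0, 0, 6)
  hs$HEATfit <- rep(0, 5)
  a2 <- series_avg(hs)
  expect_equal(unname(a2["HEATobj_mean"]), 1.2)
  expect_equal(unname(a2["HEATobj_sd"]), sd(c(0, 0, 0, 0, 6)))
})

test_that("N-gram features enumerate all contiguous subsequences", {
  f <- ngram_features(c(1, 2, 3))
  expect_length(f, 9)
  expect_equal(unname(f[c("mean_s1_l1", "mean_s2_l1", "mean_s3_l1")]),
               c(1, 2, 3))
  expect_equal(unname(f[c("mean_s1_l2", "mean_s2_l2", "mean_s1_l3")]),
               c(1.5, 2.5, 2))
  expect_equal(unname(f[c("sd_s1_l2", "sd_s2_l2", "sd_s1_l3")]),
               c(sd(1:2), sd(2:3), 1))
  ## n^2 identity drives the standardization parameter counts
  expect_length(ngram_features(seq_len(22)), 484)
  expect_length(ngram_features(seq_len(10)), 100)
  expect_error(ngram_features(5), class = "heatrr_invalid")
  ## agrees with direct enumeration on a random vector
  set.seed(7)
  x <- rnorm(6)
  f <- ngram_features(x)
  for (s in 1:5) for (l in 2:(6 - s + 1)) {
    expect_equal(unname(f[sprintf("mean_s%d_l%d", s, l)]),
                 mean(x[s:(s + l - 1)]))
    expect_equal(unname(f[sprintf("sd_s%d_l%d", s, l)]),
                 sd(x[s:(s + l - 1)]))
  }
})

test_that("standardization is leakage-free and invertible", {
  set.seed(8)
  train <- matrix(rnorm(40, 10, 3), 10, 4)
  test <- matrix(rnorm(20, 12, 3), 5, 4)
  sp <- fit_standardizer(train)
  zt <- apply_standardizer(sp, train)
  expect_equal(unname(colMeans(zt)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zt, 2, sd)), rep(1, 4), tolerance = 1e-12)
  ## params learned on train: held-out columns are generally not centered
  zh <- apply_standardizer(sp, test)
  expect_gt(max(abs(colMeans(zh))), 0.01)
  ## round trip recovers the originals
  back <- sweep(sweep(zh, 2, sp$scale, `*`), 2, sp$center, `+`)
  expect_equal(unname(back), unname(test), tolerance = 1e-9)
  ## the two-point example
  sp2 <- fit_standardizer(matrix(c(1, 3), 2, 1))
  expect_equal(unname(sp2$center), 2)
  expect_equal(unname(sp2$scale), sd(c(1, 3)))
  expect_equal(as.numeric(apply_standardizer(sp2, matrix(2))), 0)
  ## constant columns warn and get scale 1
  expect_warning(sp3 <- fit_standardizer(cbind(c(1, 2, 3), c(5, 5, 5))),
                 "constant")
  expect_equal(unname(sp3$scale[2]), 1)
})

test_that("feature-set matrices have the documented dimensions", {
  cfg <- generator_config(n_per_class = 3)
  bench <- make_benchmark(cfg, seed = 31)
  ctl <- ctl_small()
  expect_equal(dim(heat_feature_set(bench$samples, "rawRR")), c(6, 22))
  expect_equal(dim(heat_feature_set(bench$samples, "rawRR_ngram",
                                    n_sub = 10)), c(6, 100))
  X <- heat_feature_set(bench$samples, "heatObjective", control = ctl)
  expect_equal(dim(X), c(6, 1))
  Xs <- heat_feature_set(bench$samples, "heatSolution", control = ctl)
  expect_equal(ncol(Xs), 9)
  expect_equal(rownames(Xs), bench$samples$sample_id)
})
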