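test_that("ratio gating reproduces a hand-enumerated 4x4 example", {
  # constructed mixed scene: ratios 1 (signal), 8 (out of gate), plus a
  # dim pixel that survives the ratio gate but fails the background cut
  den <- matrix(100, 4, 4)
  num <- matrix(100, 4, 4)
  num[1, 1] <- 800            # ratio 8 -> ratio-excluded
  num[2, 2] <- 150            # ratio 1.5, bright -> included
  num[3, 3] <- 20; den[3, 3] <- 20   # ratio 1 but dim in both channels
  res <- compute_ratio_result(num, den, ratio_config("rogfp"))
  # oracle: enumerate per pixel
  r <- as.vector(num / den)
  in_gate <- r >= 0.25 & r <= 4
  expect_equal(res$n_excluded_ratio, sum(!in_gate))
  mn <- mean(num[in_gate]); md <- mean(den[in_gate])
  inc <- in_gate & num >= 0.5 * mn & den >= 0.5 * md
  expect_equal(res$n_excluded_bg, sum(in_gate) - sum(inc))
  expect_equal(res$mean_ratio, mean(r[inc]))
  expect_equal(res$n_included + res$n_excluded_ratio + res$n_excluded_bg, 16)
})

test_that("uniform equal channels give ratio 1 and all-out-of-gate errors", {
  u <- matrix(100, 8, 8)
  res <- compute_ratio_result(u, u)
  expect_equal(res$mean_ratio, 1.0)
  expect_equal(res$n_excluded_ratio, 0)
  expect_equal(res$n_excluded_bg, 0)
  expect_error(compute_ratio_result(5 * u, u), "no signal")
  expect_error(compute_ratio_result(u, matrix(1, 4, 4)), "shape")
})

test_that("ratio scoring is invariant to common rescaling and channel swap", {
  sc <- gen_redox_scene(true_ratio = 1.8, noise_sd = 10, seed = 21)
  res <- compute_ratio_result(sc$numerator, sc$denominator)
  scaled <- compute_ratio_result(unclass(sc$numerator) * 3.7,
                                 unclass(sc$denominator) * 3.7)
  expect_equal(scaled$mean_ratio, res$mean_ratio)
  expect_equal(scaled$n_included, res$n_included)
  # reciprocal bounds + swapped channels: included ratios map to reciprocals
  swapped <- compute_ratio_result(sc$denominator, sc$numerator)
  expect_equal(swapped$n_included, res$n_included)
  expect_equal(swapped$n_excluded_ratio, res$n_excluded_ratio)
})

test_that("masked pixels are removed before gating", {
  sc <- gen_redox_scene(true_ratio = 2, noise_sd = 0, dim = c(8, 8, 1), seed = 3)
  mask <- array(0, c(8, 8, 1)); mask[1:4, , 1] <- 1
  res <- compute_ratio_result(sc$numerator, sc$denominator, mask = mask)
  expect_equal(res$n_masked, 32)
  expect_equal(res$n_included + res$n_excluded_ratio + res$n_excluded_bg, 32)
})

test_that("percent oxidation interpolates the DA/DTT calibration", {
  cal <- redox_calibration(da_mean = 3.26, dtt_mean = 1.0, cell_type = "neuron")
  expect_equal(percent_oxidized(1.0, cal), 0)
  expect_equal(percent_oxidized(3.26, cal), 100)
  expect_equal(percent_oxidized((3.26 + 1) / 2, cal), 50)
  expect_warning(out <- percent_oxidized(4.0, cal), "outside")
  expect_gt(out, 100)
  # affine invariance under common rescaling of x, DA, DTT
  k <- 7.3
  calk <- redox_calibration(3.26 * k, 1.0 * k)
  expect_equal(percent_oxidized(2 * k, calk), percent_oxidized(2, cal))
  expect_error(redox_calibration(1, 1), "da_mean > dtt_mean")
})

test_that("group-mean normalization fixes the control mean at 1", {
  expect_equal(normalize_to_group_mean(c(2, 4), c(1, 3)), c(1, 2))
  ctrl <- c(1.2, 0.8, 1.1)
  expect_equal(mean(normalize_to_group_mean(ctrl, ctrl)), 1)
  expect_error(normalize_to_group_mean(1:3, c(-1, 1)), "positive")
  # pooled pseudo-experiments keep within-experiment order
  set.seed(5)
  e1 <- rlnorm(8); e2 <- rlnorm(8) * 10
  pooled <- c(normalize_to_group_mean(e1, e1[1:4]),
              normalize_to_group_mean(e2, e2[1:4]))
  expect_equal(order(pooled[1:8]), order(e1))
  expect_equal(order(pooled[9:16]), order(e2))
})

test_that("CaLexA index equals the ratio of stack totals", {
  g <- array(2, c(4, 4, 3)); r <- array(1, c(4, 4, 3))
  expect_equal(calexa_index(g, r), 2.0)
  expect_error(calexa_index(g, array(0, c(4, 4, 3))), "zero")
  set.seed(8)
  g <- array(runif(64, 0, 50), c(4, 4, 4))
  r <- array(runif(64, 1, 50), c(4, 4, 4))
  expect_equal(calexa_index(g, r), sum(g) / sum(r))
})

test_that("MDA intensity is the sum-projection mean above threshold", {
  expect_equal(mda_mean_intensity(matrix(10, 5, 5), 5), 10)
  expect_error(mda_mean_intensity(matrix(3, 5, 5), 5), "above")
  # two-slice constructed stack vs hand-summed projection
  s <- array(c(1, 2, 3, 4, 10, 20, 30, 40), c(2, 2, 2))
  proj <- matrix(c(11, 22, 33, 44), 2, 2)
  expect_equal(mda_mean_intensity(s, 20), mean(proj[proj > 20]))
})
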