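test_that("map generation is deterministic and validates its scenario", {
  sph <- build_sphere()
  sc <- substrate_scenario(n_points = 120, seed = 9)
  expect_identical(generate_map(sc, sph), generate_map(sc, sph))
  expect_error(substrate_scenario(n_points = 0), "positive")
  expect_error(substrate_scenario(
    scar_patches = list(list(region = 9, radius_deg = 10, mean = 0.2))))
  expect_error(substrate_scenario(
    scar_patches = list(list(region = 2, radius_deg = -1, mean = 0.2))),
    "angular radius")
})

test_that("a no-abnormality noise-free map is uniformly healthy", {
  sph <- build_sphere()
  sc <- substrate_scenario(
    n_points = 200, seed = 10,
    noise_sd = c(uni = 0, bip = 0, lat = 0, imp = 0),
    baseline = list(uni = 8, bip = 3, lat0 = -20, lat_slope = 0,
                    uni_x_slope = 0, imp = 100))
  ex <- generate_map(sc, sph)
  expect_true(all(ex$points$bip_v == 3))
  expect_equal(sum(ex$points$bip_v < 0.5), 0)
  expect_true(all(ex$points$lat == -20))
})

test_that("scar patches depress exactly the points inside the patch geometry", {
  sph <- build_sphere()
  sc <- substrate_scenario(
    n_points = 800, seed = 11, jitter_sd = 0,
    noise_sd = c(uni = 0, bip = 0, lat = 0, imp = 0),
    baseline = list(uni = 8, bip = 3, lat0 = -20, lat_slope = 0,
                    uni_x_slope = 0, imp = 100),
    scar_patches = list(list(region = 3, radius_deg = 30, mean = 0.2)))
  ex <- generate_map(sc, sph)
  # brute-force membership: angular distance of each point direction to the
  # region-3 centroid direction
  P <- as.matrix(ex$points[, c("x", "y", "z")])
  dirs <- P / sqrt(rowSums(P^2))
  ctr <- region_centroid(sph, 3)
  inside <- acos(pmin(1, pmax(-1, dirs %*% ctr))) <= 30 * pi / 180
  expect_equal(unname(ex$points$bip_v < 0.5), as.vector(inside))
  expect_equal(mean(ex$points$bip_v < 0.5), mean(inside))
  expect_equal(attr(ex, "planted")$scar, as.vector(inside))
})

test_that("late patches and the isthmus ramp shift activation times additively", {
  sph <- build_sphere()
  base_sc <- substrate_scenario(
    n_points = 400, seed = 12, noise_sd = c(uni = 0, bip = 0, lat = 0, imp = 0))
  late_sc <- substrate_scenario(
    n_points = 400, seed = 12, noise_sd = c(uni = 0, bip = 0, lat = 0, imp = 0),
    late_patches = list(list(region = 2, radius_deg = 20, offset = 35)))
  b <- generate_map(base_sc, sph); l <- generate_map(late_sc, sph)
  m <- attr(l, "planted")$late
  expect_true(any(m))
  expect_equal(l$points$lat[m], b$points$lat[m] + 35)
  expect_equal(l$points$lat[!m], b$points$lat[!m])
})

test_that("clinical covariates follow their documented distributions", {
  co <- generate_clinical(10, seed = 2)
  expect_true(all(co$NYHA %in% 1:4))
  expect_false(anyNA(co))
  expect_identical(co, generate_clinical(10, seed = 2))

  big <- generate_clinical(10000, seed = 3)
  # truncation at 10 barely moves the configured mean-30 sd-8 pulmonary pressure
  se <- 8 / sqrt(10000)
  expect_lt(abs(mean(big$PAP) - 30), 3 * se + 0.05)
  expect_true(all(big$PAP >= 10))
  expect_true(all(big$Hypertension %in% 0:1))
  expect_lt(abs(mean(big$Hypertension) - 0.5), 3 * sqrt(0.25 / 10000))

  miss <- generate_clinical(2000, seed = 4, missing_rate = 0.3)
  frac <- mean(is.na(miss$TAPSE))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_error(generate_clinical(0), "positive")
})

test_that("outcome assignment follows the generative logistic model", {
  # zero model: symmetric coin
  co <- generate_clinical(4000, seed = 5)
  out <- assign_outcomes(co, outcome_model(intercept = 0,
                                           coefficients = c(NYHA = 0)), seed = 6)
  expect_lt(abs(mean(out$MAE) - 0.5), 3 * sqrt(0.25 / 4000))

  # logit-zero crossing: intercept/coefficient = 21.007/3.889 = 5.4015
  co2 <- co; co2$NYHA <- 21.007 / 3.889
  out2 <- assign_outcomes(co2, outcome_model(intercept = -21.007,
                                             coefficients = c(NYHA = 3.889)),
                          seed = 7)
  expect_equal(attr(out2, "p_mae"), rep(0.5, 4000))

  # empirical rate converges to the mean generative probability
  out3 <- assign_outcomes(generate_clinical(20000, seed = 8,
                                            include_features = TRUE),
                          seed = 9)
  p <- attr(out3, "p_mae")
  se <- sqrt(sum(p * (1 - p))) / 20000
  expect_lt(abs(mean(out3$MAE) - mean(p)), 3 * se)

  expect_error(assign_outcomes(co, outcome_model(coefficients = c(GhostVar = 1))),
               "GhostVar")
})
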