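make_fmap <- function(faces, sphere, uni = 8, bip = 3, lat = 0, imp = 100) {
  n <- length(faces)
  structure(list(face = faces, point = seq_len(n),
                 values = data.frame(uni_v = rep_len(uni, n),
                                     bip_v = rep_len(bip, n),
                                     lat = rep_len(lat, n),
                                     imp = rep_len(imp, n)),
                 region = region_of(faces, sphere),
                 point_face = faces, n_points = n, n_collisions = 0L),
            class = "face_value_map")
}

test_that("gradient value does the stated arithmetic", {
  pts <- data.frame(x = c(0, 5), y = 0, z = 0, lat = c(0, 10))
  gr <- gradient_value(pts, feature_params(gr_radius = 7))
  expect_equal(gr$per_point, c(2, 2))       # 10 ms over 5 mm
  # uniform activation: all gradients zero
  pts$lat <- 4
  expect_equal(gradient_value(pts)$per_point, c(0, 0))
  # out-of-radius pairs are ignored, near-coincident pairs skipped
  pts2 <- data.frame(x = c(0, 20), y = 0, z = 0, lat = c(0, 100))
  expect_equal(gradient_value(pts2)$per_point, c(0, 0))
  pts3 <- data.frame(x = c(0, 0.01), y = 0, z = 0, lat = c(0, 100))
  expect_equal(gradient_value(pts3)$per_point, c(0, 0))
  expect_error(gradient_value(pts3[1, , drop = FALSE]), "at least 2")
})

test_that("per-point gradients match the brute-force pair search", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 200
    pts <- data.frame(x = runif(n, -30, 30), y = runif(n, -30, 30),
                      z = runif(n, -30, 30), lat = runif(n, -50, 50))
    p <- feature_params(gr_radius = 7)
    expect_equal(gradient_value(pts, p)$per_point,
                 bf_gradient(pts, 7, 0.1), tolerance = 1e-12)
  }
})

test_that("regional gradient is the regional maximum of per-point values", {
  sph <- build_sphere()
  ex <- generate_map(substrate_scenario(n_points = 300, seed = 32))
  can <- canonical_orientation(ex)
  fmap <- suppressWarnings(project_points(can, sph))
  reg <- region_of(fmap$point_face, sph)
  gr <- gradient_value(can$points, feature_params(), region = reg)
  for (r in 1:8) {
    sel <- reg == r
    if (any(sel)) expect_equal(gr$regional[r], max(gr$per_point[sel]))
    else expect_true(is.na(gr$regional[r]))
  }
})

test_that("voltage-discrepancy extent follows the 20%-of-range rule", {
  sph <- build_sphere()
  # 10 occupied faces in a row; 2 adjacent ones with strong unipolar depression
  faces <- face_of_direction(cbind(cos(seq(0, 0.9, by = 0.1)),
                                   sin(seq(0, 0.9, by = 0.1)), 0.004), sph)
  fmap <- make_fmap(faces, sph, uni = c(8, 8, 1, 1, 8, 8, 8, 8, 8, 8))
  p <- feature_params(min_cluster = 2)
  v <- vlt_extent(fmap, sph, p)
  expect_equal(v$scalar, 20)               # 2 of 10 faces
  # all discrepancies equal: nothing strictly exceeds the cut
  expect_equal(vlt_extent(make_fmap(faces, sph), sph, p)$scalar, 0)
  # regional values partition the counted faces
  reg <- region_of(faces, sph)
  expect_equal(v$regional[unique(reg[3:4])],
               100 * sum(v$counted) / sum(reg == unique(reg[3:4])))
})

test_that("late-potential extent uses the latest 20% and the non-late denominator", {
  sph <- build_sphere()
  faces <- face_of_direction(cbind(cos(seq(0, 0.9, by = 0.1)),
                                   sin(seq(0, 0.9, by = 0.1)), 0.004), sph)
  fmap <- make_fmap(faces, sph, lat = seq(0, 90, by = 10))
  p <- feature_params(min_cluster = 2)
  l <- late_extent(fmap, sph, p)
  expect_equal(sum(l$critical), 2)         # 80 and 90 ms exceed 0 + 0.8*90
  expect_equal(l$scalar, 100 * 2 / 8)      # percentage of non-late faces
  pt <- feature_params(min_cluster = 2, late_denominator = "total")
  expect_equal(late_extent(fmap, sph, pt)$scalar, 20)
  expect_equal(late_extent(make_fmap(faces, sph, lat = 5), sph, p)$scalar, 0)
})

test_that("scar extent counts clustered sub-0.5 mV faces", {
  sph <- build_sphere()
  faces <- face_of_direction(cbind(cos(seq(0, 0.2, by = 0.1)),
                                   sin(seq(0, 0.2, by = 0.1)), 0.004), sph)
  fmap <- make_fmap(faces, sph, bip = c(0.3, 0.6, 1.6))
  expect_equal(scar_extent(fmap, sph, feature_params(min_cluster = 1))$scalar,
               100 / 3, tolerance = 1e-9)
  expect_equal(scar_extent(make_fmap(faces, sph, bip = c(0.6, 0.9, 1.6)),
                           sph, feature_params(min_cluster = 1))$scalar, 0)
})

test_that("cluster membership matches a brute-force flood fill", {
  sph <- build_sphere()
  set.seed(33)
  for (rep in 1:5) {
    faces <- sort(sample(sph$n_faces, 120))
    for (lr in c(1L, 4L)) {
      cl <- cluster_faces(faces, sph, lr)
      oracle <- bf_components(faces, sph, lr)
      # same partition: cluster ids co-vary exactly
      expect_equal(outer(cl, cl, "=="), outer(oracle, oracle, "=="))
    }
  }
})

test_that("regional impedance is the regional mean of occupied faces", {
  sph <- build_sphere()
  set.seed(34)
  faces <- sort(sample(sph$n_faces, 200))
  imp <- runif(200, 80, 140)
  fmap <- make_fmap(faces, sph, imp = imp)
  got <- regional_impedance(fmap, sph)
  reg <- region_of(faces, sph)
  for (r in 1:8) {
    if (any(reg == r)) expect_equal(got[r], mean(imp[reg == r]))
    else expect_true(is.na(got[r]))
  }
  expect_equal(regional_impedance(make_fmap(faces, sph, imp = 100), sph),
               ifelse(tabulate(reg, 8) > 0, 100, NA_real_))
})

test_that("monotonicity: stricter cutoffs and larger clusters never raise extents", {
  sph <- build_sphere()
  ex <- generate_map(substrate_scenario(
    n_points = 600, seed = 35,
    scar_patches = list(list(region = 2, radius_deg = 25, mean = 0.2))))
  fmap <- suppressWarnings(project_points(canonical_orientation(ex), sph))
  base <- scar_extent(fmap, sph, feature_params())$scalar
  lower <- scar_extent(fmap, sph, feature_params(scar_cutoff = 0.25))$scalar
  expect_lte(lower, base)
  for (mc in c(5L, 10L, 25L)) {
    expect_lte(scar_extent(fmap, sph, feature_params(min_cluster = mc))$scalar,
               base)
  }
  v1 <- vlt_extent(fmap, sph, feature_params(min_cluster = 3))$scalar
  v2 <- vlt_extent(fmap, sph, feature_params(min_cluster = 8))$scalar
  expect_lte(v2, v1)
})

test_that("feature extraction of a flat healthy map is all zeros", {
  sph <- build_sphere()
  sc <- substrate_scenario(
    n_points = 500, seed = 36, jitter_sd = 0,
    noise_sd = c(uni = 0, bip = 0, lat = 0, imp = 0),
    baseline = list(uni = 8, bip = 3, lat0 = -20, lat_slope = 0,
                    uni_x_slope = 0, imp = 100))
  fv <- suppressWarnings(extract_features(generate_map(sc, sph), sph))
  expect_equal(fv$GR, 0)
  expect_equal(fv$VLT, 0)
  expect_equal(fv$LAT, 0)
  expect_equal(fv$ScarAreas, 0)
  expect_equal(unname(unlist(fv[paste0("IMP", 1:8)])), rep(100, 8))
})

test_that("all extent features stay in range and the vector has stable names", {
  sph <- build_sphere()
  ex <- generate_map(substrate_scenario(
    n_points = 500, seed = 37,
    scar_patches = list(list(region = 1, radius_deg = 20, mean = 0.3)),
    late_patches = list(list(region = 4, radius_deg = 20, offset = 40))))
  fv <- suppressWarnings(extract_features(ex, sph))
  expect_identical(names(fv), feature_names())
  ext <- unlist(fv[c("VLT", paste0("VLT", 1:8), "ScarAreas", paste0("Scar", 1:8))])
  ext <- ext[!is.na(ext)]
  expect_true(all(ext >= 0 & ext <= 100))
  grv <- unlist(fv[c("GR", paste0("GR", 1:8))])
  expect_true(all(grv[!is.na(grv)] >= 0))
})
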