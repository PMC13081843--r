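test_that("frame fitting recovers exact concentric caps", {
  ref <- make_cap_referents(r_jz = 900, r_myo = 1500, jitter = 0)
  fr <- fit_half_dome_frame(ref)
  expect_lt(abs(fr$boundary$r_jz - 900), 1)
  expect_lt(abs(fr$boundary$r_myo - 1500), 1)
  expect_lt(max(fr$residuals), 1e-4)
})

test_that("frame fitting tolerates landmark noise", {
  # oracle = known generating radii; 10 um isotropic jitter on landmarks
  for (s in 1:3) {
    ref <- make_cap_referents(jitter = 10, seed = s)
    fr <- fit_half_dome_frame(ref)
    expect_lt(abs(fr$boundary$r_jz - 900), 15)
    expect_lt(abs(fr$boundary$r_myo - 1500), 15)
  }
})

test_that("degenerate geometry (inner outside outer) is rejected", {
  ref <- make_cap_referents(r_jz = 1600, r_myo = 1500)
  expect_error(fit_half_dome_frame(ref), "degenerate")
})

test_that("spheroid boundaries also recover concentric caps", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref, boundary_model = "spheroid")
  expect_lt(abs(fr$boundary$r_jz - 900), 2)
  expect_lt(abs(fr$boundary$r_myo - 1500), 2)
})

test_that("normalized depth hits 0, 1 and linear midpoints by definition", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref)
  pts <- rbind(point_at_depth(0), point_at_depth(1), point_at_depth(0.5))
  np <- normalize_points(pts, fr)
  expect_equal(np$d, c(0, 1, 0.5), tolerance = 1e-6)
  expect_equal(np$region, c("decidua", "myometrium", "decidua"))
  # r = 1200 midway between 900 and 1500 along the same ray -> d = 0.5
  expect_equal(sqrt(sum(point_at_depth(0.5)^2)), 1200)
})

test_that("depth is strictly increasing along any ray", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref)
  d_seq <- seq(0.05, 1.4, by = 0.05)
  pts <- t(vapply(d_seq, point_at_depth, numeric(3), ct = 0.4, phi = 2.2))
  np <- normalize_points(pts, fr)
  expect_true(all(diff(np$d) > 0))
})

test_that("joint rigid motion leaves normalized coordinates unchanged", {
  ref <- make_cap_referents(jitter = 5, seed = 7)
  fr <- fit_half_dome_frame(ref)
  set.seed(11)
  pts <- t(vapply(runif(50, 0.05, 1.3), point_at_depth, numeric(3)))
  pts <- pts + matrix(rnorm(150, 0, 40), ncol = 3)
  np1 <- normalize_points(pts, fr)
  fr2 <- fit_half_dome_frame(apply_rigid_referents(ref))
  np2 <- normalize_points(rigid_transform(pts), fr2)
  expect_lt(max(abs(np1$d - np2$d)), 1e-6)
  expect_lt(max(abs(np1$v - np2$v)), 1e-6)
  du <- abs(np1$u - np2$u)
  expect_lt(max(pmin(du, 1 - du)), 1e-6)   # azimuth wraps
  expect_identical(np1$region, np2$region)
})

test_that("a point at the frame center is excluded with a diagnostic", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref)
  np <- normalize_points(rbind(fr$center, point_at_depth(0.5)), fr)
  expect_equal(nrow(np), 1)
  expect_equal(nrow(attr(np, "excluded")), 1)
  expect_match(attr(np, "excluded")$reason, "center")
})

test_that("volume floor is inclusive and counted separately from mesometrial removal", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref)
  m <- t(vapply(seq(0.1, 0.9, length.out = 10), point_at_depth, numeric(3)))
  sp <- spots_from_matrix(m, volume = c(50, 60, 99, rep(500, 6), 100))
  flt <- filter_spots(sp, min_volume = 100, frame = fr)
  expect_equal(flt$report$removed_volume, 3)
  expect_equal(flt$report$removed_mesometrial, 0)
  expect_equal(flt$report$n_kept, 7)
  expect_true("s0010" %in% flt$spots$spot_id)  # exactly at floor: retained
})

test_that("generated mesometrial spots are all removed (generator oracle)", {
  cfg <- site_config(n_trophoblasts = 400, mesometrial_fraction = 0.2,
                     contaminant_fraction = 0, jitter = 0, p_env = 0.3)
  site <- generate_site(cfg, seed = 3)
  fr <- fit_half_dome_frame(site$referents)
  flt <- filter_spots(site$spots, 100, fr)
  meso_ids <- site$truth$trophoblasts$spot_id[
    site$truth$trophoblasts$category == "mesometrial"]
  expect_equal(flt$report$removed_mesometrial, length(meso_ids))
  expect_false(any(meso_ids %in% flt$spots$spot_id))
})

test_that("missing volumes disable the volume rule with a warning", {
  ref <- make_cap_referents(jitter = 0)
  fr <- fit_half_dome_frame(ref)
  sp <- spots_from_matrix(rbind(point_at_depth(0.3)), volume = NA_real_)
  expect_warning(flt <- filter_spots(sp, 100, fr), "no volumes")
  expect_equal(flt$report$n_kept, 1)
})

test_that("2D relative depth matches brute-force hand computation", {
  # border: segment of points on y = 0; myometrium: points on y = 10
  border <- cbind(x = seq(-5, 5, by = 1), y = 0)
  myo <- cbind(x = c(-2, 0, 3), y = 10)
  objs <- cbind(x = c(0, 1, -3, 2.5, 4), y = c(0, 5, 2, 9.5, 10))
  dep <- relative_depth_2d(objs, border, myo)
  # independent brute force with explicit loops
  mind <- function(p, set) min(sqrt((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2))
  span <- max(apply(myo, 1, mind, set = border))
  expected <- apply(objs, 1, mind, set = border) / span
  expect_equal(as.numeric(dep), pmin(1, expected), tolerance = 1e-9)
  expect_equal(dep[[1]], 0)            # object on the border
  # object at the farthest myometrium point, colinear geometry -> 1
  far <- cbind(x = 0, y = 10)
  expect_equal(as.numeric(relative_depth_2d(far, border, myo)), 1)
  expect_error(relative_depth_2d(objs, border[0, , drop = FALSE], myo),
               "non-empty")
})
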