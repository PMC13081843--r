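# Fixtures: ideal concentric-cap frame at the origin, points placed at known
# depths, straight-line artery "centerlines".

frame_fixture <- function() fit_half_dome_frame(make_cap_referents(jitter = 0))

test_that("localization rules assign the four categories as stated", {
  fr <- frame_fixture()
  p_dec <- point_at_depth(0.5)            # decidual trophoblast
  p_myo <- point_at_depth(1.2)            # myometrial trophoblast
  tro <- normalize_points(rbind(p_dec, p_myo), fr)
  # artery sample 5 um from the decidual point, 100+ um from the myometrial one
  art <- rbind(p_dec + c(5, 0, 0))
  cl <- classify_trophoblasts(tro, art, r_adj = 20)
  expect_equal(cl$per_point$category,
               c("spiral_artery_adjacent", "myometrial_stromal"))
  expect_equal(sum(cl$breakdown$n), cl$n_in_domain)
  expect_equal(sum(cl$breakdown$fraction), 1, tolerance = 1e-9)
})

test_that("classification partitions every in-domain point exactly once", {
  site <- generate_site(site_config(n_trophoblasts = 500,
                                    myometrial_fraction = 0.2), seed = 5)
  fr <- fit_half_dome_frame(site$referents)
  np <- normalize_points(site$spots, fr)
  tro <- np[np$channel == "trophoblast", ]; class(tro) <- class(np)
  art <- resample_centerlines(site$trees, 10)
  cl <- classify_trophoblasts(tro, art)
  expect_equal(sum(cl$breakdown$n), sum(tro$region != "outside"))
  expect_equal(nrow(cl$per_point), cl$n_in_domain)
})

test_that("enlarging the adjacency radius never loses adjacent points", {
  site <- generate_site(site_config(n_trophoblasts = 400), seed = 6)
  fr <- fit_half_dome_frame(site$referents)
  np <- normalize_points(site$spots, fr)
  tro <- np[np$channel == "trophoblast", ]; class(tro) <- class(np)
  art <- resample_centerlines(site$trees, 10)
  n_adj <- vapply(c(10, 20, 40), function(r) {
    bd <- classify_trophoblasts(tro, art, r_adj = r)$breakdown
    sum(bd$n[bd$category %in% c("spiral_artery_adjacent",
                                "myometrial_artery_adjacent")])
  }, numeric(1))
  expect_true(all(diff(n_adj) >= 0))
})

test_that("no artery reference yields non-adjacent classes with a warning", {
  fr <- frame_fixture()
  tro <- normalize_points(rbind(point_at_depth(0.5)), fr)
  expect_warning(cl <- classify_trophoblasts(tro, NULL), "no artery")
  expect_equal(cl$per_point$category, "interstitial")
})

test_that("invasion summaries report max depth and myometrial fraction", {
  fr <- frame_fixture()
  np1 <- normalize_points(t(vapply(c(0.1, 0.4, 0.9), point_at_depth,
                                   numeric(3))), fr)
  s1 <- invasion_summary(np1)
  expect_equal(s1$max_depth, 0.9, tolerance = 1e-6)
  expect_equal(s1$myometrial_fraction, 0)

  np2 <- normalize_points(t(vapply(c(0.5, 1.1), point_at_depth, numeric(3))), fr)
  s2 <- invasion_summary(np2)
  expect_equal(s2$max_depth, 1.1, tolerance = 1e-6)
  expect_equal(s2$myometrial_fraction, 0.5)

  empty <- np1[0, ]; class(empty) <- class(np1)
  expect_true(invasion_summary(empty)$empty)
})

test_that("empirical max depth matches a direct-sampling oracle", {
  # Beta-distributed depths capped at 0.95; oracle = direct resampling of the
  # generating distribution at matched n.
  cfg <- site_config(n_trophoblasts = 2000, p_env = 0, jitter = 0,
                     contaminant_fraction = 0)
  site <- generate_site(cfg, seed = 8)
  fr <- fit_half_dome_frame(site$referents)
  np <- normalize_points(site$spots, fr)
  tro <- np[np$channel == "trophoblast", ]; class(tro) <- class(np)
  obs <- invasion_summary(tro)$max_depth
  set.seed(99)
  oracle <- replicate(200, max(0.95 * rbeta(2000, 2, 2)))
  expect_gt(obs, quantile(oracle, 0.001))
  expect_lt(obs, 0.95 * 1.001)
})

test_that("decidual branch entries count once per entering path", {
  fr <- frame_fixture()
  # one path from d = 1.3 straight down to d = 0.2 -> one entry
  t1 <- line_tree(point_at_depth(1.3), point_at_depth(0.2))
  expect_equal(as.integer(count_decidual_branches(list(t1), fr)), 1)

  # bifurcation in the myometrium, both daughters descending -> two entries
  stem <- point_at_depth(1.3, ct = 0.7)
  fork <- point_at_depth(1.1, ct = 0.7)
  nodes <- rbind(
    data.frame(id = 1:5, x = seq(stem[1], fork[1], length.out = 5),
               y = seq(stem[2], fork[2], length.out = 5),
               z = seq(stem[3], fork[3], length.out = 5),
               radius = 10, parent = c(-1L, 1:4)),
    {
      a <- point_at_depth(0.3, ct = 0.75, phi = 1.1)
      b <- point_at_depth(0.3, ct = 0.65, phi = 0.9)
      rbind(data.frame(id = 6:10, x = seq(fork[1], a[1], length.out = 5),
                       y = seq(fork[2], a[2], length.out = 5),
                       z = seq(fork[3], a[3], length.out = 5),
                       radius = 8, parent = c(5L, 6:9)),
            data.frame(id = 11:15, x = seq(fork[1], b[1], length.out = 5),
                       y = seq(fork[2], b[2], length.out = 5),
                       z = seq(fork[3], b[3], length.out = 5),
                       radius = 8, parent = c(5L, 11:14)))
    })
  t2 <- as_centerline_tree(nodes)
  expect_equal(as.integer(count_decidual_branches(list(t2), fr)), 2)

  # tree entirely inside the decidua: contributes zero, with a warning
  t3 <- line_tree(point_at_depth(0.8), point_at_depth(0.3))
  expect_warning(n3 <- count_decidual_branches(list(t3), fr), "decidua")
  expect_equal(as.integer(n3), 0)
})

test_that("envelopment fractions respond to coverage and radius", {
  fr <- frame_fixture()
  tr <- line_tree(point_at_depth(1.2), point_at_depth(0.1), k = 40)
  samp <- resample_centerlines(list(tr), 10)
  d <- normalize_points(samp[, c("x", "y", "z")], fr)$d
  dec <- as.matrix(samp[d >= 0 & d < 1, c("x", "y", "z")])
  # trophoblasts within r_env along 100% of the decidual samples
  tro_full <- dec + 5
  em <- envelopment(list(tr), tro_full, fr, r_env = 20)
  expect_equal(em$envelopment_fraction, 1)
  expect_true(em$enveloped)
  # none within r_env
  em0 <- envelopment(list(tr), dec + 500, fr, r_env = 20)
  expect_equal(em0$envelopment_fraction, 0)
  expect_false(em0$enveloped)
  # radius monotonicity
  half <- dec[seq_len(ceiling(nrow(dec) / 2)), , drop = FALSE] + 15
  f1 <- envelopment(list(tr), half, fr, r_env = 10)$envelopment_fraction
  f2 <- envelopment(list(tr), half, fr, r_env = 30)$envelopment_fraction
  expect_gte(f2, f1)
  # artery with no decidual segment is excluded from the denominator
  t_myo <- line_tree(point_at_depth(1.4), point_at_depth(1.05))
  em2 <- envelopment(list(t_myo), tro_full, fr)
  expect_true(is.na(em2$enveloped))
  expect_equal(attr(em2, "n_excluded"), 1)
})

test_that("placental connection requires a terminal near d = 0", {
  fr <- frame_fixture()
  t_conn <- line_tree(point_at_depth(1.2), point_at_depth(0))
  t_short <- line_tree(point_at_depth(1.2), point_at_depth(0.4))
  n <- count_placenta_connected(list(t_conn, t_short), fr, tolerance = 30)
  expect_equal(as.integer(n), 1)
  expect_equal(attr(n, "connected"), c(TRUE, FALSE))
})

test_that("off-midline invasion inflates the 2D/3D discrepancy ratio", {
  fr <- frame_fixture()
  # construction oracle: shallow isotropic background plus a deep cluster
  # confined to azimuth u ~ 0.25 (off every midline section)
  set.seed(21)
  ct_bg <- runif(300, 0.1, 0.99)
  shallow <- (900 + 0.3 * 600 * runif(300)^0.5) *
    cbind(sqrt(1 - ct_bg^2) * cos(2 * pi * runif(300)),
          sqrt(1 - ct_bg^2) * sin(2 * pi * runif(300)), ct_bg)
  deep <- t(vapply(runif(60, 0.85, 0.95), point_at_depth, numeric(3),
                   ct = 0.5, phi = pi / 2))   # u = 0.25
  np <- normalize_points(rbind(shallow, deep), fr)
  vs <- virtual_sections(np, fr)
  expect_gt(vs$ratio, 2)
  ok <- !is.na(vs$sections$max_depth_2d)
  expect_true(all(vs$sections$max_depth_2d[ok] <= vs$max_depth_3d))

  # comparison refuses to report a mean from too few sections
  lone <- normalize_points(rbind(point_at_depth(0.5)), fr)
  vs2 <- virtual_sections(lone, fr)
  expect_true(is.na(vs2$ratio))
  expect_match(vs2$reason, "non-empty")
})
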