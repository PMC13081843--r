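# synthetic_data module: implantation-site generator.
#
# Geometry: a half-dome decidua between two concentric spherical caps
# (junctional-zone outer edge at r_jz, myometrial surface at r_myo) sitting
# on the mesometrial plane, wrapped by a myometrial shell out to r_outer.
# Spiral arteries are helical centerlines seeded on the myometrial side and
# descending toward the ectoplacental cone at the dome apex; a configurable
# fraction reach the junctional-zone surface (placenta-connected).
# Trophoblasts are a mixture: a myometrial-invader fraction (of which a
# stated share targets myometrial artery segments), the rest decidual with
# Beta-distributed depth, von Mises azimuth, and a perivascular fraction
# snapped to within the adjacency radius of designated enveloped arteries.
# Every generated point carries a ground-truth label so classifier and
# metric recovery can be tested exactly.

#' Configuration for a synthetic implantation site
#'
#' Defaults describe a mid-gestation (E12.5-like) control site: 16 spiral
#' arteries of which 75% connect to the placenta, 3000 trophoblasts with
#' depth support reaching 95% of the decidual thickness, 75% of decidual
#' trophoblasts perivascular, no azimuthal bias, and no myometrial invasion.
#' See [site_preset()] for the named control/knockout presets.
#'
#' @param r_jz,r_myo,r_outer junctional-zone, myometrial-surface and outer
#'   myometrial radii in µm (strictly increasing).
#' @param n_trees number of spiral-artery centerline trees.
#' @param coil_radius,coil_pitch helix geometry of the spiral, µm.
#' @param connected_fraction fraction of arteries extended to the
#'   junctional-zone surface.
#' @param enveloped_fraction fraction of arteries designated as
#'   trophoblast-enveloped (drawn from the connected arteries first);
#'   perivascular trophoblasts are placed along these.
#' @param centerline_step node spacing along centerlines, µm.
#' @param n_trophoblasts trophoblast spot count.
#' @param depth_shape1,depth_shape2 Beta parameters of the decidual depth
#'   distribution on `(0, d_cap)`.
#' @param d_cap support cap of decidual invasion depth (0.95: invasion
#'   reaching nearly all the way through the decidua).
#' @param p_env perivascular (artery-snapped) fraction of decidual
#'   trophoblasts.
#' @param kappa von Mises azimuthal concentration (0 = isotropic).
#' @param mu_azimuth mean azimuth of the von Mises draw, in turns `[0, 1)`;
#'   0.25 is perpendicular to the front-back midline plane.
#' @param myometrial_fraction fraction of trophoblasts invading the
#'   myometrial shell (abnormal; 0 in controls).
#' @param artery_targeted_fraction of the myometrial invaders, the share
#'   snapped to myometrial artery segments.
#' @param r_snap snapping radius for perivascular placement, µm; shared with
#'   the classifier's default adjacency radius so ground truth and
#'   classification use one definition.
#' @param volume_meanlog,volume_sdlog log-normal spot-volume parameters, µm³.
#' @param contaminant_fraction fraction of trophoblast spots given volumes
#'   below a 100 µm³ detection floor (exercises volume filtering).
#' @param mesometrial_fraction extra trophoblast-channel spots (as a fraction
#'   of `n_trophoblasts`) placed in the mesometrial region, where signal is
#'   uninterpretable and must be excluded.
#' @param n_jz_referents,n_myo_referents,n_lum_referents referent counts.
#' @param jitter isotropic landmark jitter sd, µm.
#' @param site_id,group identifiers stamped onto the outputs.
#' @return A validated `site_config` list.
#' @export
site_config <- function(r_jz = 900, r_myo = 1500, r_outer = 1800,
                        n_trees = 16, coil_radius = 60, coil_pitch = 150,
                        connected_fraction = 0.75, enveloped_fraction = 0.6,
                        centerline_step = 20,
                        n_trophoblasts = 3000, depth_shape1 = 2,
                        depth_shape2 = 2, d_cap = 0.95, p_env = 0.75,
                        kappa = 0, mu_azimuth = 0.25,
                        myometrial_fraction = 0,
                        artery_targeted_fraction = 0.75, r_snap = 20,
                        volume_meanlog = log(500), volume_sdlog = 0.4,
                        contaminant_fraction = 0.05,
                        mesometrial_fraction = 0,
                        n_jz_referents = 25, n_myo_referents = 25,
                        n_lum_referents = 8, jitter = 5,
                        site_id = "site_1", group = "control") {
  cfg <- as.list(environment())
  fr <- c("connected_fraction", "enveloped_fraction", "p_env",
          "myometrial_fraction", "artery_targeted_fraction",
          "contaminant_fraction", "mesometrial_fraction")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must be in [0, 1]", call. = FALSE)
  if (!(r_jz < r_myo && r_myo < r_outer))
    stop("radii must satisfy r_jz < r_myo < r_outer", call. = FALSE)
  if (n_trees < 0) stop("n_trees must be >= 0", call. = FALSE)
  if (d_cap <= 0 || d_cap > 1) stop("d_cap must be in (0, 1]", call. = FALSE)
  if (p_env > 0 && n_trees == 0)
    stop("infeasible config: p_env > 0 requires n_trees > 0", call. = FALSE)
  if (myometrial_fraction * artery_targeted_fraction > 0 && n_trees == 0)
    stop("infeasible config: artery-targeted invaders require n_trees > 0",
         call. = FALSE)
  structure(cfg, class = "site_config")
}

#' Named generator presets
#'
#' Gestational-stage and perturbation presets whose headline parameters
#' mirror the implantation-site phenotypes the pipeline is designed to
#' measure: artery counts rising from 8 to 16 across gestation, invasion
#' depth support growing from 10% to 95% of the decidua, a control
#' perivascular fraction of 0.75 with 12 of 16 arteries placenta-connected,
#' and a knockout-like state with perivascular fraction 0.10, 20% myometrial
#' invasion of which 75% artery-targeted, azimuthally biased invasion, and
#' only 3 connected arteries.
#'
#' @param name one of `"wildtype_E6_5"`, `"wildtype_E8_5"`,
#'   `"wildtype_E12_5"`, `"cxcl12_ko_E12_5"`.
#' @param ... overrides passed to [site_config()].
#' @return A `site_config`.
#' @export
site_preset <- function(name = c("wildtype_E12_5", "cxcl12_ko_E12_5",
                                 "wildtype_E6_5", "wildtype_E8_5"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    wildtype_E6_5 = list(n_trees = 8, connected_fraction = 0.25,
                         enveloped_fraction = 0, p_env = 0,
                         n_trophoblasts = 150, d_cap = 0.10,
                         group = "wildtype_E6_5"),
    wildtype_E8_5 = list(n_trees = 10, connected_fraction = 0.4,
                         enveloped_fraction = 0, p_env = 0,
                         n_trophoblasts = 600, d_cap = 0.25,
                         group = "wildtype_E8_5"),
    wildtype_E12_5 = list(n_trees = 16, connected_fraction = 0.75,
                          enveloped_fraction = 0.6, p_env = 0.75,
                          n_trophoblasts = 3000, d_cap = 0.95,
                          group = "control"),
    cxcl12_ko_E12_5 = list(n_trees = 16, connected_fraction = 3 / 16,
                           enveloped_fraction = 2 / 16, p_env = 0.10,
                           myometrial_fraction = 0.20,
                           artery_targeted_fraction = 0.75,
                           kappa = 4, n_trophoblasts = 3000, d_cap = 0.95,
                           group = "knockout"))
  do.call(site_config, utils::modifyList(base, list(...)))
}

.dir3 <- function(ct, phi) {
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(st * cos(phi), st * sin(phi), ct)
}

# One helical centerline from p0 to p1 with tapered coil amplitude so both
# endpoints lie exactly on the chord (root cleanly myometrial, tip exactly
# at its target radius).
.helix_path <- function(p0, p1, coil_radius, pitch, step, phase) {
  chord <- p1 - p0
  L <- sqrt(sum(chord^2))
  Tv <- chord / L
  ref <- if (abs(Tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  N1 <- .unit(.cross(Tv, ref))
  N2 <- .cross(Tv, N1)
  k <- max(3L, ceiling(L / step) + 1L)
  s <- seq(0, 1, length.out = k)
  amp <- coil_radius * pmax(0, pmin(1, s / 0.15, (1 - s) / 0.12))
  ang <- 2 * pi * s * L / pitch + phase
  sweep(outer(s, chord), 2, p0, "+") +
    amp * cos(ang) %o% N1 + amp * sin(ang) %o% N2
}

#' Generate one synthetic implantation site
#'
#' Produces the full input bundle for the analysis pipeline -- a two-channel
#' `spot_table` (artery spots sampled along the centerlines, trophoblast
#' spots from the configured mixture), the centerline trees, the anatomical
#' referents, and a ground-truth record of every generating label --
#' reproducibly from `seed`.
#'
#' @param config a [site_config()].
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#' @return List with `spots`, `trees`, `referents`, `truth`, `config`.
#' @export
generate_site <- function(config = site_config(), seed = 1) {
  stopifnot(inherits(config, "site_config"))
  .with_seed(seed, .generate_site_impl(config, seed))
}

.generate_site_impl <- function(cfg, seed) {
  shell <- cfg$r_myo - cfg$r_jz

  ## --- arteries -----------------------------------------------------------
  n_tr <- cfg$n_trees
  trees <- list()
  artery_truth <- data.frame(tree_id = character(0), connected = logical(0),
                             enveloped = logical(0))
  if (n_tr > 0) {
    n_conn <- round(cfg$connected_fraction * n_tr)
    n_env <- round(cfg$enveloped_fraction * n_tr)
    conn <- rep(FALSE, n_tr); conn[sample.int(n_tr, n_conn)] <- TRUE
    env <- rep(FALSE, n_tr)
    pool <- if (n_env <= n_conn) which(conn) else seq_len(n_tr)
    if (n_env > 0) env[pool[sample.int(length(pool), n_env)]] <- TRUE
    ct_s <- runif(n_tr, 0.25, 0.9)
    phi_s <- 2 * pi * (seq_len(n_tr) - 1) / n_tr + rnorm(n_tr, 0, 0.1)
    r_start <- (cfg$r_myo + cfg$r_outer) / 2
    for (i in seq_len(n_tr)) {
      p0 <- r_start * .dir3(ct_s[i], phi_s[i])[1, ]
      ct_e <- runif(1, 0.91, 0.995)
      r_end <- if (conn[i]) cfg$r_jz else
        cfg$r_jz + runif(1, 0.2, 0.5) * shell
      p1 <- r_end * .dir3(ct_e, phi_s[i])[1, ]
      path <- .helix_path(p0, p1, cfg$coil_radius, cfg$coil_pitch,
                          cfg$centerline_step, runif(1, 0, 2 * pi))
      k <- nrow(path)
      nodes <- data.frame(id = seq_len(k), x = path[, 1], y = path[, 2],
                          z = path[, 3],
                          radius = seq(15, 8, length.out = k),
                          parent = c(-1L, seq_len(k - 1L)))
      trees[[i]] <- as_centerline_tree(nodes, tree_id = sprintf("tree_%02d", i),
                                       site_id = cfg$site_id)
    }
    artery_truth <- data.frame(tree_id = sprintf("tree_%02d", seq_len(n_tr)),
                               connected = conn, enveloped = env)
  }

  # centerline samples at the classifier's resolution; depths from the exact
  # generating geometry (center at the origin)
  if (n_tr > 0) {
    samp <- resample_centerlines(trees, step = 10)
    samp_d <- (sqrt(samp$x^2 + samp$y^2 + samp$z^2) - cfg$r_jz) / shell
    dec_ok <- samp_d >= 0.05 & samp_d <= 0.95
    env_ids <- artery_truth$tree_id[artery_truth$enveloped]
    dec_env <- dec_ok & samp$tree_id %in% env_ids
    if (!any(dec_env)) dec_env <- dec_ok
    myo_ok <- samp_d >= 1.05 & samp_d <= 1.2
  }

  ## --- trophoblasts -------------------------------------------------------
  n_t <- cfg$n_trophoblasts
  pos <- matrix(0, 0, 3); category <- character(0)
  beta_depth <- numeric(0)
  if (n_t > 0) {
    is_myo <- runif(n_t) < cfg$myometrial_fraction
    phi <- .rvonmises(n_t, 2 * pi * cfg$mu_azimuth, cfg$kappa)
    pos <- matrix(NA_real_, n_t, 3)
    category <- character(n_t)
    beta_depth <- rep(NA_real_, n_t)

    # decidual component: Beta depth on (0, d_cap), isotropic polar angle
    dec <- which(!is_myo)
    bd <- cfg$d_cap * stats::rbeta(length(dec), cfg$depth_shape1,
                                   cfg$depth_shape2)
    beta_depth[dec] <- bd
    ct <- runif(length(dec), 0.05, 0.995)
    pos[dec, ] <- (cfg$r_jz + bd * shell) * .dir3(ct, phi[dec])
    category[dec] <- "interstitial"
    snap <- dec[runif(length(dec)) < cfg$p_env]
    if (length(snap) > 0) {
      if (n_tr == 0 || !any(dec_env))
        stop("infeasible config: perivascular placement without decidual ",
             "artery samples", call. = FALSE)
      cand <- which(dec_env)
      tgt <- cand[sample.int(length(cand), length(snap), replace = TRUE)]
      pos[snap, ] <- as.matrix(samp[tgt, c("x", "y", "z")]) +
        .runif_ball(length(snap), cfg$r_snap)
      category[snap] <- "spiral_artery_adjacent"
      beta_depth[snap] <- NA_real_
    }

    # myometrial invaders
    myo <- which(is_myo)
    if (length(myo) > 0) {
      dmy <- runif(length(myo), 1.02, 1.18)
      ct <- runif(length(myo), 0.2, 0.95)
      pos[myo, ] <- (cfg$r_jz + dmy * shell) * .dir3(ct, phi[myo])
      category[myo] <- "myometrial_stromal"
      tgt_my <- myo[runif(length(myo)) < cfg$artery_targeted_fraction]
      if (length(tgt_my) > 0) {
        if (n_tr == 0 || !any(myo_ok))
          stop("infeasible config: artery-targeted myometrial invaders ",
               "without myometrial artery samples", call. = FALSE)
        cand_my <- which(myo_ok)
        tgt <- cand_my[sample.int(length(cand_my), length(tgt_my),
                                  replace = TRUE)]
        pos[tgt_my, ] <- as.matrix(samp[tgt, c("x", "y", "z")]) +
          .runif_ball(length(tgt_my), cfg$r_snap)
        category[tgt_my] <- "myometrial_artery_adjacent"
      }
    }
  }

  # mesometrial-region contaminant signal (excluded by spot filtering)
  n_meso <- round(cfg$mesometrial_fraction * n_t)
  if (n_meso > 0) {
    ct <- runif(n_meso, -0.6, -0.05)
    phi_m <- runif(n_meso, 0, 2 * pi)
    r_m <- runif(n_meso, cfg$r_myo, cfg$r_outer)
    pos <- rbind(pos, r_m * .dir3(ct, phi_m))
    category <- c(category, rep("mesometrial", n_meso))
    beta_depth <- c(beta_depth, rep(NA_real_, n_meso))
  }
  n_all <- nrow(pos)
  vol <- stats::rlnorm(n_all, cfg$volume_meanlog, cfg$volume_sdlog)
  low <- runif(n_all) < cfg$contaminant_fraction
  vol[low] <- runif(sum(low), 5, 95)

  troph <- if (n_all > 0)
    data.frame(spot_id = sprintf("t%05d", seq_len(n_all)),
               x = pos[, 1], y = pos[, 2], z = pos[, 3], volume = vol,
               channel = "trophoblast", stringsAsFactors = FALSE)
  else data.frame(spot_id = character(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), volume = numeric(0),
                  channel = character(0), stringsAsFactors = FALSE)

  ## --- artery spots -------------------------------------------------------
  if (n_tr > 0) {
    asamp <- resample_centerlines(trees, step = 25)
    am <- as.matrix(asamp[, c("x", "y", "z")]) +
      matrix(rnorm(3 * nrow(asamp), 0, 3), ncol = 3)
    art <- data.frame(spot_id = sprintf("a%05d", seq_len(nrow(am))),
                      x = am[, 1], y = am[, 2], z = am[, 3],
                      volume = stats::rlnorm(nrow(am), log(800), 0.3),
                      channel = "artery", stringsAsFactors = FALSE)
  } else {
    art <- troph[0, ]
  }
  spots <- .new_spot_table(rbind(art, troph), cfg$site_id, cfg$group)

  ## --- referents ----------------------------------------------------------
  jit <- function(m) m + matrix(rnorm(length(m), 0, cfg$jitter), ncol = 3)
  ring_phi <- 2 * pi * (seq_len(cfg$n_lum_referents) - 1) / cfg$n_lum_referents
  lum <- jit(1.1 * cfg$r_outer * cbind(cos(ring_phi), sin(ring_phi), 0))
  # Systematic cap coverage in antipodal azimuthal pairs: the noiseless cap
  # centroid then lies exactly on the dome axis, as a careful annotator's
  # evenly spread landmarks would.
  cap_pts <- function(n, r) {
    n_pairs <- n %/% 2L
    ct <- rep(seq(0.15, 0.92, length.out = max(1L, n_pairs)), each = 2L)
    phi0 <- 2.399963 * seq_len(max(1L, n_pairs))   # golden-angle spread
    phi <- as.vector(rbind(phi0, phi0 + pi))
    pts <- r * .dir3(ct, phi)
    if (n %% 2L == 1L) pts <- rbind(pts, r * .dir3(0.999, 0))
    jit(pts)
  }
  jz <- cap_pts(cfg$n_jz_referents, cfg$r_jz)
  myo_r <- cap_pts(cfg$n_myo_referents, cfg$r_myo)
  r_mid <- (cfg$r_jz + cfg$r_myo) / 2
  front <- jit(r_mid * .dir3(cos(80 * pi / 180), 0))
  back <- jit(r_mid * .dir3(cos(80 * pi / 180), pi))
  ref_df <- data.frame(
    label = c(rep("luminal_epithelium", nrow(lum)),
              rep("junctional_zone_outer", nrow(jz)),
              rep("myometrium_outer", nrow(myo_r)), "front", "back"),
    rbind(lum, jz, myo_r, front, back))
  names(ref_df)[2:4] <- c("x", "y", "z")
  referents <- as_referent_set(ref_df, site_id = cfg$site_id)

  ## --- ground truth -------------------------------------------------------
  true_depth <- if (n_all > 0)
    (sqrt(rowSums(pos^2)) - cfg$r_jz) / shell else numeric(0)
  truth <- list(
    trophoblasts = data.frame(spot_id = troph$spot_id, category = category,
                              true_depth = true_depth,
                              beta_depth = beta_depth, low_volume = low,
                              stringsAsFactors = FALSE),
    arteries = artery_truth,
    center = c(0, 0, 0), axis = c(0, 0, 1),
    config = unclass(cfg), seed = seed)

  list(spots = spots, trees = trees, referents = referents, truth = truth,
       config = cfg)
}

#' Generate a two-group cohort of synthetic sites
#'
#' Independent sites with per-site seeds derived deterministically from the
#' master seed; identical arguments reproduce the cohort bit-identically.
#'
#' @param control_config,perturbed_config [site_config()]s for the two arms.
#' @param n_sites_per_group sites per arm (>= 1).
#' @param seed master seed.
#' @return List of site bundles (as from [generate_site()]), each with
#'   `site_id` and `group` set; group labels are taken from the configs.
#' @export
generate_cohort <- function(control_config, perturbed_config,
                            n_sites_per_group = 3, seed = 1) {
  stopifnot(n_sites_per_group >= 1)
  n <- n_sites_per_group
  seeds <- .with_seed(seed, sample.int(2^30, 2 * n))
  cfgs <- c(rep(list(control_config), n), rep(list(perturbed_config), n))
  lapply(seq_len(2 * n), function(i) {
    cfg <- cfgs[[i]]
    grp <- cfg$group
    idx <- if (i <= n) i else i - n
    cfg$site_id <- sprintf("%s_%02d", grp, idx)
    generate_site(cfg, seed = seeds[i])
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Housekeeping Ct values are drawn from Normal(20, `noise_sd`); target Ct
#' adds a baseline delta-Ct, the per-group effect (in cycles; the reference
#' group's effect is 0), and independent noise. A +1-cycle effect therefore
#' halves relative expression under [delta_delta_ct()].
#'
#' @param n_per_group samples per group.
#' @param effects named numeric vector of group effects in Ct cycles; the
#'   first element is the reference group and must be 0.
#' @param baseline_dct baseline target-minus-housekeeping Ct.
#' @param noise_sd measurement noise sd, cycles.
#' @param seed integer seed.
#' @return A `ct_table` data frame with a `"reference"` attribute.
#' @export
generate_ct_table <- function(n_per_group = 3, effects = c(control = 0,
                                                           knockout = 1),
                              baseline_dct = 5, noise_sd = 0.2, seed = 1) {
  stopifnot(!is.null(names(effects)), all(is.finite(effects)), noise_sd >= 0,
            effects[1] == 0)
  .with_seed(seed, {
    groups <- rep(names(effects), each = n_per_group)
    n <- length(groups)
    hk <- stats::rnorm(n, 20, noise_sd)
    tg <- hk + baseline_dct + rep(unname(effects), each = n_per_group) +
      stats::rnorm(n, 0, noise_sd)
    out <- data.frame(sample_id = sprintf("%s_%02d", groups,
                                          sequence(rep(n_per_group,
                                                       length(effects)))),
                      group = groups, ct_target = tg, ct_housekeeping = hk,
                      stringsAsFactors = FALSE)
    attr(out, "reference") <- names(effects)[1]
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
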