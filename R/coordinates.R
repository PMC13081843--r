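# coordinates module: the half-dome anatomical frame.
#
# The implantation site is modeled as a half-dome sitting on the mesometrial
# plane: an inner boundary surface at the outer junctional-zone edge (the
# placental border, normalized depth d = 0) and an outer boundary at the
# myometrium (d = 1), with the myometrial shell continuing the same linear
# ray parameterization past 1. Both boundaries are spherical caps sharing a
# center on the dome axis by default; an axially symmetric ellipsoidal
# (spheroid) cap model is selectable.

#' Fit the half-dome anatomical frame from referents
#'
#' The dome axis points from the centroid of the luminal-epithelium referents
#' (mesometrial side) through the centroid of the junctional-zone referents.
#' The shared boundary center is found on that axis by least squares over the
#' junctional-zone and myometrium referents jointly; each boundary is then a
#' spherical cap (`"sphere"`, radius = mean distance to the center) or a
#' spheroid cap (`"spheroid"`, independent polar and equatorial radii fitted
#' by Nelder-Mead). The front/back referents fix azimuth zero; the
#' mesometrial cutoff plane passes through the luminal-epithelium centroid,
#' normal to the axis.
#'
#' @param referents a `referent_set` (see [read_referents()]).
#' @param boundary_model `"sphere"` (default) or `"spheroid"`.
#' @param d_max_allowed largest normalized depth still reported as
#'   myometrium; points beyond are flagged `outside`. Default 1.5, which for
#'   equal-thickness decidua and shell keeps the full myometrium in view.
#' @return A `half_dome_frame` with the fitted center, axis, azimuthal origin,
#'   boundary parameters, per-surface maximum residuals (µm), and the
#'   mesometrial cutoff plane.
#' @export
fit_half_dome_frame <- function(referents, boundary_model = c("sphere", "spheroid"),
                                d_max_allowed = 1.5) {
  boundary_model <- match.arg(boundary_model)
  stopifnot(inherits(referents, "referent_set"), d_max_allowed > 1)
  pts <- function(lab) .as_points3(referents[referents$label == lab,
                                             c("x", "y", "z")])
  p_lum <- pts("luminal_epithelium")
  p_jz <- pts("junctional_zone_outer")
  p_myo <- pts("myometrium_outer")
  m_lum <- colMeans(p_lum)
  m_jz <- colMeans(p_jz)
  axis <- .unit(m_jz - m_lum)

  dist_to <- function(p, c0) sqrt(rowSums(sweep(p, 2, c0)^2))
  L <- 1.5 * max(dist_to(p_myo, m_lum))

  if (boundary_model == "sphere") {
    sse <- function(t) {
      c0 <- m_lum + t * axis
      dj <- dist_to(p_jz, c0); dm <- dist_to(p_myo, c0)
      sum((dj - mean(dj))^2) + sum((dm - mean(dm))^2)
    }
    t_opt <- stats::optimize(sse, c(-L, L), tol = 1e-8)$minimum
    center <- m_lum + t_opt * axis
    r_jz <- mean(dist_to(p_jz, center))
    r_myo <- mean(dist_to(p_myo, center))
    bnd <- list(r_jz = r_jz, r_myo = r_myo)
    radius_fun <- function(cos_theta, which) {
      if (which == "jz") rep(r_jz, length(cos_theta)) else rep(r_myo, length(cos_theta))
    }
  } else {
    # spheroid: r(theta) = 1 / sqrt((cos/rp)^2 + (sin/re)^2), symmetric in axis
    fit_surface <- function(p, c0) {
      rel <- sweep(p, 2, c0)
      r <- sqrt(rowSums(rel^2))
      ct <- pmin(1, pmax(-1, rel %*% axis / r))
      st2 <- 1 - ct^2
      obj <- function(par) {
        rp <- exp(par[1]); re <- exp(par[2])
        sum((r - 1 / sqrt(ct^2 / rp^2 + st2 / re^2))^2)
      }
      fit <- stats::optim(c(log(mean(r)), log(mean(r))), obj,
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000))
      list(rp = exp(fit$par[1]), re = exp(fit$par[2]), sse = fit$value)
    }
    sse <- function(t) {
      c0 <- m_lum + t * axis
      fit_surface(p_jz, c0)$sse + fit_surface(p_myo, c0)$sse
    }
    t_opt <- stats::optimize(sse, c(-L, L), tol = 1e-6)$minimum
    center <- m_lum + t_opt * axis
    fj <- fit_surface(p_jz, center); fm <- fit_surface(p_myo, center)
    bnd <- list(jz = fj[c("rp", "re")], myo = fm[c("rp", "re")],
                r_jz = mean(unlist(fj[c("rp", "re")])),
                r_myo = mean(unlist(fm[c("rp", "re")])))
    radius_fun <- function(cos_theta, which) {
      pr <- if (which == "jz") bnd$jz else bnd$myo
      st2 <- 1 - cos_theta^2
      1 / sqrt(cos_theta^2 / pr$rp^2 + st2 / pr$re^2)
    }
  }

  # azimuthal origin from the front referent, orthogonalized against the axis
  f <- colMeans(pts("front")) - center
  f_perp <- f - sum(f * axis) * axis
  if (sqrt(sum(f_perp^2)) < 1e-9)
    stop("front referent lies on the dome axis; azimuth undefined", call. = FALSE)
  u0 <- .unit(f_perp)
  w <- .cross(axis, u0)

  # residuals and sanity: outer boundary must enclose inner everywhere
  resid <- function(p, which) {
    rel <- sweep(p, 2, center)
    r <- sqrt(rowSums(rel^2))
    ct <- pmin(1, pmax(-1, rel %*% axis / r))
    max(abs(r - radius_fun(ct, which)))
  }
  res_jz <- resid(p_jz, "jz"); res_myo <- resid(p_myo, "myo")
  ct_grid <- seq(0, 1, length.out = 64)
  gap <- radius_fun(ct_grid, "myo") - radius_fun(ct_grid, "jz")
  if (any(gap <= 0))
    stop(sprintf(paste0("degenerate frame: outer boundary does not enclose ",
                        "inner boundary (min gap %.1f um; residuals jz %.1f, ",
                        "myo %.1f um)"), min(gap), res_jz, res_myo),
         call. = FALSE)

  structure(list(center = center, axis = axis, u0 = u0, w = w,
                 boundary_model = boundary_model, boundary = bnd,
                 radius_fun = radius_fun,
                 meso_point = m_lum, d_max_allowed = d_max_allowed,
                 residuals = c(jz = res_jz, myo = res_myo)),
            class = "half_dome_frame")
}

#' @export
print.half_dome_frame <- function(x, ...) {
  cat("Half-dome frame (", x$boundary_model, " boundaries)\n", sep = "")
  cat(sprintf("  r_jz  = %.1f um   r_myo = %.1f um\n",
              x$boundary$r_jz, x$boundary$r_myo))
  cat(sprintf("  max residuals: jz %.2f um, myo %.2f um\n",
              x$residuals["jz"], x$residuals["myo"]))
  cat(sprintf("  d_max_allowed = %.2f\n", x$d_max_allowed))
  invisible(x)
}

#' Filter spots by volume floor and mesometrial exclusion
#'
#' Two rules, applied in order: (1) spots with volume strictly below
#' `min_volume` are removed (the floor is inclusive: a spot exactly at
#' `min_volume` is retained; spots with missing volume are retained); (2)
#' spots on the mesometrial side of the cutoff plane are removed, since
#' trophoblast and epithelial signal are indistinguishable there.
#'
#' @param spots a `spot_table`.
#' @param min_volume volume floor in µm³ (default 100, approximating the size
#'   detection limit of light-sheet spot detection).
#' @param frame a `half_dome_frame` supplying the mesometrial cutoff plane.
#' @return A list with `spots` (the retained `spot_table`) and `report`
#'   (counts removed by each rule).
#' @export
filter_spots <- function(spots, min_volume = 100, frame) {
  stopifnot(inherits(spots, "spot_table"), min_volume >= 0,
            inherits(frame, "half_dome_frame"))
  n_in <- nrow(spots)
  if (all(is.na(spots$volume)) && min_volume > 0) {
    warning("spot table has no volumes; volume filter skipped", call. = FALSE)
    keep_vol <- rep(TRUE, n_in)
  } else {
    keep_vol <- is.na(spots$volume) | spots$volume >= min_volume
  }
  removed_volume <- sum(!keep_vol)
  sub <- spots[keep_vol, , drop = FALSE]
  side <- as.vector(.as_points3(sub) %*% frame$axis -
                      sum(frame$meso_point * frame$axis))
  keep_side <- side >= 0
  removed_meso <- sum(!keep_side)
  out <- sub[keep_side, , drop = FALSE]
  class(out) <- class(spots)
  if (nrow(out) == 0L)
    warning("all spots removed by filtering", call. = FALSE)
  list(spots = out,
       report = list(n_input = n_in, removed_volume = removed_volume,
                     removed_mesometrial = removed_meso, n_kept = nrow(out),
                     min_volume = min_volume))
}

#' Map spots into normalized half-dome coordinates
#'
#' Each point is projected along its ray from the fitted center: depth
#' `d = (r - r_jz(dir)) / (r_myo(dir) - r_jz(dir))`, so `d = 0` on the
#' junctional-zone (placental border) surface and `d = 1` on the myometrial
#' surface, continuing linearly into the shell. Azimuth `u` in `[0, 1)` runs
#' around the dome axis with `u = 0` on the front half-plane; polar `v` in
#' `[0, 1]` runs from the apex to the equator. Region flags are exhaustive
#' and mutually exclusive: `decidua` (`0 <= d < 1`, antimesometrial side),
#' `myometrium` (`1 <= d <= d_max_allowed`, antimesometrial side), otherwise
#' `outside`. A point coinciding with the center has no direction; it is
#' excluded and reported via the `"excluded"` attribute.
#'
#' @param spots a `spot_table`, or any matrix/data frame of µm coordinates.
#' @param frame a `half_dome_frame`.
#' @return A `normalized_points` data frame carrying `spot_id`, `channel`,
#'   raw `x`,`y`,`z` and normalized `d`, `u`, `v`, `region`.
#' @export
normalize_points <- function(spots, frame) {
  stopifnot(inherits(frame, "half_dome_frame"))
  p <- .as_points3(spots, "spots")
  ids <- if (is.data.frame(spots) && "spot_id" %in% names(spots))
    spots$spot_id else sprintf("p%05d", seq_len(nrow(p)))
  chan <- if (is.data.frame(spots) && "channel" %in% names(spots))
    spots$channel else rep(NA_character_, nrow(p))

  rel <- sweep(p, 2, frame$center)
  r <- sqrt(rowSums(rel^2))
  degenerate <- r < 1e-9
  excluded <- data.frame(spot_id = ids[degenerate],
                         reason = rep("point at frame center: direction undefined",
                                      sum(degenerate)),
                         stringsAsFactors = FALSE)
  keep <- !degenerate
  rel <- rel[keep, , drop = FALSE]; r <- r[keep]
  p <- p[keep, , drop = FALSE]

  ct <- pmin(1, pmax(-1, as.vector(rel %*% frame$axis) / r))
  r_in <- frame$radius_fun(ct, "jz")
  r_out <- frame$radius_fun(ct, "myo")
  d <- (r - r_in) / (r_out - r_in)

  phi <- atan2(as.vector(rel %*% frame$w), as.vector(rel %*% frame$u0))
  u <- (phi / (2 * pi)) %% 1
  v <- pmin(1, acos(ct) / (pi / 2))

  side <- as.vector(p %*% frame$axis - sum(frame$meso_point * frame$axis)) >= 0
  region <- ifelse(!side, "outside",
                   ifelse(d >= 0 & d < 1, "decidua",
                          ifelse(d >= 1 & d <= frame$d_max_allowed,
                                 "myometrium", "outside")))
  out <- data.frame(spot_id = ids[keep], channel = chan[keep],
                    x = p[, 1], y = p[, 2], z = p[, 3],
                    d = d, u = u, v = v, region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("normalized_points", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "frame") <- frame
  out
}

#' Relative depth of objects in a 2D tissue section
#'
#' Implements the standard 2D-section quantification: each object's minimum
#' Euclidean distance to the placental border point set, normalized by the
#' maximum placenta-to-myometrium span of the section (the largest over
#' myometrium points of their minimum distance to the border). Values above 1
#' are clipped to 1; the number clipped is reported in the `"n_clipped"`
#' attribute and raw ratios in `"raw"`.
#'
#' @param objects n x 2 matrix (or data frame with `x`,`y`) of object
#'   positions in the section plane, µm.
#' @param border placental-border reference points, n x 2.
#' @param myometrium myometrium reference points, n x 2.
#' @return Numeric vector of depths in `[0, 1]`.
#' @export
relative_depth_2d <- function(objects, border, myometrium) {
  as2 <- function(m, what) {
    if (is.data.frame(m)) m <- as.matrix(m[, intersect(c("x", "y"), names(m))])
    m <- as.matrix(m)
    if (ncol(m) != 2) stop(what, ": expected 2 columns", call. = FALSE)
    storage.mode(m) <- "double"
    m
  }
  objects <- as2(objects, "objects")
  border <- as2(border, "border")
  myometrium <- as2(myometrium, "myometrium")
  if (nrow(border) == 0L || nrow(myometrium) == 0L)
    stop("border and myometrium reference sets must be non-empty", call. = FALSE)
  min_d <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(pmax(0, apply(d2, 1, min)))
  }
  span <- max(min_d(myometrium, border))
  if (span <= 0) stop("degenerate section: zero placenta-myometrium span",
                      call. = FALSE)
  raw <- min_d(objects, border) / span
  out <- pmin(1, raw)
  attr(out, "n_clipped") <- sum(raw > 1)
  attr(out, "raw") <- raw
  out
}
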