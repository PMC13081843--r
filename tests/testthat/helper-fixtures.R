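# Shared fixtures, built in code.

# Referents sampled exactly from two concentric hemispherical caps (shared
# center `center`), with optional isotropic jitter. Deterministic placement.
make_cap_referents <- function(r_jz = 900, r_myo = 1500, center = c(0, 0, 0),
                               jitter = 0, n_cap = 24, seed = 1) {
  set.seed(seed)
  dirs <- function(n) {
    ct <- rep(seq(0.15, 0.92, length.out = n / 2), each = 2)
    phi0 <- 2.399963 * seq_len(n / 2)
    phi <- as.vector(rbind(phi0, phi0 + pi))
    st <- sqrt(1 - ct^2)
    cbind(st * cos(phi), st * sin(phi), ct)
  }
  jit <- function(m) m + matrix(rnorm(length(m), 0, jitter), ncol = 3)
  shift <- function(m) sweep(m, 2, center, "+")
  ring <- 2 * pi * (0:7) / 8
  lum <- shift(jit(1.2 * r_myo * cbind(cos(ring), sin(ring), 0)))
  jz <- shift(jit(r_jz * dirs(n_cap)))
  myo <- shift(jit(r_myo * dirs(n_cap)))
  mid <- (r_jz + r_myo) / 2
  front <- shift(jit(mid * cbind(sin(80 * pi / 180), 0, cos(80 * pi / 180))))
  back <- shift(jit(mid * cbind(-sin(80 * pi / 180), 0, cos(80 * pi / 180))))
  df <- data.frame(label = c(rep("luminal_epithelium", 8),
                             rep("junctional_zone_outer", n_cap),
                             rep("myometrium_outer", n_cap), "front", "back"),
                   rbind(lum, jz, myo, front, back))
  names(df)[2:4] <- c("x", "y", "z")
  as_referent_set(df, site_id = "fixture")
}

# A point at normalized depth d along direction (ct, phi) of the ideal
# concentric-cap geometry centered at the origin.
point_at_depth <- function(d, ct = 0.6, phi = 1, r_jz = 900, r_myo = 1500) {
  st <- sqrt(1 - ct^2)
  (r_jz + d * (r_myo - r_jz)) * c(st * cos(phi), st * sin(phi), ct)
}

# Spot table wrapper around a coordinate matrix.
spots_from_matrix <- function(m, channel = "trophoblast", volume = 500) {
  df <- data.frame(spot_id = sprintf("s%04d", seq_len(nrow(m))),
                   x = m[, 1], y = m[, 2], z = m[, 3],
                   volume = volume, channel = channel,
                   site_id = "fixture", group = "test",
                   stringsAsFactors = FALSE)
  class(df) <- c("spot_table", "data.frame")
  df
}

# Straight-line centerline tree between two points, `k` nodes.
line_tree <- function(p0, p1, k = 20, tree_id = "tree_1") {
  s <- seq(0, 1, length.out = k)
  nodes <- data.frame(id = seq_len(k),
                      x = p0[1] + s * (p1[1] - p0[1]),
                      y = p0[2] + s * (p1[2] - p0[2]),
                      z = p0[3] + s * (p1[3] - p0[3]),
                      radius = 10, parent = c(-1L, seq_len(k - 1L)))
  as_centerline_tree(nodes, tree_id = tree_id)
}

# A rotation (about an arbitrary axis) plus translation, applied to rows.
rigid_transform <- function(m, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(300, -150, 80)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(m %*% t(R), 2, shift, "+")
}

apply_rigid_referents <- function(ref, ...) {
  m <- rigid_transform(as.matrix(ref[, c("x", "y", "z")]), ...)
  df <- data.frame(label = ref$label, x = m[, 1], y = m[, 2], z = m[, 3])
  as_referent_set(df, site_id = attr(ref, "site_id"))
}
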