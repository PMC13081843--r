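# interface_metrics module: trophoblast localization classes, invasion
# summaries, artery branch/envelopment/connection metrics from centerline
# trees, and the virtual 2D-section versus 3D comparison.

.CATEGORIES <- c("spiral_artery_adjacent", "interstitial",
                 "myometrial_stromal", "myometrial_artery_adjacent")

#' Resample centerline trees at uniform arc-length spacing
#'
#' Each parent-child segment is subdivided at approximately `step` µm; node
#' positions themselves are always included. Distances measured against the
#' resulting sample set approximate point-to-curve distances to within half
#' a step.
#'
#' @param trees a `centerline_tree` or list of them.
#' @param step arc-length spacing in µm (default 10).
#' @return Data frame with `tree_id`, `x`, `y`, `z` for every sample.
#' @export
resample_centerlines <- function(trees, step = 10) {
  if (inherits(trees, "centerline_tree")) trees <- list(trees)
  stopifnot(step > 0)
  out <- lapply(trees, function(tr) {
    df <- as.data.frame(tr)
    idx <- match(df$parent, df$id)
    segs <- which(!is.na(idx))
    pts <- list(as.matrix(df[df$parent == -1, c("x", "y", "z")]))
    for (i in segs) {
      p0 <- as.numeric(df[idx[i], c("x", "y", "z")])
      p1 <- as.numeric(df[i, c("x", "y", "z")])
      len <- sqrt(sum((p1 - p0)^2))
      k <- max(1L, ceiling(len / step))
      tt <- seq_len(k) / k
      pts[[length(pts) + 1L]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                                       p0[2] + tt * (p1[2] - p0[2]),
                                       p0[3] + tt * (p1[3] - p0[3]))
    }
    m <- do.call(rbind, pts)
    data.frame(tree_id = attr(tr, "tree_id") %||% "tree", x = m[, 1],
               y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify trophoblast localization
#'
#' Four-way exhaustive classification of every in-domain trophoblast:
#' decidual points (`0 <= d < 1`) are `spiral_artery_adjacent` when their
#' minimum Euclidean distance (raw µm) to any artery reference point is at
#' most `r_adj`, otherwise `interstitial`; myometrial points
#' (`1 <= d <= d_max`) are analogously `myometrial_artery_adjacent` or
#' `myometrial_stromal`. Points flagged `outside` are not classified.
#'
#' @param trophoblasts `normalized_points` for the trophoblast channel.
#' @param arteries artery reference positions in raw µm: a data frame or
#'   matrix of points (e.g. [resample_centerlines()] output or artery spots).
#'   An empty reference set classifies everything as non-adjacent with a
#'   warning.
#' @param r_adj adjacency radius in µm (default 20, about one to two
#'   trophoblast diameters).
#' @return A `localization_breakdown`: counts and fractions per category,
#'   the per-point assignment, and the radius used.
#' @export
classify_trophoblasts <- function(trophoblasts, arteries, r_adj = 20) {
  stopifnot(inherits(trophoblasts, "normalized_points"), r_adj > 0)
  dom <- trophoblasts[trophoblasts$region %in% c("decidua", "myometrium"), ,
                      drop = FALSE]
  if (is.null(arteries) || NROW(arteries) == 0L) {
    warning("no artery reference points; all trophoblasts classified as ",
            "non-adjacent", call. = FALSE)
    near <- rep(FALSE, nrow(dom))
  } else {
    near <- .min_dist_to_set(dom, .as_points3(arteries, "arteries")) <= r_adj
  }
  myo <- dom$region == "myometrium"
  category <- ifelse(myo,
                     ifelse(near, "myometrial_artery_adjacent",
                            "myometrial_stromal"),
                     ifelse(near, "spiral_artery_adjacent", "interstitial"))
  counts <- table(factor(category, levels = .CATEGORIES))
  n <- nrow(dom)
  breakdown <- data.frame(category = .CATEGORIES,
                          n = as.integer(counts),
                          fraction = if (n > 0) as.numeric(counts) / n
                          else rep(NA_real_, 4L),
                          stringsAsFactors = FALSE)
  per_point <- data.frame(spot_id = dom$spot_id, d = dom$d,
                          region = dom$region, category = category,
                          stringsAsFactors = FALSE)
  structure(list(breakdown = breakdown, per_point = per_point,
                 n_in_domain = n, r_adj = r_adj),
            class = "localization_breakdown")
}

#' @export
print.localization_breakdown <- function(x, ...) {
  cat("Trophoblast localization (r_adj =", x$r_adj, "um, n =",
      x$n_in_domain, "):\n")
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Summarize trophoblast invasion depth
#'
#' Per-point normalized depths of all in-domain trophoblasts, their maximum
#' (the headline invasion statistic), and the fraction at `d >= 1`
#' (myometrial invaders -- abnormal for mouse pregnancy).
#'
#' @param trophoblasts `normalized_points` for the trophoblast channel.
#' @return An `invasion_summary`; when no trophoblast is in domain the
#'   summary is returned with `empty = TRUE` and `NA` statistics rather
#'   than zeros.
#' @export
invasion_summary <- function(trophoblasts) {
  stopifnot(inherits(trophoblasts, "normalized_points"))
  dom <- trophoblasts[trophoblasts$region %in% c("decidua", "myometrium"), ,
                      drop = FALSE]
  if (nrow(dom) == 0L)
    return(structure(list(empty = TRUE, n = 0L, max_depth = NA_real_,
                          myometrial_fraction = NA_real_, depths = numeric(0)),
                     class = "invasion_summary"))
  structure(list(empty = FALSE, n = nrow(dom), max_depth = max(dom$d),
                 myometrial_fraction = mean(dom$d >= 1), depths = dom$d),
            class = "invasion_summary")
}

#' @export
print.invasion_summary <- function(x, ...) {
  if (x$empty) cat("Invasion summary: no in-domain trophoblasts\n")
  else cat(sprintf(paste0("Invasion summary: n = %d, max depth = %.3f, ",
                          "myometrial fraction = %.3f\n"),
                   x$n, x$max_depth, x$myometrial_fraction))
  invisible(x)
}

.tree_depths <- function(tree, frame) {
  np <- normalize_points(as.data.frame(tree)[, c("x", "y", "z")], frame)
  np$d
}

#' Count artery branches entering the decidua
#'
#' A branch "enters" where a tree edge crosses the `d = 1` surface inward
#' (parent at `d >= 1`, child at `d < 1`). Each root-to-leaf path contributes
#' at most one entry per distinct entering branch: once a path has crossed
#' inward, further wiggles across the surface on that path are not
#' re-counted, but independent daughters that each descend from the
#' myometrium count separately.
#'
#' @param trees list of `centerline_tree` objects.
#' @param frame a `half_dome_frame`.
#' @return Integer total; per-tree counts in attribute `"per_tree"`. Trees
#'   entirely inside the decidua contribute 0 with a warning (no myometrial
#'   anchor).
#' @export
count_decidual_branches <- function(trees, frame) {
  if (inherits(trees, "centerline_tree")) trees <- list(trees)
  per_tree <- vapply(trees, function(tr) {
    df <- as.data.frame(tr)
    d <- .tree_depths(tr, frame)
    if (all(d < 1)) {
      warning("tree ", attr(tr, "tree_id"),
              " lies entirely inside the decidua; no myometrial anchor",
              call. = FALSE)
      return(0L)
    }
    children <- split(seq_len(nrow(df)), match(df$parent, df$id))
    root <- which(df$parent == -1)
    count <- 0L
    # iterative DFS; `crossed` is sticky down each path after the first entry
    stack <- list(list(node = root, crossed = FALSE))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      kids <- children[[as.character(top$node)]]
      for (k in kids) {
        enters <- d[top$node] >= 1 && d[k] < 1
        cr <- top$crossed
        if (!cr && enters) { count <- count + 1L; cr <- TRUE }
        stack[[length(stack) + 1L]] <- list(node = k, crossed = cr)
      }
    }
    count
  }, integer(1))
  structure(sum(per_tree), per_tree = per_tree)
}

#' Trophoblast envelopment of spiral arteries
#'
#' Each artery's decidual centerline (samples with `0 <= d < 1`) is scored by
#' the fraction of samples having at least one trophoblast within `r_env`;
#' the artery is "enveloped" when that fraction reaches `coverage_threshold`
#' (default 0.5 -- trophoblasts along most of its length). Arteries with no
#' decidual segment are excluded from the denominator.
#'
#' @param trees list of `centerline_tree` objects.
#' @param trophoblasts trophoblast positions in raw µm (matrix, data frame,
#'   `spot_table`, or `normalized_points`).
#' @param frame a `half_dome_frame`.
#' @param r_env envelopment radius, µm.
#' @param coverage_threshold fraction of decidual length in `(0, 1]`.
#' @param step centerline resampling step, µm.
#' @return An `artery_metrics` data frame with one row per artery
#'   (`tree_id`, `n_decidual_samples`, `envelopment_fraction`, `enveloped`)
#'   plus summary attributes `n_enveloped`, `n_evaluated`, `n_excluded`.
#' @export
envelopment <- function(trees, trophoblasts, frame, r_env = 20,
                        coverage_threshold = 0.5, step = 10) {
  stopifnot(r_env > 0, coverage_threshold > 0, coverage_threshold <= 1)
  if (inherits(trees, "centerline_tree")) trees <- list(trees)
  tp <- .as_points3(trophoblasts, "trophoblasts")
  samples <- resample_centerlines(trees, step)
  d <- normalize_points(samples[, c("x", "y", "z")], frame)$d
  rows <- lapply(unique(samples$tree_id), function(id) {
    sel <- samples$tree_id == id & d >= 0 & d < 1
    if (!any(sel))
      return(data.frame(tree_id = id, n_decidual_samples = 0L,
                        envelopment_fraction = NA_real_, enveloped = NA))
    md <- .min_dist_to_set(samples[sel, c("x", "y", "z")], tp)
    frac <- mean(md <= r_env)
    data.frame(tree_id = id, n_decidual_samples = sum(sel),
               envelopment_fraction = frac,
               enveloped = frac >= coverage_threshold)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("artery_metrics", "data.frame"),
            n_enveloped = sum(out$enveloped, na.rm = TRUE),
            n_evaluated = sum(!is.na(out$enveloped)),
            n_excluded = sum(is.na(out$enveloped)),
            r_env = r_env, coverage_threshold = coverage_threshold)
}

#' Count arteries connected to the placenta
#'
#' A tree is connected when at least one of its terminal nodes reaches the
#' junctional-zone surface: normalized depth `d <= tolerance / shell`, where
#' `shell` is the local decidual thickness in µm along the leaf's ray.
#'
#' @param trees list of `centerline_tree` objects.
#' @param frame a `half_dome_frame`.
#' @param tolerance reach tolerance in µm (default 30).
#' @return Integer count; per-tree logical in attribute `"connected"`.
#' @export
count_placenta_connected <- function(trees, frame, tolerance = 30) {
  if (inherits(trees, "centerline_tree")) trees <- list(trees)
  stopifnot(tolerance >= 0)
  connected <- vapply(trees, function(tr) {
    df <- as.data.frame(tr)
    leaves <- !(df$id %in% df$parent)
    p <- .as_points3(df[leaves, c("x", "y", "z")])
    np <- normalize_points(p, frame)
    rel <- sweep(p, 2, frame$center)
    r <- sqrt(rowSums(rel^2))
    ct <- pmin(1, pmax(-1, as.vector(rel %*% frame$axis) / r))
    shell <- frame$radius_fun(ct, "myo") - frame$radius_fun(ct, "jz")
    any(np$d <= tolerance / shell)
  }, logical(1))
  structure(sum(connected), connected = connected, tolerance = tolerance)
}

#' Virtual 2D sections versus the full 3D measurement
#'
#' Emulates midline cryosectioning of an implantation site: the midline plane
#' contains the dome axis and the front-back axis, and parallel slabs of
#' `slab_thickness` are taken at the given offsets. Each section's invasion
#' read-out is the maximum normalized depth among the trophoblasts inside the
#' slab, i.e. the depth measure is the frame's own placenta-to-myometrium
#' axis evaluated on the section's subset of points, so a section can never
#' exceed the 3D maximum and the comparison isolates pure sampling bias.
#' The discrepancy ratio is `3D max / mean(per-section max)`.
#'
#' @param trophoblasts `normalized_points` for the trophoblast channel.
#' @param frame a `half_dome_frame`.
#' @param slab_thickness section thickness, µm (default 70, a typical
#'   cryosection).
#' @param offsets slab center offsets from the midline, µm; defaults to five
#'   sections within ±240 µm.
#' @param min_sections minimum number of non-empty sections required to
#'   report a mean (default 3).
#' @return A `section_comparison`: per-section table, 3D maximum, ratio, and
#'   the parameters used. When fewer than `min_sections` sections contain a
#'   trophoblast the ratio is `NA` with a reason.
#' @export
virtual_sections <- function(trophoblasts, frame, slab_thickness = 70,
                             offsets = c(-240, -120, 0, 120, 240),
                             min_sections = 3) {
  stopifnot(inherits(trophoblasts, "normalized_points"),
            inherits(frame, "half_dome_frame"), slab_thickness > 0)
  dom <- trophoblasts[trophoblasts$region %in% c("decidua", "myometrium"), ,
                      drop = FALSE]
  if (nrow(dom) == 0L)
    stop("no in-domain trophoblasts to section", call. = FALSE)
  p <- .as_points3(dom)
  off_coord <- as.vector(sweep(p, 2, frame$center) %*% frame$w)
  secs <- lapply(offsets, function(o) {
    inside <- abs(off_coord - o) <= slab_thickness / 2
    data.frame(offset = o, n = sum(inside),
               max_depth_2d = if (any(inside)) max(dom$d[inside]) else NA_real_)
  })
  secs <- do.call(rbind, secs)
  max3d <- max(dom$d)
  nonempty <- sum(!is.na(secs$max_depth_2d))
  if (nonempty >= min_sections) {
    ratio <- max3d / mean(secs$max_depth_2d, na.rm = TRUE)
    reason <- NULL
  } else {
    ratio <- NA_real_
    reason <- sprintf("only %d non-empty sections (need >= %d)",
                      nonempty, min_sections)
  }
  structure(list(sections = secs, max_depth_3d = max3d, ratio = ratio,
                 reason = reason, slab_thickness = slab_thickness,
                 offsets = offsets, n_nonempty = nonempty),
            class = "section_comparison")
}

#' @export
print.section_comparison <- function(x, ...) {
  cat(sprintf("Virtual sections (thickness %g um):\n", x$slab_thickness))
  print(x$sections, row.names = FALSE)
  cat(sprintf("  3D max depth %.3f; discrepancy ratio (3D / mean 2D) = %s\n",
              x$max_depth_3d,
              if (is.na(x$ratio)) paste0("NA (", x$reason, ")")
              else sprintf("%.3f", x$ratio)))
  invisible(x)
}
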