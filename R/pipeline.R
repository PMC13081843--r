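# cli_pipeline module: end-to-end orchestration with config, provenance and
# deterministic seeding. The package's functions (and the vignette) are the
# interface; `run_site()` and `run_cohort()` compose every stage.

#' Analysis configuration for a pipeline run
#'
#' All tunable parameters of the analysis stages in one record; every value
#' is echoed into the run manifest so results are traceable.
#'
#' @param min_volume spot volume floor, µm³.
#' @param boundary_model half-dome boundary family (`"sphere"`/`"spheroid"`).
#' @param d_max_allowed outermost reported normalized depth.
#' @param r_adj trophoblast-artery adjacency radius, µm.
#' @param r_env envelopment radius, µm.
#' @param coverage_threshold enveloped-artery coverage threshold.
#' @param centerline_step centerline resampling step, µm.
#' @param connection_tolerance placental-connection tolerance, µm.
#' @param bandwidth,grid_shape,n_boot,ci_level density/overlap settings (see
#'   [bootstrap_overlap()]).
#' @param slab_thickness,section_offsets,min_sections virtual-section
#'   settings (see [virtual_sections()]).
#' @param seed master seed for all randomness in the run.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(min_volume = 100,
                            boundary_model = "sphere", d_max_allowed = 1.5,
                            r_adj = 20, r_env = 20, coverage_threshold = 0.5,
                            centerline_step = 10, connection_tolerance = 30,
                            bandwidth = "scott", grid_shape = c(50, 50, 50),
                            n_boot = 1000, ci_level = 0.95,
                            slab_thickness = 70,
                            section_offsets = c(-240, -120, 0, 120, 240),
                            min_sections = 3, seed = 1) {
  structure(as.list(environment()), class = "analysis_config")
}

# Normalized half-dome Cartesian coordinates used for density estimation:
# frame-local axes (front, side, dome axis) scaled by the myometrial radius,
# so sites of different absolute size share one dimensionless domain.
.frame_coords <- function(points, frame) {
  rel <- sweep(.as_points3(points), 2, frame$center)
  cbind(rel %*% frame$u0, rel %*% frame$w, rel %*% frame$axis) /
    frame$boundary$r_myo
}

.digest_or_na <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    unname(tools::md5sum(x)) else NA_character_
}

#' Run the full analysis on one implantation site
#'
#' Composes every stage: referent-based frame fitting, spot filtering
#' (volume floor + mesometrial exclusion), coordinate normalization, density
#' overlap with bootstrap CI, trophoblast localization, invasion summary,
#' artery metrics from centerline trees (when supplied), and the virtual
#' 2D-vs-3D section comparison. Re-running with the same inputs, config and
#' seed reproduces every number bit-identically. Stages that cannot run are
#' recorded with an explicit reason rather than silently skipped.
#'
#' @param spots a `spot_table` or path readable by [read_spot_table()].
#' @param referents a `referent_set` or path for [read_referents()].
#' @param trees optional list of `centerline_tree`s or SWC path.
#' @param config an [analysis_config()].
#' @return A `site_report` list: `frame`, `filter_report`, `overlap`,
#'   `localization`, `invasion`, `artery_metrics`, `sections`, `manifest`.
#' @export
run_site <- function(spots, referents, trees = NULL,
                     config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  digests <- list(spots = .digest_or_na(spots),
                  referents = .digest_or_na(referents),
                  trees = .digest_or_na(trees))
  if (is.character(spots)) spots <- read_spot_table(spots)
  if (is.character(referents)) referents <- read_referents(referents)
  if (is.character(trees)) trees <- read_centerline_trees(trees)
  site_id <- spots$site_id[1] %||% NA_character_

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for site ", site_id, ": ",
           conditionMessage(e), call. = FALSE))
  }

  frame <- stage("frame", fit_half_dome_frame(
    referents, boundary_model = config$boundary_model,
    d_max_allowed = config$d_max_allowed))
  flt <- stage("filter", filter_spots(spots, config$min_volume, frame))
  kept <- flt$spots
  norm <- stage("normalize", normalize_points(kept, frame))
  tro <- norm[norm$channel == "trophoblast", , drop = FALSE]
  art <- norm[norm$channel == "artery", , drop = FALSE]
  class(tro) <- class(art) <- class(norm)

  in_dom <- function(np) np[np$region != "outside", , drop = FALSE]
  overlap <- NULL; overlap_reason <- NULL
  if (nrow(in_dom(art)) >= 2 && nrow(in_dom(tro)) >= 2) {
    overlap <- stage("overlap", bootstrap_overlap(
      .frame_coords(in_dom(art), frame), .frame_coords(in_dom(tro), frame),
      n_boot = config$n_boot, seed = config$seed,
      bandwidth = config$bandwidth, grid_shape = config$grid_shape,
      ci_level = config$ci_level))
  } else {
    overlap_reason <- "fewer than 2 in-domain points in a channel"
  }

  artery_ref <- if (!is.null(trees) && length(trees))
    resample_centerlines(trees, config$centerline_step)
  else if (nrow(art)) art[, c("x", "y", "z")] else NULL

  localization <- NULL; invasion <- NULL; loc_reason <- NULL
  if (nrow(tro)) {
    localization <- stage("localization",
                          classify_trophoblasts(tro, artery_ref,
                                                r_adj = config$r_adj))
    invasion <- stage("invasion", invasion_summary(tro))
  } else loc_reason <- "no trophoblast spots after filtering"

  artery_metrics <- NULL; artery_reason <- NULL
  if (!is.null(trees) && length(trees)) {
    artery_metrics <- stage("artery_metrics", list(
      n_branches = as.integer(count_decidual_branches(trees, frame)),
      n_connected = as.integer(count_placenta_connected(
        trees, frame, config$connection_tolerance)),
      envelopment = envelopment(trees, tro, frame, r_env = config$r_env,
                                coverage_threshold = config$coverage_threshold,
                                step = config$centerline_step)))
  } else artery_reason <- "no centerline trees supplied"

  sections <- NULL; section_reason <- NULL
  if (nrow(in_dom(tro)) > 0) {
    sections <- stage("sections", virtual_sections(
      tro, frame, slab_thickness = config$slab_thickness,
      offsets = config$section_offsets, min_sections = config$min_sections))
  } else section_reason <- "no in-domain trophoblasts"

  manifest <- list(
    package = "deciduamap",
    version = as.character(utils::packageVersion("deciduamap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    site_id = site_id, seed = config$seed,
    config = unclass(config), input_digests = digests,
    counts = list(spots_in = flt$report$n_input,
                  spots_kept = flt$report$n_kept,
                  trophoblasts = nrow(tro), arteries = nrow(art),
                  trees = if (is.null(trees)) 0L else length(trees)),
    omitted = Filter(Negate(is.null),
                     list(overlap = overlap_reason,
                          localization = loc_reason,
                          artery_metrics = artery_reason,
                          sections = section_reason)))

  structure(list(site_id = site_id, frame = frame,
                 filter_report = flt$report, overlap = overlap,
                 localization = localization, invasion = invasion,
                 artery_metrics = artery_metrics, sections = sections,
                 manifest = manifest),
            class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  cat("Site report:", x$site_id, "\n")
  cat(sprintf("  spots kept %d / %d\n", x$filter_report$n_kept,
              x$filter_report$n_input))
  if (!is.null(x$overlap)) print(x$overlap)
  if (!is.null(x$invasion)) print(x$invasion)
  if (!is.null(x$artery_metrics))
    cat(sprintf("  artery branches %d, placenta-connected %d, enveloped %d/%d\n",
                x$artery_metrics$n_branches, x$artery_metrics$n_connected,
                attr(x$artery_metrics$envelopment, "n_enveloped"),
                attr(x$artery_metrics$envelopment, "n_evaluated")))
  if (length(x$manifest$omitted))
    cat("  omitted:", paste(names(x$manifest$omitted),
                            unlist(x$manifest$omitted), sep = ": ",
                            collapse = "; "), "\n")
  invisible(x)
}

# Scalar per-site metrics used for group comparisons.
.site_metrics <- function(rep) {
  env <- rep$artery_metrics$envelopment
  c(bc_median = if (!is.null(rep$overlap)) rep$overlap$bootstrap_median else NA,
    max_depth = if (!is.null(rep$invasion)) rep$invasion$max_depth else NA,
    myometrial_fraction = if (!is.null(rep$invasion))
      rep$invasion$myometrial_fraction else NA,
    spiral_adjacent_fraction = if (!is.null(rep$localization))
      rep$localization$breakdown$fraction[1] else NA,
    n_branches = if (!is.null(rep$artery_metrics))
      rep$artery_metrics$n_branches else NA,
    n_connected = if (!is.null(rep$artery_metrics))
      rep$artery_metrics$n_connected else NA,
    enveloped_fraction = if (!is.null(env))
      attr(env, "n_enveloped") / max(1L, attr(env, "n_evaluated")) else NA)
}

#' Run the analysis over a cohort and compare groups
#'
#' Runs [run_site()] on every site, assembles the per-site scalar metrics,
#' and (with at least two groups) compares each metric between groups with
#' the requested test. Single-group cohorts return per-site reports only,
#' with an explicit notice. An optional 2x2 binary-outcome table (e.g.
#' adhesion rates) is analyzed with [fisher_exact()] and [odds_ratio_ci()].
#'
#' @param sites list of site bundles: each a list with `spots`, `referents`,
#'   optional `trees` (the structure produced by [generate_site()] /
#'   [generate_cohort()]).
#' @param config an [analysis_config()]; per-site seeds are derived from
#'   `config$seed`.
#' @param method group-comparison method for [group_compare()].
#' @param binary_outcomes optional 2x2 count matrix for the Fisher path.
#' @return A `cohort_report`: per-site reports, metric table, group
#'   comparisons (or a notice), and optional contingency results.
#' @export
run_cohort <- function(sites, config = analysis_config(),
                       method = "mannwhitney_pairwise",
                       binary_outcomes = NULL) {
  stopifnot(length(sites) >= 1)
  seeds <- .with_seed(config$seed, sample.int(2^30, length(sites)))
  reports <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    run_site(s$spots, s$referents, s$trees, cfg_i)
  })
  groups <- vapply(sites, function(s) s$spots$group[1] %||% NA_character_,
                   character(1))
  metrics <- do.call(rbind, lapply(reports, .site_metrics))
  metrics <- data.frame(site_id = vapply(reports, `[[`, "", "site_id"),
                        group = groups, metrics, row.names = NULL)

  comparisons <- list(); notice <- NULL
  if (length(unique(groups)) >= 2) {
    for (mcol in setdiff(names(metrics), c("site_id", "group"))) {
      vals <- split(metrics[[mcol]], metrics$group)
      vals <- lapply(vals, function(v) v[!is.na(v)])
      if (any(vapply(vals, length, integer(1)) < 2)) next
      comparisons[[mcol]] <- tryCatch(
        group_compare(vals, method = method),
        error = function(e) paste("not compared:", conditionMessage(e)))
    }
  } else {
    notice <- "single group: comparisons skipped"
  }
  contingency <- NULL
  if (!is.null(binary_outcomes)) {
    contingency <- list(fisher = fisher_exact(binary_outcomes),
                        odds_ratio = odds_ratio_ci(binary_outcomes))
  }
  structure(list(reports = reports, metrics = metrics,
                 comparisons = comparisons, notice = notice,
                 contingency = contingency,
                 seed = config$seed, site_seeds = seeds),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report:", nrow(x$metrics), "sites\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  if (!is.null(x$notice)) cat(" ", x$notice, "\n")
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    if (inherits(cm, "group_test")) {
      cat("--", nm, "--\n"); print(cm)
    }
  }
  invisible(x)
}
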