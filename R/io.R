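# io_formats module: spot tables, anatomical referents, SWC-like centerline
# trees, and result serialization. All coordinates are carried internally in
# micrometres; no recentring happens at read time.

.CHANNELS <- c("artery", "trophoblast")
.REFERENT_LABELS <- c("luminal_epithelium", "myometrium_outer",
                      "junctional_zone_outer", "front", "back")

#' Describe the column layout of a spot-table export
#'
#' Segmentation packages export point detections with vendor-specific column
#' names and units. A dialect maps those columns onto the fields the package
#' needs and supplies a multiplicative factor converting positions to
#' micrometres. The default matches common exports with columns
#' `"Position X"/"Position Y"/"Position Z"`, `"Volume"`, `"Channel"` and
#' `"ID"` already in micrometres.
#'
#' @param sep field separator (`","` or `"\t"`).
#' @param col_x,col_y,col_z names of the coordinate columns.
#' @param col_volume name of the volume column (µm³), or `NA` if absent.
#' @param col_channel name of the channel column.
#' @param col_id name of the spot identifier column, or `NA` to number rows.
#' @param scale factor applied to coordinates to obtain µm (e.g. 1000 for mm).
#' @param channel_map named character vector translating channel values in the
#'   file to `"artery"`/`"trophoblast"`; identity by default.
#' @return A `spot_dialect` list.
#' @export
spot_dialect <- function(sep = ",", col_x = "Position X", col_y = "Position Y",
                         col_z = "Position Z", col_volume = "Volume",
                         col_channel = "Channel", col_id = "ID",
                         scale = 1, channel_map = NULL) {
  stopifnot(is.numeric(scale), scale > 0)
  structure(list(sep = sep, col_x = col_x, col_y = col_y, col_z = col_z,
                 col_volume = col_volume, col_channel = col_channel,
                 col_id = col_id, scale = scale, channel_map = channel_map),
            class = "spot_dialect")
}

.new_spot_table <- function(df, site_id = NA_character_, group = NA_character_) {
  stopifnot(all(c("spot_id", "x", "y", "z", "volume", "channel") %in% names(df)))
  df$site_id <- df$site_id %||% site_id
  if (!"site_id" %in% names(df)) df$site_id <- site_id
  if (!"group" %in% names(df)) df$group <- group
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a spot table
#'
#' Reads a delimited export of point detections, applies the dialect's column
#' mapping and unit scale, and validates each row. Rows with non-finite
#' coordinates, negative volumes, or channels outside
#' `c("artery", "trophoblast")` are rejected; they are returned in the
#' `"rejected"` attribute together with row indices and reasons, so that
#' accepted plus rejected rows always account for every input row.
#'
#' @param path file to read.
#' @param dialect a [spot_dialect()].
#' @param site_id,group identifiers attached to every accepted row.
#' @return A `spot_table` data frame with columns `spot_id`, `x`, `y`, `z`
#'   (µm), `volume` (µm³, possibly `NA`), `channel`, `site_id`, `group`, and
#'   attribute `rejected`.
#' @export
read_spot_table <- function(path, dialect = spot_dialect(),
                            site_id = NA_character_, group = NA_character_) {
  if (!file.exists(path)) stop("spot table not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0L) stop("spot table is empty: ", path, call. = FALSE)
  for (col in c(dialect$col_x, dialect$col_y, dialect$col_z, dialect$col_channel)) {
    if (!col %in% names(raw))
      stop("spot table missing required column '", col, "'", call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  has_vol <- !is.na(dialect$col_volume) && dialect$col_volume %in% names(raw)
  if (!has_vol)
    warning("no volume column; volume-based filtering will be a no-op",
            call. = FALSE)
  ch <- as.character(raw[[dialect$col_channel]])
  if (!is.null(dialect$channel_map)) {
    mapped <- dialect$channel_map[ch]
    ch <- ifelse(is.na(mapped), ch, unname(mapped))
  }
  ids <- if (!is.na(dialect$col_id) && dialect$col_id %in% names(raw))
    as.character(raw[[dialect$col_id]]) else sprintf("spot_%05d", seq_len(nrow(raw)))
  df <- data.frame(spot_id = ids,
                   x = num(dialect$col_x) * dialect$scale,
                   y = num(dialect$col_y) * dialect$scale,
                   z = num(dialect$col_z) * dialect$scale,
                   volume = if (has_vol) num(dialect$col_volume) else NA_real_,
                   channel = ch, stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(df))
  bad_coord <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  reason[bad_coord] <- "non-finite coordinate"
  bad_vol <- has_vol & !is.na(df$volume) & df$volume < 0
  reason[is.na(reason) & bad_vol] <- "negative volume"
  bad_ch <- !(df$channel %in% .CHANNELS)
  reason[is.na(reason) & bad_ch] <- paste0("unknown channel (allowed: ",
                                           paste(.CHANNELS, collapse = ", "), ")")
  reason[is.na(reason) & duplicated(df$spot_id)] <- "duplicate spot_id"
  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- .new_spot_table(df[keep, , drop = FALSE], site_id, group)
  message(sum(keep), " spots accepted, ", nrow(rejected), " rejected from ",
          basename(path))
  attr(out, "rejected") <- rejected
  out
}

#' Read anatomical referents
#'
#' Referents are labelled landmark points placed on an implantation site:
#' luminal epithelium of the neighbouring inter-implantation sites
#' (mesometrial side), the outer junctional-zone edge (placental border), the
#' outer myometrium edge, and single "front"/"back" markers that anchor the
#' azimuthal origin. Accepts JSON (array of objects with `label`, `x`, `y`,
#' `z`) or delimited text with those columns.
#'
#' @param path file to read.
#' @param site_id site identifier attached to the set.
#' @return A `referent_set` data frame with columns `label`, `x`, `y`, `z`.
#' @export
read_referents <- function(path, site_id = NA_character_) {
  if (!file.exists(path)) stop("referent file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  }
  as_referent_set(df, site_id = site_id)
}

#' Validate a referent data frame
#'
#' @param df data frame with columns `label`, `x`, `y`, `z`.
#' @param site_id site identifier.
#' @return A validated `referent_set`.
#' @export
as_referent_set <- function(df, site_id = NA_character_) {
  if (!all(c("label", "x", "y", "z") %in% names(df)))
    stop("referents need columns label, x, y, z", call. = FALSE)
  unknown <- setdiff(unique(df$label), .REFERENT_LABELS)
  if (length(unknown))
    stop("unknown referent label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(.REFERENT_LABELS, collapse = ", "), call. = FALSE)
  cnt <- table(factor(df$label, levels = .REFERENT_LABELS))
  need <- c(luminal_epithelium = 1, myometrium_outer = 4,
            junctional_zone_outer = 4, front = 1, back = 1)
  low <- names(need)[cnt[names(need)] < need]
  if (length(low))
    stop("too few referent points for: ",
         paste(sprintf("%s (need >= %d, have %d)", low, need[low], cnt[low]),
               collapse = "; "), call. = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("referent coordinates must be finite", call. = FALSE)
  out <- df[, c("label", "x", "y", "z")]
  rownames(out) <- NULL
  attr(out, "site_id") <- site_id
  class(out) <- c("referent_set", "data.frame")
  out
}

#' Read centerline trees from an SWC-like file
#'
#' Seven whitespace-separated columns per node: `id type x y z radius parent`,
#' with `parent = -1` marking a root. Lines starting with `#` are comments.
#' Each root and its descendants form one tree; a file may hold several.
#'
#' @param path file to read.
#' @param site_id site identifier attached to each tree.
#' @return A list of `centerline_tree` objects (data frame of nodes plus
#'   `tree_id`/`site_id` attributes).
#' @export
read_centerline_trees <- function(path, site_id = NA_character_) {
  if (!file.exists(path)) stop("centerline file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  .build_trees(df[, c("id", "x", "y", "z", "radius", "parent")], site_id)
}

.build_trees <- function(nodes, site_id = NA_character_) {
  if (anyDuplicated(nodes$id)) stop("duplicated node ids", call. = FALSE)
  if (any(nodes$radius <= 0)) stop("node radii must be > 0", call. = FALSE)
  idx <- match(nodes$parent, nodes$id)
  orphan <- nodes$parent != -1 & is.na(idx)
  if (any(orphan))
    stop("orphan parent reference(s) at node id(s): ",
         paste(nodes$id[orphan], collapse = ", "), call. = FALSE)
  # root of each node, with cycle detection along parent chains
  root <- integer(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0)
    j <- i
    while (nodes$parent[j] != -1) {
      if (j %in% seen)
        stop("parent cycle involving node id(s): ",
             paste(nodes$id[seen], collapse = ", "), call. = FALSE)
      seen <- c(seen, j)
      j <- idx[j]
    }
    root[i] <- j
  }
  lapply(seq_along(unique(root)), function(k) {
    r <- unique(root)[k]
    sub <- nodes[root == r, , drop = FALSE]
    rownames(sub) <- NULL
    structure(sub, class = c("centerline_tree", "data.frame"),
              tree_id = paste0("tree_", k), site_id = site_id)
  })
}

#' Construct a centerline tree from a node table
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z`, `radius`,
#'   `parent` (`-1` = root).
#' @param tree_id,site_id identifiers.
#' @return A `centerline_tree`.
#' @export
as_centerline_tree <- function(nodes, tree_id = "tree_1", site_id = NA_character_) {
  trees <- .build_trees(nodes, site_id)
  if (length(trees) != 1L)
    stop("node table contains ", length(trees), " roots; expected one",
         call. = FALSE)
  attr(trees[[1L]], "tree_id") <- tree_id
  trees[[1L]]
}

#' Write centerline trees to an SWC file
#' @param trees list of `centerline_tree` objects.
#' @param path output file.
#' @export
write_centerline_trees <- function(trees, path) {
  if (inherits(trees, "centerline_tree")) trees <- list(trees)
  offset <- 0L
  rows <- lapply(trees, function(tr) {
    df <- as.data.frame(tr)
    remap <- stats::setNames(df$id + offset, df$id)
    out <- data.frame(id = df$id + offset, type = 2L,
                      x = df$x, y = df$y, z = df$z, radius = df$radius,
                      parent = ifelse(df$parent == -1, -1L,
                                      unname(remap[as.character(df$parent)])))
    offset <<- offset + max(df$id)
    out
  })
  utils::write.table(do.call(rbind, rows), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a result record
#'
#' JSON preserves nested result objects (overlap results, manifests) at full
#' double precision; delimited output flattens a data frame (or a list
#' coercible to one) to a table with a header row.
#'
#' @param results a result record (list or data frame).
#' @param path output file.
#' @param format `"json"` or `"delimited"`.
#' @param sep field separator for delimited output.
#' @export
write_results <- function(results, path, format = c("json", "delimited"),
                          sep = "\t") {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory",
                             call. = FALSE)
  if (format == "json") {
    # I(17) significant digits: doubles survive the round-trip bit-exactly
    jsonlite::write_json(.strip_classes(results), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, null = "null",
                         na = "null")
  } else {
    df <- as.data.frame(results)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# jsonlite serializes S3 classes it does not know by attribute-stripping
# anyway; do it explicitly so round-trips are predictable.
.strip_classes <- function(x) {
  if (is.data.frame(x)) { class(x) <- "data.frame"; return(x) }
  if (is.list(x)) { attributes(x) <- attributes(x)["names"]; return(lapply(x, .strip_classes)) }
  x
}

#' Read back a JSON result record
#' @param path file written by [write_results()].
#' @return The deserialized list.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
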