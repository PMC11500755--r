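#' Streamline length
#'
#' Sum of Euclidean segment lengths of a polyline.
#'
#' @param polyline numeric matrix, points x 3 (mm).
#' @return length in mm.
#' @export
streamline_length <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("a streamline needs at least 2 points")
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Maximum turning angle of a polyline
#'
#' Largest angle (degrees) between successive segment directions.
#'
#' @param polyline numeric matrix, points x 3 (mm), at least 3 points.
#' @return degrees in `[0, 180]`.
#' @export
max_turning_angle <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 3) stop("turning angles need at least 3 points")
  d <- diff(polyline)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("degenerate zero-length segment")
  u <- d / len
  cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  max(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
}

#' Streamline filter configuration
#'
#' The standard tracking acceptance parameters: quantitative anisotropy
#' (QA) >= 0.05, maximum turning angle <= 70 degrees, length 20-250 mm, and
#' exclusion of streamlines touching labeled regions (brainstem, basal
#' ganglia, thalamus, CSF by default masks).
#'
#' @param qa_min QA threshold.
#' @param angle_max degrees.
#' @param length_range mm, `(min, max)`.
#' @param exclusion_regions data.frame of spherical masks (label, x, y, z,
#'   radius) or NULL to skip the exclusion step.
#' @export
filter_config <- function(qa_min = 0.05, angle_max = 70,
                          length_range = c(20, 250),
                          exclusion_regions = NULL) {
  stopifnot(length(length_range) == 2, length_range[1] > 0,
            length_range[1] < length_range[2], angle_max > 0,
            angle_max <= 180)
  structure(list(qa_min = qa_min, angle_max = angle_max,
                 length_range = length_range,
                 exclusion_regions = exclusion_regions),
            class = "filter_config")
}

split_streamlines <- function(set) {
  split(as.data.frame(set)[c("x", "y", "z")], set$streamline_id)
}

#' Filter a streamline set
#'
#' Keeps streamlines with QA at or above threshold, length within range,
#' maximum turning angle within bound, and no vertex inside any exclusion
#' region.
#'
#' @param set a `streamline_set` (long data.frame: streamline_id,
#'   point_index, x, y, z, qa, optionally tract).
#' @param cfg a [filter_config()].
#' @return the surviving subset, same format.
#' @export
filter_streamlines <- function(set, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(set) == 0) return(set)
  keep_ids <- vapply(split_streamlines(set), function(pts) {
    pts <- as.matrix(pts)
    len <- streamline_length(pts)
    if (len < cfg$length_range[1] || len > cfg$length_range[2]) return(FALSE)
    if (nrow(pts) >= 3 && max_turning_angle(pts) > cfg$angle_max)
      return(FALSE)
    ex <- cfg$exclusion_regions
    if (!is.null(ex) && nrow(ex)) {
      for (i in seq_len(nrow(ex))) {
        d2 <- (pts[, 1] - ex$x[i])^2 + (pts[, 2] - ex$y[i])^2 +
          (pts[, 3] - ex$z[i])^2
        if (any(d2 <= ex$radius[i]^2)) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  qa_by_id <- tapply(set$qa, set$streamline_id, function(q) q[1])
  ok_ids <- names(keep_ids)[keep_ids &
                              qa_by_id[names(keep_ids)] >= cfg$qa_min]
  out <- set[as.character(set$streamline_id) %in% ok_ids, , drop = FALSE]
  class(out) <- class(set)
  out
}

#' ROI adjacency from streamline endpoints
#'
#' Two parcels are adjacent when at least one streamline has one endpoint
#' within `tolerance` mm of one parcel's sphere and its other endpoint within
#' the other's. Symmetric with a zero diagonal; optionally count-valued.
#'
#' @param set a (typically filtered) `streamline_set`.
#' @param parcels data.frame (label, x, y, z, radius), non-overlapping.
#' @param tolerance endpoint-to-parcel slack, mm (default 3).
#' @param counts return streamline counts instead of logicals.
#' @return labeled square matrix over the parcel labels.
#' @export
endpoint_adjacency <- function(set, parcels, tolerance = 3, counts = FALSE) {
  if (is.null(parcels) || nrow(parcels) == 0) stop("parcel map is empty")
  labels <- parcels$label
  adj <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
  assign_parcel <- function(pt) {
    d <- sqrt((parcels$x - pt[1])^2 + (parcels$y - pt[2])^2 +
                (parcels$z - pt[3])^2)
    inside <- which(d <= parcels$radius + tolerance)
    if (!length(inside)) return(NA_integer_)
    inside[which.min(d[inside])]
  }
  if (nrow(set)) for (pts in split_streamlines(set)) {
    pts <- as.matrix(pts)
    a <- assign_parcel(pts[1, ])
    b <- assign_parcel(pts[nrow(pts), ])
    if (is.na(a) || is.na(b) || a == b) next
    adj[a, b] <- adj[a, b] + 1L
    adj[b, a] <- adj[b, a] + 1L
  }
  if (counts) adj else adj > 0
}

#' Task-preferential connectivity edges
#'
#' The simultaneity-plus-adjacency rule: for each sliding window, an edge is
#' emitted for every adjacent region pair whose two regions both carry a
#' significant task effect of the same sign in that same window. The
#' preference direction follows the sign (positive coefficient =
#' Stroop-preferential under the Stroop = 1 coding).
#'
#' @param effects a [fdr_across_tests()] table (columns roi, window_start,
#'   coefficient, sign, and a significance flag).
#' @param adjacency labeled adjacency matrix from [endpoint_adjacency()];
#'   must cover every region in `effects`.
#' @param sig_col which flag gates an edge: `"q_significant"` (FDR, default)
#'   or a column of uncorrected flags.
#' @return data.frame of edges: roi_a, roi_b, window_start, preference,
#'   coefficient_a, coefficient_b; unordered pairs, each emitted once.
#' @export
task_preferential_edges <- function(effects, adjacency,
                                    sig_col = "q_significant") {
  rois <- unique(effects$roi)
  missing <- setdiff(rois, rownames(adjacency))
  if (length(missing))
    stop("region(s) absent from the adjacency vocabulary: ",
         paste(missing, collapse = ", "))
  sig <- effects[[sig_col]]
  if (is.null(sig)) stop("effects table lacks significance column '",
                         sig_col, "'")
  out <- list()
  for (w in sort(unique(effects$window_start))) {
    ew <- effects[effects$window_start == w & sig, ]
    if (nrow(ew) < 2) next
    for (i in seq_len(nrow(ew) - 1)) for (j in (i + 1):nrow(ew)) {
      a <- ew$roi[i]; b <- ew$roi[j]
      if (a == b) next
      if (!adjacency[a, b]) next
      if (ew$sign[i] != ew$sign[j]) next
      ord <- order(c(a, b))
      pair <- c(a, b)[ord]
      coefs <- c(ew$coefficient[i], ew$coefficient[j])[ord]
      out[[length(out) + 1]] <- data.frame(
        roi_a = pair[1], roi_b = pair[2], window_start = w,
        preference = if (ew$sign[i] > 0) "stroop" else "reading",
        coefficient_a = coefs[1], coefficient_b = coefs[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(roi_a = character(), roi_b = character(),
                      window_start = numeric(), preference = character(),
                      coefficient_a = numeric(), coefficient_b = numeric()))
  do.call(rbind, out)
}

#' Export a connectivity atlas
#'
#' Writes one TSV of edges per window plus a JSON timeline mapping window
#' starts to their edge lists; [read_atlas()] restores the edge table
#' losslessly.
#'
#' @param edges a [task_preferential_edges()] table.
#' @param path output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_atlas <- function(edges, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create atlas directory: ", path)
  windows <- sort(unique(edges$window_start))
  files <- character(0)
  for (w in windows) {
    f <- file.path(path, sprintf("edges_win_%+05d.tsv", w))
    write.table(edges[edges$window_start == w, ], f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  timeline <- lapply(windows, function(w) {
    ew <- edges[edges$window_start == w, ]
    list(window_start = w,
         edges = lapply(seq_len(nrow(ew)), function(i) as.list(ew[i, ])))
  })
  jf <- file.path(path, "timeline.json")
  jsonlite::write_json(timeline, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' Read back an exported atlas
#'
#' @param path directory written by [export_atlas()].
#' @return the edge table (zero rows for an empty atlas).
#' @export
read_atlas <- function(path) {
  jf <- file.path(path, "timeline.json")
  if (!file.exists(jf)) stop("no timeline.json under ", path)
  timeline <- jsonlite::read_json(jf)
  rows <- list()
  for (win in timeline) for (e in win$edges)
    rows[[length(rows) + 1]] <- as.data.frame(e, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(roi_a = character(), roi_b = character(),
                      window_start = numeric(), preference = character(),
                      coefficient_a = numeric(), coefficient_b = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$window_start, out$roi_a, out$roi_b), , drop = FALSE]
}
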