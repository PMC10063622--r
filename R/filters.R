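#' Detection-cleaning filter configuration
#'
#' Bundles the thresholds of the four post-detection filters applied before
#' any statistics:
#' \describe{
#'   \item{redundancy}{an insect cannot sit at exactly the same spot for
#'     most of the experiment; any rounded position (tolerance
#'     `redundancy_tol` px) that recurs in more than `redundancy_frac` of
#'     all frames is a static artifact (dust, glue) and all its detections
#'     are removed.}
#'   \item{area}{particle area must lie in `[area_min, area_max]` px^2.}
#'   \item{edge}{the perpendicular offset from the skeleton must not exceed
#'     `edge_max_frac` of the corridor half-width (removes wall shadows).}
#'   \item{circularity}{minimal circularity `circ_min` (removes streaks).}
#' }
#'
#' @param redundancy_tol position rounding tolerance (px).
#' @param redundancy_frac fraction of frames above which a recurring
#'   position is declared static.
#' @param area_min,area_max particle area bounds (px^2).
#' @param edge_max_frac maximal perpendicular offset, as a fraction of
#'   `path_width / 2`.
#' @param circ_min minimal circularity.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(redundancy_tol = 2, redundancy_frac = 0.5,
                          area_min = 2, area_max = 200,
                          edge_max_frac = 0.9, circ_min = 0.4) {
  stopifnot(redundancy_tol > 0, redundancy_frac > 0, redundancy_frac <= 1,
            area_min > 0, area_max >= area_min,
            edge_max_frac > 0, edge_max_frac <= 1, circ_min >= 0)
  structure(list(redundancy_tol = redundancy_tol,
                 redundancy_frac = redundancy_frac,
                 area_min = area_min, area_max = area_max,
                 edge_max_frac = edge_max_frac, circ_min = circ_min),
            class = "filter_config")
}

#' Apply the four cleaning filters to a detection table
#'
#' Each filter is a pure predicate on a detection row (the redundancy
#' predicate depends on the whole table), so the retained set does not
#' depend on the order of application; removal counts are reported for the
#' fixed order redundancy, area, edge, circularity (a detection failing
#' several filters is counted against the first).
#'
#' @param detections a detection table from [analyze_sequence()], with the
#'   projection columns `s_mm` and `perp_mm` already attached (e.g. via
#'   [project_to_path()]).
#' @param config a [filter_config()].
#' @param n_frames total number of frames in the experiment (for the
#'   redundancy fraction); default `max(detections$frame)`.
#' @param path_width corridor width (mm), for the edge filter.
#' @return a list: `detections` (the retained subset, all columns
#'   preserved, plus one logical `pass_*` column per filter), `removed`
#'   (named integer vector of removal counts in application order), and
#'   `n_kept`.
#' @export
apply_filters <- function(detections, config, n_frames = NULL,
                          path_width = 10) {
  stopifnot(inherits(config, "filter_config"),
            all(c("s_mm", "perp_mm", "area", "circularity", "frame") %in%
                  names(detections)))
  if (is.null(n_frames)) n_frames <- max(detections$frame, 1)
  key <- paste(round(detections$x / config$redundancy_tol),
               round(detections$y / config$redundancy_tol))
  frames_at <- tapply(detections$frame, key,
                      function(f) length(unique(f)))
  static <- names(frames_at)[frames_at > config$redundancy_frac * n_frames]
  pass_redundancy <- !(key %in% static)
  pass_area <- detections$area >= config$area_min &
    detections$area <= config$area_max
  pass_edge <- detections$perp_mm <= config$edge_max_frac * path_width / 2
  pass_circ <- detections$circularity >= config$circ_min
  removed <- c(
    redundancy = sum(!pass_redundancy),
    area = sum(pass_redundancy & !pass_area),
    edge = sum(pass_redundancy & pass_area & !pass_edge),
    circularity = sum(pass_redundancy & pass_area & pass_edge & !pass_circ)
  )
  keep <- pass_redundancy & pass_area & pass_edge & pass_circ
  out <- detections[keep, , drop = FALSE]
  out$pass_redundancy <- pass_redundancy[keep]
  out$pass_area <- pass_area[keep]
  out$pass_edge <- pass_edge[keep]
  out$pass_circularity <- pass_circ[keep]
  rownames(out) <- NULL
  list(detections = out, removed = removed, n_kept = sum(keep))
}
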