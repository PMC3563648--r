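# Scanpath and bisection analytics.

#' Bisection offsets in degrees and percent of line length
#'
#' Exact conversions of a bisection point against the true line centre:
#' positive offsets are rightward (ipsilesional for a left-field deficit).
#'
#' @param bisection_x scene x of the bisection point.
#' @param centre_x true line centre (scene px).
#' @param length_px line length (px).
#' @param px_per_deg pixels per degree.
#' @return named numeric `offset_deg`, `offset_pct`.
#' @export
bisection_error <- function(bisection_x, centre_x = 500, length_px = 495,
                            px_per_deg = 11) {
  c(offset_deg = (bisection_x - centre_x) / px_per_deg,
    offset_pct = 100 * (bisection_x - centre_x) / length_px)
}

#' Horizontal fixation-density histogram along the line
#'
#' Bins fixation x positions in 1-degree bins across the scene; fixations
#' farther than 1 degree from the line in the vertical direction are
#' excluded (and counted).
#'
#' @param trials list of `hemiscan_trial` (or a single trial).
#' @param line_y scene y of the line.
#' @param scene_width_px scene width.
#' @param px_per_deg pixels per degree.
#' @return list with `bin_edges` (degrees), `counts`, `n_excluded`.
#' @export
fixation_density <- function(trials, line_y = 500, scene_width_px = 1000,
                             px_per_deg = 11) {
  if (inherits(trials, "hemiscan_trial")) trials <- list(trials)
  xs <- unlist(lapply(trials, function(tr) tr$fixations$x))
  ys <- unlist(lapply(trials, function(tr) tr$fixations$y))
  keep <- abs(ys - line_y) <= px_per_deg
  n_excluded <- sum(!keep)
  edges <- seq(0, ceiling(scene_width_px / px_per_deg))
  b <- findInterval(xs[keep] / px_per_deg, edges, rightmost.closed = TRUE)
  counts <- tabulate(b, nbins = length(edges) - 1)
  list(bin_edges = edges, counts = counts, n_excluded = n_excluded)
}

#' Percentage of fixations near stimuli vs in blank regions
#'
#' A fixation is "near" a stimulus when it lies within `radius_px` of the
#' item's bounding box (closed boundary). The first fixation of each trial
#' is the imposed central starting position, not a saccade chosen by the
#' model, and is excluded by default.
#'
#' @param trial a `hemiscan_trial` (or list of them).
#' @param scene the search scene.
#' @param radius_px proximity radius (default 2 degrees).
#' @param drop_initial exclude each trial's imposed starting fixation.
#' @return named numeric `pct_near`, `pct_blank`.
#' @export
pct_fixations_on_stimuli <- function(trial, scene, radius_px = 22,
                                     drop_initial = TRUE) {
  trials <- if (inherits(trial, "hemiscan_trial")) list(trial) else trial
  boxes <- lapply(scene$items, item_bbox)
  near_one <- function(x, y) {
    for (bb in boxes) {
      dx <- max(bb[["x0"]] - x, 0, x - bb[["x1"]])
      dy <- max(bb[["y0"]] - y, 0, y - bb[["y1"]])
      if (dx^2 + dy^2 <= radius_px^2) return(TRUE)
    }
    FALSE
  }
  f <- do.call(rbind, lapply(trials, function(tr) {
    fx <- tr$fixations
    if (drop_initial && nrow(fx) > 1) fx <- fx[-1, , drop = FALSE]
    fx
  }))
  if (nrow(f) == 0) stop("no fixations")
  near <- mapply(near_one, f$x, f$y)
  c(pct_near = 100 * mean(near), pct_blank = 100 * mean(!near))
}

#' Did a line-task trial stray off the line?
#'
#' TRUE when any fixation lies more than 1 degree vertically off the line
#' (the same rule as the density histogram's exclusion).
#' @param trial a `hemiscan_trial`.
#' @param line_y scene y of the line.
#' @param px_per_deg pixels per degree.
#' @export
strays_off_line <- function(trial, line_y = 500, px_per_deg = 11) {
  any(abs(trial$fixations$y - line_y) > px_per_deg)
}
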