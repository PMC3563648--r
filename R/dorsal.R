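# Dorsal stream: a retinotopic parietal priority map integrating ventral
# feature evidence, scene novelty, and task/compensation biases; saccade
# targets are read out as the map's peak. Parietal lesions (step and
# gradient) are applied to the map after every integration step.

#' Initialise the parietal state
#'
#' @param params a [hemiscan_params()] list.
#' @return A `parietal_state`: activity matrix `P` (`par_n` x `par_n`,
#'   1 cell = 1 degree), resampling matrix from the extrastriate grid,
#'   elapsed time.
#' @export
parietal_init <- function(params = hemiscan_params()) {
  n <- params$par_n
  structure(list(
    P = matrix(0, n, n),
    A = resample_matrix(33L, n),
    params = params,
    t_ms = 0
  ), class = "parietal_state")
}

#' Feedforward drive to the parietal map
#'
#' Resamples the extrastriate feature maps onto the parietal grid and sums
#' them, weighted by the current feature-feedback vector (so during search
#' the remembered target's features dominate the priority landscape).
#'
#' @param state a `parietal_state`.
#' @param ex list of extrastriate maps (`h`, `v`, `red`, `green`).
#' @param feature_bias named numeric from [it_feature_feedback()], or NULL
#'   for unweighted summation (free viewing / bisection).
#' @return matrix on the parietal grid.
#' @export
parietal_drive <- function(state, ex, feature_bias = NULL) {
  A <- state$A
  out <- matrix(0, nrow(A), nrow(A))
  for (k in names(ex)) {
    w <- 1
    if (!is.null(feature_bias) && k %in% names(feature_bias))
      w <- max(0, 1 + feature_bias[[k]])
    if (w > 0) out <- out + w * (A %*% ex[[k]] %*% t(A))
  }
  out
}

#' Apply a unilateral parietal lesion to an activity map
#'
#' `step`: activity in the affected hemifield is zeroed. `gradient`:
#' activity is scaled by a linear impairment ramp running from
#' `gradient_floor` at the far periphery of the affected field to 1 at the
#' vertical meridian (the intact field is untouched). Idempotent for the
#' step profile; the gradient is re-applied each integration step as part
#' of the dynamics.
#'
#' @param P parietal activity matrix.
#' @param lesion a [lesion_spec()] with `site = "parietal"`, or NULL.
#' @return the lesioned matrix.
#' @export
apply_parietal_lesion <- function(P, lesion) {
  if (is.null(lesion)) return(P)
  if (!inherits(lesion, "lesion_spec") || lesion$site != "parietal")
    stop("lesion site must be 'parietal'")
  n <- ncol(P)
  cols <- hemifield_cols(n, lesion$side)
  if (lesion$profile == "step") {
    P[, cols] <- 0
  } else {
    half <- length(cols)
    ramp <- seq(lesion$gradient_floor, 1, length.out = half + 1L)[-(half + 1L)]
    if (lesion$side == "right_field") ramp <- rev(ramp)[seq_along(cols)]
    P[, cols] <- sweep(P[, cols, drop = FALSE], 2, ramp, `*`)
  }
  P
}

#' Contralesional spatial-compensation bias field
#'
#' A leftward (or rightward) linear ramp added to the parietal input,
#' modelling a strategic bias of attention toward the blind/neglected side.
#' Zero weight returns an all-zero field.
#'
#' @param n parietal grid side.
#' @param side side favoured by the bias (`"left_field"` typically).
#' @param weight peak bias at the favoured edge.
#' @return an `n` x `n` matrix.
#' @export
spatial_compensation_field <- function(n, side = "left_field", weight = 1) {
  if (weight < 0) stop("compensation weight must be nonnegative")
  ramp <- seq(1, 0, length.out = n)
  if (side == "right_field") ramp <- rev(ramp)
  matrix(weight * ramp, n, n, byrow = TRUE)
}

#' Bisection-task midpoint bias field
#'
#' Circular Gaussian added to the parietal input during line bisection,
#' centred on the running estimate of the line midpoint (the fovea before
#' any estimates exist); it draws fixation toward the estimated midpoint.
#'
#' @param n parietal grid side.
#' @param weight peak amplitude (the task's bisection weight).
#' @param sigma width in parietal cells (degrees).
#' @param centre `c(col, row)` of the Gaussian peak in grid cells (may be
#'   fractional or outside the grid); default is the map centre.
#' @return an `n` x `n` matrix.
#' @export
bisection_bias_field <- function(n, weight = 1, sigma = 12, centre = NULL) {
  if (is.null(centre)) centre <- c((n + 1) / 2, (n + 1) / 2)
  d2 <- outer((seq_len(n) - centre[2])^2, (seq_len(n) - centre[1])^2, `+`)
  weight * exp(-d2 / (2 * sigma^2))
}

#' One Euler step of the parietal priority map
#'
#' Leaky-integrator update of the priority map from the (novelty-weighted)
#' feedforward drive plus any static bias fields, with a global inhibitory
#' pool and additive Gaussian noise; the parietal lesion (if any) is
#' applied to the updated activity, so step lesions silence their hemifield
#' at every instant and gradient lesions chronically attenuate it.
#'
#' @param state a `parietal_state`.
#' @param drive matrix from [parietal_drive()] (NULL before onset).
#' @param novelty matrix of per-cell novelty factors in [0, 1] (1 = never
#'   inspected), or NULL for uniform novelty. Novelty multiplies the
#'   stimulus drive and the compensation bias (inspected locations lose
#'   their pull), but not the task bias.
#' @param comp_bias spatial-compensation bias field, or NULL.
#' @param task_bias bisection (midpoint) bias field, or NULL.
#' @param lesion a parietal [lesion_spec()] or NULL.
#' @param dt time step, ms.
#' @param noise add the per-step Gaussian noise (disable for the pure
#'   stimulus-representation map).
#' @return the updated `parietal_state`.
#' @export
parietal_step <- function(state, drive, novelty = NULL, comp_bias = NULL,
                          task_bias = NULL, lesion = NULL, dt = NULL,
                          noise = TRUE) {
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  P <- state$P
  inp <- if (is.null(drive)) 0 else p$par_drive_gain * drive
  if (!is.null(comp_bias)) inp <- inp + comp_bias
  if (!is.null(novelty)) inp <- inp * novelty
  if (!is.null(task_bias)) inp <- inp + task_bias
  if (noise) inp <- inp + matrix(stats::rnorm(length(P), 0, p$noise_sd),
                                 nrow(P))
  P <- P + (dt / p$tau_par) * (-P + inp - p$par_inh * mean(P))
  P[P < 0] <- 0
  P <- apply_parietal_lesion(P, lesion)
  state$P <- P
  state$t_ms <- state$t_ms + dt
  state
}

#' Scene coordinates of parietal receptive-field centres
#'
#' @param state a `parietal_state` (or integer grid side).
#' @param fixation scene `c(x, y)` of the current fixation.
#' @return list with vectors `x` (per column) and `y` (per row), scene px.
#' @export
parietal_rf_centres <- function(state, fixation) {
  p <- if (inherits(state, "parietal_state")) state$params else hemiscan_params()
  n <- if (inherits(state, "parietal_state")) nrow(state$P) else state
  c0 <- (n + 1) / 2
  cell <- p$px_per_deg
  list(x = fixation[1] + (seq_len(n) - c0) * cell,
       y = fixation[2] + (seq_len(n) - c0) * cell)
}

#' Select the next saccade target
#'
#' The saccade lands on the receptive-field centre of the most active
#' parietal cell, clipped to the scene. Returns NULL when the map carries
#' no suprathreshold activity (no candidate target).
#'
#' @param state a `parietal_state`.
#' @param fixation current scene fixation `c(x, y)`.
#' @param scene_size `c(width, height)` px for clipping.
#' @param floor minimum peak activity for a valid target.
#' @return scene `c(x, y)` or NULL.
#' @export
select_saccade_target <- function(state, fixation,
                                  scene_size = c(1000L, 1000L),
                                  floor = 1e-6) {
  P <- state$P
  if (max(P) <= floor) return(NULL)
  ij <- which(P == max(P), arr.ind = TRUE)[1, ]
  ctr <- parietal_rf_centres(state, fixation)
  x <- min(max(ctr$x[ij[2]], 0), scene_size[1] - 1)
  y <- min(max(ctr$y[ij[1]], 0), scene_size[2] - 1)
  c(x, y)
}

#' Per-cell novelty factors for the current fixation
#'
#' Novelty starts at 1 everywhere in the scene and is multiplied by the
#' inhibition-of-return factor within a disc around each previously
#' fixated location; this routine samples that scene-level memory at the
#' parietal receptive-field centres.
#'
#' @param state a `parietal_state`.
#' @param fixation current scene fixation `c(x, y)`.
#' @param history matrix (or data.frame) of previous fixations, columns x, y.
#' @return matrix of factors in (0, 1] on the parietal grid.
#' @export
novelty_field <- function(state, fixation, history = NULL) {
  p <- state$params
  n <- nrow(state$P)
  out <- matrix(1, n, n)
  if (is.null(history) || NROW(history) == 0) return(out)
  ctr <- parietal_rf_centres(state, fixation)
  hx <- history[, 1]; hy <- history[, 2]
  for (k in seq_along(hx)) {
    d2 <- outer((ctr$y - hy[k])^2, (ctr$x - hx[k])^2, `+`)
    out[d2 <= p$ior_radius_px^2] <- out[d2 <= p$ior_radius_px^2] * p$ior_factor
  }
  out
}

#' Suprathreshold horizontal extent of parietal line activity
#'
#' Scene x-coordinates of the outer receptive-field edges of the leftmost
#' and rightmost parietal columns whose activity (within the line's row
#' band) exceeds a fraction of the current map maximum. Parietal receptive
#' fields are large (several degrees across, `extent_rf_px`), so an active
#' cell signals stimulus presence out to its field boundary, not just at
#' its centre. Used by the bisection ledger when no endstop is visible on
#' a side: cortically represented extent then stands in for the line end.
#'
#' @param state a `parietal_state`.
#' @param fixation current scene fixation `c(x, y)`.
#' @param line_y scene y of the line (to restrict the row band), or NULL
#'   for the full map.
#' @param map activity matrix to threshold instead of the priority map
#'   (e.g. the lesion-filtered stimulus drive, free of novelty and noise).
#' @return list with `left`, `right` scene x (NA when nothing is
#'   suprathreshold) and the column indices.
#' @export
parietal_extent <- function(state, fixation, line_y = NULL, map = NULL) {
  p <- state$params
  P <- if (is.null(map)) state$P else map
  n <- nrow(P)
  ctr <- parietal_rf_centres(state, fixation)
  rows <- seq_len(n)
  if (!is.null(line_y)) rows <- which(abs(ctr$y - line_y) <= p$px_per_deg)
  if (length(rows) == 0)
    return(list(left = NA_real_, right = NA_real_,
                cols = integer(0)))
  if (max(P) <= 1e-9)
    return(list(left = NA_real_, right = NA_real_, cols = integer(0)))
  prof <- apply(P[rows, , drop = FALSE], 2, max)
  th <- p$extent_threshold * max(P)
  cols <- which(prof >= th & prof > 0)
  # a single active column is a point, not an extent: it cannot supply
  # two line-end estimates
  if (length(cols) < 2)
    return(list(left = NA_real_, right = NA_real_, cols = cols))
  list(left = ctr$x[min(cols)] - p$extent_rf_px,
       right = ctr$x[max(cols)] + p$extent_rf_px, cols = cols)
}
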