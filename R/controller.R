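# Trial engine: the fixation loop coupling early vision, ventral and
# dorsal dynamics; saccade triggering; the line-end-estimate ledger; and
# the bisection decision.

#' Configure a trial
#'
#' @param task `"search"`, `"free_view"` or `"bisection"`.
#' @param lesion a [lesion_spec()] or NULL.
#' @param compensation `"none"`, `"spatial"`, `"lateral"` or `"both"`.
#' @param bisection_weight peak of the midpoint bias (bisection task only).
#' @param seed integer; fully determines the trial.
#' @param endstop_only if TRUE the ledger records only endstop-provenance
#'   estimates (cortical-extent fallback disabled) — the ablation used to
#'   show that endstop evidence alone bisects near centre.
#' @param params a [hemiscan_params()] list.
#' @return A `trial_config` list.
#' @export
trial_config <- function(task = c("bisection", "free_view", "search"),
                         lesion = NULL,
                         compensation = c("none", "spatial", "lateral", "both"),
                         bisection_weight = 0,
                         seed = 1L,
                         endstop_only = FALSE,
                         params = hemiscan_params()) {
  task <- match.arg(task)
  compensation <- match.arg(compensation)
  if (bisection_weight < 0) stop("bisection_weight must be nonnegative")
  if (bisection_weight > 0 && task != "bisection")
    stop("bisection_weight > 0 requires task = 'bisection'")
  if (!is.null(lesion) && !inherits(lesion, "lesion_spec"))
    stop("lesion must be a lesion_spec or NULL")
  structure(list(task = task, lesion = lesion, compensation = compensation,
                 bisection_weight = bisection_weight, seed = as.integer(seed),
                 endstop_only = endstop_only, params = params),
            class = "trial_config")
}

#' Saccade trigger decision
#'
#' A saccade is triggered once the competition between object identities in
#' the ventral stream is resolved: the leading IT unit exceeds the
#' runner-up by the resolution margin (and a small absolute floor), after a
#' minimum fixation time. With no resolvable competition (blank view,
#' perfectly tied objects) the saccade is forced at the fixation deadline.
#'
#' @param ventral a `ventral_state`.
#' @param elapsed_ms time since fixation onset.
#' @param max_fixation_ms forced-saccade deadline.
#' @param params a [hemiscan_params()] list.
#' @return logical.
#' @export
trigger_saccade <- function(ventral, elapsed_ms, max_fixation_ms = NULL,
                            params = hemiscan_params()) {
  if (is.null(max_fixation_ms)) max_fixation_ms <- params$max_fixation_ms
  if (elapsed_ms >= max_fixation_ms) return(TRUE)
  if (elapsed_ms < params$min_fixation_ms) return(FALSE)
  u <- ventral$it
  if (length(u) == 0) return(FALSE)
  lead <- max(u)
  runner <- if (length(u) > 1) sort(u, decreasing = TRUE)[2] else 0
  lead >= 0.1 && lead >= params$trigger_margin * runner
}

#' Record line-end estimates for the current fixation
#'
#' Per side: if an endstopped-cell response is visible in the current view
#' it supplies the estimate (provenance `"endstop"`); otherwise the
#' furthest suprathreshold extent of parietal activity on that side does
#' (provenance `"cortical_extent"`). Either kind of estimate counts only
#' where the parietal map itself is suprathreshold — an unattended line end
#' (silenced or attenuated by a parietal lesion) is not registered.
#'
#' @param ends output of [detect_endstops()] for this fixation.
#' @param parietal a `parietal_state` at fixation end.
#' @param fixation scene `c(x, y)`.
#' @param ledger data.frame ledger so far (may be empty/NULL).
#' @param fix_index fixation number for bookkeeping.
#' @param line_y scene y of the line.
#' @param endstop_only disable the cortical-extent fallback.
#' @param rep_map lesion-filtered stimulus representation on the parietal
#'   grid (novelty- and noise-free); defaults to the priority map.
#' @return the extended ledger data.frame with columns
#'   `fix`, `side`, `x`, `provenance`.
#' @export
record_line_end_estimates <- function(ends, parietal, fixation,
                                      ledger = NULL, fix_index = 1L,
                                      line_y = NULL, endstop_only = FALSE,
                                      rep_map = NULL) {
  p <- parietal$params
  if (is.null(ledger))
    ledger <- data.frame(fix = integer(0), side = character(0),
                         x = numeric(0), provenance = character(0),
                         stringsAsFactors = FALSE)
  P <- if (is.null(rep_map)) parietal$P else rep_map
  n <- nrow(P)
  mx <- max(P)
  if (mx <= 1e-9) return(ledger)
  th <- p$extent_threshold * mx
  ctr <- parietal_rf_centres(parietal, fixation)
  attended <- function(x_scene) {
    j <- which.min(abs(ctr$x - x_scene))
    i <- if (is.null(line_y)) which.max(P[, j]) else
      which.min(abs(ctr$y - line_y))
    P[i, j] >= th
  }
  ext <- parietal_extent(parietal, fixation, line_y, map = P)
  for (side in c("left", "right")) {
    hit <- ends$hits[ends$hits$side == side, , drop = FALSE]
    est <- NULL
    if (nrow(hit) > 0) {
      # outermost endstop on that side
      x <- if (side == "left") min(hit$x) else max(hit$x)
      # the endstop-only ablation probes the veridical endstop signal
      # directly, bypassing attentional registration
      if (endstop_only || attended(x)) est <- list(x = x, prov = "endstop")
    }
    if (is.null(est) && !endstop_only) {
      x <- if (side == "left") ext$left else ext$right
      if (!is.na(x)) est <- list(x = x, prov = "cortical_extent")
    }
    if (!is.null(est))
      ledger <- rbind(ledger, data.frame(
        fix = fix_index, side = side, x = est$x, provenance = est$prov,
        stringsAsFactors = FALSE))
  }
  ledger
}

#' Running midpoint of a ledger
#' @param ledger ledger data.frame.
#' @return scene x, or NA when either side is still empty.
#' @export
ledger_midpoint <- function(ledger) {
  if (is.null(ledger) || nrow(ledger) == 0) return(NA_real_)
  l <- ledger$x[ledger$side == "left"]
  r <- ledger$x[ledger$side == "right"]
  if (length(l) == 0 || length(r) == 0) return(NA_real_)
  (mean(l) + mean(r)) / 2
}

#' Bisection decision from a completed ledger
#'
#' The line is bisected at the midpoint of the mean left and mean right
#' line-end estimates accumulated over the trial's fixations.
#'
#' @param ledger ledger data.frame.
#' @param centre_x true line centre (scene px).
#' @param length_px true line length (px).
#' @param px_per_deg pixels per degree.
#' @return list with `bisection_x`, `offset_deg`, `offset_pct`.
#' @export
compute_bisection_point <- function(ledger, centre_x = 500,
                                    length_px = 495, px_per_deg = 11) {
  l <- ledger$x[ledger$side == "left"]
  r <- ledger$x[ledger$side == "right"]
  if (length(l) == 0 || length(r) == 0)
    stop("insufficient evidence: no line-end estimates on one side")
  x <- (mean(l) + mean(r)) / 2
  e <- bisection_error(x, centre_x = centre_x, length_px = length_px,
                       px_per_deg = px_per_deg)
  list(bisection_x = x, offset_deg = e[["offset_deg"]],
       offset_pct = e[["offset_pct"]])
}

# conjunction-search object inventory and frontal cue for a scene
scene_objects <- function(scene) {
  items <- scene$items
  if (length(items) == 0) return(list(objects = character(0), cue = NULL))
  objs <- unique(vapply(items, function(it)
    paste(it$colour, it$orientation, sep = "_"), character(1)))
  tgt <- Filter(function(it) isTRUE(it$is_target), items)
  cue <- if (length(tgt)) paste(tgt[[1]]$colour, tgt[[1]]$orientation,
                                sep = "_") else NULL
  list(objects = objs, cue = cue)
}

#' Run one trial of the model
#'
#' Seeded fixation loop: per fixation the retinal view is processed through
#' retina/V1 (with any V1 lesion), the coupled ventral and parietal
#' dynamics are integrated in time until a saccade is triggered, line-end
#' estimates are recorded (bisection task), the next fixation is the
#' priority-map peak, and the inspected location loses novelty. The first
#' fixation is the scene centre.
#'
#' @param scene a `hemiscan_scene`.
#' @param config a [trial_config()].
#' @return A `hemiscan_trial`: list with `fixations` (data.frame x, y,
#'   onset_ms, duration_ms), `bisection` (list or NULL), `ledger`,
#'   `found_target`, `config`.
#' @export
run_trial <- function(scene, config) {
  stopifnot(inherits(scene, "hemiscan_scene"), inherits(config, "trial_config"))
  p <- config$params
  with_seed(config$seed, run_trial_impl(scene, config, p))
}

run_trial_impl <- function(scene, config, p) {
  task <- config$task
  line_task <- task %in% c("bisection", "free_view")
  v1_les <- if (!is.null(config$lesion) && config$lesion$site == "v1")
    config$lesion else NULL
  par_les <- if (!is.null(config$lesion) && config$lesion$site == "parietal")
    config$lesion else NULL
  comp_side <- if (!is.null(config$lesion)) config$lesion$side else "left_field"
  use_spatial <- config$compensation %in% c("spatial", "both")
  use_lateral <- config$compensation %in% c("lateral", "both")
  lat_facing <- if (comp_side == "left_field") "rightward" else "leftward"

  max_fix <- if (line_task) p$max_fixations_line else p$max_fixations_search
  scene_size <- c(scene$width_px, scene$height_px)
  line_y <- if (line_task) scene$items[[1]]$y else NULL

  so <- if (task == "search") scene_objects(scene) else
    list(objects = "green_horizontal", cue = NULL)
  frontal <- if (!is.null(so$cue)) stats::setNames(1, so$cue) else NULL

  n_par <- p$par_n
  # comp_gain converts the search-task bias weight from salience units
  # (stimulus ~ 1) to parietal input units (stimulus drive ~ par_drive_gain);
  # the line-task weight is already expressed in input units
  comp_field <- if (use_spatial) {
    w <- if (line_task) p$comp_weight_line else
      p$comp_weight_search * p$comp_gain
    spatial_compensation_field(n_par, comp_side, w)
  } else NULL

  target_item <- NULL
  if (task == "search") {
    tg <- Filter(function(it) isTRUE(it$is_target), scene$items)
    if (length(tg)) target_item <- tg[[1]]
  }

  fixation <- c(floor(scene$width_px / 2), floor(scene$height_px / 2))
  history <- matrix(numeric(0), ncol = 2)
  fixrec <- data.frame(x = numeric(0), y = numeric(0),
                       onset_ms = numeric(0), duration_ms = numeric(0))
  ledger <- NULL
  clock <- 0
  found <- FALSE

  for (fi in seq_len(max_fix)) {
    view <- extract_retinal_view(scene, fixation, p$retina_px)
    stack <- v1_response(retina_response(view, p), p)
    if (!is.null(v1_les)) stack <- apply_v1_lesion(stack, v1_les)
    ends <- detect_endstops(stack, params = p)
    if (!is.null(v1_les)) {
      # a deafferented hemifield truncates the line at the vertical
      # meridian; termination responses at the scotoma border are artifacts
      # of the lesion, not stimulus ends, and are discounted (otherwise no
      # completion across the border could ever be perceived)
      bs <- if (v1_les$side == "left_field") "left" else "right"
      keep <- !(ends$hits$side == bs &
                  abs(ends$hits$x - fixation[1]) <= p$scotoma_margin_px)
      ends$hits <- ends$hits[keep, , drop = FALSE]
    }

    # endstop gating: a visible line end on the blind side's flank stops
    # the lateral relay from extending the line past a seen termination
    gate_side <- if (comp_side == "left_field") "left" else "right"
    lat_w <- if (use_lateral &&
                 !any(ends$hits$side == gate_side)) p$lat_weight else 0

    vin <- ex_input(stack, p)
    vst <- ventral_init(nrow(vin$h), objects = so$objects, params = p,
                        lat_weight = lat_w, facing = lat_facing)
    pst <- parietal_init(p)
    # noiseless, bias-free companion map: the parietal representation of
    # the stimulus itself, used by the line-end ledger; integrating it
    # under the same per-step lesion lets a gradient lesion compound
    pst_rep <- pst
    history_now <- rbind(history, fixation)
    novelty <- novelty_field(pst, fixation, history_now)

    mid <- ledger_midpoint(ledger)
    task_bias <- NULL
    if (task == "bisection" && config$bisection_weight > 0) {
      centre_col <- if (is.na(mid)) (n_par + 1) / 2 else
        (mid - fixation[1]) / p$px_per_deg + (n_par + 1) / 2
      centre_row <- if (is.null(line_y)) (n_par + 1) / 2 else
        (line_y - fixation[2]) / p$px_per_deg + (n_par + 1) / 2
      task_bias <- bisection_bias_field(n_par, config$bisection_weight,
                                        p$bis_sigma,
                                        centre = c(centre_col, centre_row))
    }

    elapsed <- 0
    fb <- NULL
    drive <- NULL
    repeat {
      inp <- if (vst$t_ms >= p$onset_ms) vin else NULL
      vst <- extrastriate_step(vst, inp, it_feedback = fb)
      vst <- it_step(vst, frontal_bias = frontal)
      fb <- it_feature_feedback(vst, cue = so$cue)
      if (!is.null(inp)) drive <- parietal_drive(pst, vst$ex, fb)
      pst <- parietal_step(pst, drive, novelty = novelty,
                           comp_bias = comp_field, task_bias = task_bias,
                           lesion = par_les)
      if (task == "bisection")
        pst_rep <- parietal_step(pst_rep, drive, lesion = par_les,
                                 noise = FALSE)
      elapsed <- elapsed + p$dt
      if (trigger_saccade(vst, elapsed, p$max_fixation_ms, p)) break
    }
    rep_map <- pst_rep$P

    fixrec <- rbind(fixrec, data.frame(x = fixation[1], y = fixation[2],
                                       onset_ms = clock,
                                       duration_ms = elapsed))
    clock <- clock + elapsed
    history <- history_now

    if (task == "bisection") {
      ledger <- record_line_end_estimates(ends, pst, fixation, ledger,
                                          fix_index = fi, line_y = line_y,
                                          endstop_only = config$endstop_only,
                                          rep_map = rep_map)
    }

    if (!is.null(target_item)) {
      bb <- item_bbox(target_item)
      dx <- max(bb["x0"] - fixation[1], 0, fixation[1] - bb["x1"])
      dy <- max(bb["y0"] - fixation[2], 0, fixation[2] - bb["y1"])
      if (sqrt(dx^2 + dy^2) <= p$ior_radius_px) {
        found <- TRUE
        break
      }
    }

    nxt <- select_saccade_target(pst, fixation, scene_size)
    if (is.null(nxt)) break
    fixation <- round(nxt)
  }

  bis <- NULL
  if (task == "bisection" && !is.null(ledger) && nrow(ledger) > 0) {
    l_ok <- any(ledger$side == "left"); r_ok <- any(ledger$side == "right")
    if (l_ok && r_ok)
      bis <- compute_bisection_point(
        ledger,
        centre_x = scene$items[[1]]$x,
        length_px = scene$items[[1]]$length_px,
        px_per_deg = scene$px_per_deg)
  }

  structure(list(fixations = fixrec, bisection = bis, ledger = ledger,
                 found_target = found, config = config),
            class = "hemiscan_trial")
}

#' Run a batch of seeded trials
#'
#' @param scene a scene, or a function(seed) returning one (fresh scene per
#'   trial, as in the search experiments).
#' @param config_fn function(seed) returning a [trial_config()].
#' @param n_trials number of trials.
#' @param base_seed first seed; trial i uses `base_seed + i - 1`.
#' @return list of `hemiscan_trial`.
#' @export
run_trials <- function(scene, config_fn, n_trials = 10L, base_seed = 1L) {
  lapply(seq_len(n_trials), function(i) {
    seed <- base_seed + i - 1L
    sc <- if (is.function(scene)) scene(seed) else scene
    run_trial(sc, config_fn(seed))
  })
}

#' @export
print.hemiscan_trial <- function(x, ...) {
  cat(sprintf("<hemiscan_trial> task=%s fixations=%d%s\n",
              x$config$task, nrow(x$fixations),
              if (!is.null(x$bisection))
                sprintf(" bisection_x=%.1f (%.1f deg)",
                        x$bisection$bisection_x, x$bisection$offset_deg)
              else if (x$found_target) " target found" else ""))
  invisible(x)
}

#' @export
summary.hemiscan_trial <- function(object, ...) {
  f <- object$fixations
  out <- list(task = object$config$task,
              n_fixations = nrow(f),
              mean_duration_ms = mean(f$duration_ms),
              x_range = range(f$x), y_range = range(f$y),
              bisection = object$bisection,
              found_target = object$found_target)
  class(out) <- "summary.hemiscan_trial"
  out
}

#' @export
print.summary.hemiscan_trial <- function(x, ...) {
  cat(sprintf("Trial (%s): %d fixations, mean duration %.0f ms\n",
              x$task, x$n_fixations, x$mean_duration_ms))
  cat(sprintf("  x range [%g, %g], y range [%g, %g]\n",
              x$x_range[1], x$x_range[2], x$y_range[1], x$y_range[2]))
  if (!is.null(x$bisection))
    cat(sprintf("  bisection x = %.1f (%.2f deg, %.1f%% of line)\n",
                x$bisection$bisection_x, x$bisection$offset_deg,
                x$bisection$offset_pct))
  if (isTRUE(x$found_target)) cat("  target found\n")
  invisible(x)
}

#' Plot a trial scanpath
#'
#' Draws the scene items and the fixation sequence.
#' @param x a `hemiscan_trial`.
#' @param scene the scene the trial ran on (items are drawn when given).
#' @param ... passed to [graphics::plot()].
#' @export
plot.hemiscan_trial <- function(x, scene = NULL, ...) {
  f <- x$fixations
  graphics::plot(NA, xlim = c(0, 1000), ylim = c(1000, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)",
                 main = sprintf("Scanpath (%s)", x$config$task), ...)
  if (!is.null(scene)) {
    for (it in scene$items) {
      bb <- item_bbox(it)
      graphics::rect(bb["x0"], bb["y1"], bb["x1"], bb["y0"],
                     col = it$colour, border = NA)
    }
  }
  graphics::lines(f$x, f$y, col = "grey40")
  graphics::points(f$x, f$y, pch = 19, cex = 0.8)
  graphics::points(f$x[1], f$y[1], pch = 1, cex = 2)
  if (!is.null(x$bisection))
    graphics::abline(v = x$bisection$bisection_x, lty = 2)
  invisible(x)
}

#' Write scanpaths to CSV
#' @param trials list of `hemiscan_trial`.
#' @param path output file.
#' @export
write_scanpaths_csv <- function(trials, path) {
  rows <- do.call(rbind, lapply(seq_along(trials), function(i) {
    f <- trials[[i]]$fixations
    cbind(trial_id = i, fix_index = seq_len(nrow(f)),
          x_px = f$x, y_px = f$y, onset_ms = f$onset_ms,
          duration_ms = f$duration_ms)
  }))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Write bisection results to CSV
#' @param trials list of `hemiscan_trial`.
#' @param path output file.
#' @export
write_bisections_csv <- function(trials, path) {
  rows <- do.call(rbind, lapply(seq_along(trials), function(i) {
    b <- trials[[i]]$bisection
    if (is.null(b)) return(NULL)
    data.frame(trial_id = i, bisection_x = b$bisection_x,
               offset_deg = b$offset_deg, offset_pct = b$offset_pct)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
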