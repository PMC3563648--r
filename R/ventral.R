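# Ventral stream: V4-like extrastriate feature maps under biased
# competition, optional collinear lateral connectivity (the form-completion
# compensation), and object competition in IT under a frontal search bias.

#' Collinear lateral-connectivity kernel
#'
#' Half elliptical Gaussian giving the weights of lateral inputs gathered by
#' a horizontally tuned extrastriate cell from its neighbours. The kernel is
#' oriented along the axis of preferred orientation (`theta = 0`:
#' horizontal); only the half facing the intact hemifield is retained, so
#' activity is drawn from the good toward the blind field. With the default
#' parameters (`sigma = 9`, `delta = 0.5`) the cropped grid is 4 rows x 10
#' columns with peak weight 1 at the reference cell.
#'
#' @param theta axis orientation in radians (only 0 is used by the model).
#' @param sigma width along the long axis (grid cells).
#' @param delta width perpendicular to the long axis (grid cells).
#' @param facing `"rightward"` (gathers from the right; compensates a left
#'   hemianopia) or `"leftward"` (mirror).
#' @param floor amplitude below which weights are cropped to zero.
#' @return A `lateral_kernel` object: list with `weights` (rows = vertical
#'   offsets, attribute `offsets` giving the (dy, dx) of each cell),
#'   `row_offsets`, `col_offsets`, `facing` and the parameters.
#' @export
lateral_kernel <- function(theta = 0, sigma = 9, delta = 0.5,
                           facing = c("rightward", "leftward"),
                           floor = 0.004) {
  facing <- match.arg(facing)
  if (sigma <= 0 || delta <= 0) stop("sigma and delta must be positive")
  # support along each axis where the marginal weight clears the floor
  xmax <- base::floor(sqrt(-2 * sigma * log(floor)))
  ymax <- base::floor(sqrt(-2 * delta * log(floor)))
  dx <- 0:xmax
  # even-sized row band matching the reference rendering of the kernel
  dy <- (-ymax):(ymax - 1)
  xr <- outer(rep(1, length(dy)), dx)
  yr <- outer(dy, rep(1, length(dx)))
  if (theta != 0) {
    xo <- xr * cos(theta) + yr * sin(theta)
    yo <- -xr * sin(theta) + yr * cos(theta)
  } else {
    xo <- xr; yo <- yr
  }
  w <- exp(-(xo^2 / (2 * sigma) + yo^2 / (2 * delta)))
  w[w < floor] <- 0
  keep_r <- apply(w, 1, max) > 0
  keep_c <- apply(w, 2, max) > 0
  w <- w[keep_r, keep_c, drop = FALSE]
  dy <- dy[keep_r]; dx <- dx[keep_c]
  if (facing == "leftward") {
    w <- w[, rev(seq_along(dx)), drop = FALSE]
    dx <- rev(-dx)
  }
  structure(list(weights = w, row_offsets = dy, col_offsets = dx,
                 theta = theta, sigma = sigma, delta = delta,
                 facing = facing),
            class = "lateral_kernel")
}

# band matrices implementing y <- sum_k w[k] x[i + off[k]] as R %*% x
band_matrix <- function(n, offsets, weights) {
  A <- matrix(0, n, n)
  for (k in seq_along(offsets)) {
    src <- seq_len(n) + offsets[k]
    ok <- src >= 1 & src <= n
    A[cbind(which(ok), src[ok])] <- A[cbind(which(ok), src[ok])] + weights[k]
  }
  A
}

#' Pool V1 maps to the extrastriate grid
#'
#' Extrastriate receptive fields are larger than V1's: each map is the mean
#' of the two V1 scales, block-pooled by the extrastriate pooling factor.
#'
#' @param stack a `hemiscan_v1` stack.
#' @param params a [hemiscan_params()] list.
#' @return list of matrices `h`, `v`, `red`, `green` on the extrastriate grid.
#' @export
ex_input <- function(stack, params = hemiscan_params()) {
  f <- params$ex_pool
  out <- list()
  for (k in c("h", "v", "red", "green")) {
    out[[k]] <- block_mean((stack$maps$r1[[k]] + stack$maps$r2[[k]]) / 2, f)
  }
  out
}

#' Initialise the ventral state
#'
#' @param n extrastriate grid side.
#' @param objects character vector of object identities known to IT
#'   (e.g. `"red_vertical"`).
#' @param params a [hemiscan_params()] list.
#' @param lat_weight weight of collinear lateral inputs (0 disables).
#' @param facing facing of the lateral kernel.
#' @return A `ventral_state`.
#' @export
ventral_init <- function(n = 33L, objects = character(0),
                         params = hemiscan_params(),
                         lat_weight = 0, facing = "rightward") {
  z <- matrix(0, n, n)
  kern <- lateral_kernel(0, params$lat_sigma, params$lat_delta, facing)
  w <- kern$weights / sum(kern$weights)
  rowprof <- apply(w, 1, max); rowprof <- rowprof / sum(rowprof)
  colprof <- apply(w, 2, max); colprof <- colprof / sum(colprof)
  structure(list(
    ex = list(h = z, v = z, red = z, green = z),
    it = stats::setNames(numeric(length(objects)), objects),
    lat_weight = lat_weight,
    lat_R = band_matrix(n, kern$row_offsets, rowprof),
    lat_C = t(band_matrix(n, kern$col_offsets, colprof)),
    params = params,
    t_ms = 0
  ), class = "ventral_state")
}

#' One Euler step of the extrastriate module
#'
#' Leaky-integrator update combining feedforward V1 drive, object-based
#' feedback from IT (a gain that enhances the drive to target features and
#' suppresses the others -- feedback modulates stimulus-driven activity,
#' it does not create activity on its own), within-dimension competition
#' between feature values at each location, and -- for horizontally
#' selective cells only -- collinear lateral inputs convolved with the
#' half-Gaussian kernel. Activities saturate at `ex_cap`.
#'
#' @param state a `ventral_state`.
#' @param v1_input pooled feedforward maps from [ex_input()] (list h/v/red/
#'   green), or NULL before stimulus onset.
#' @param it_feedback named numeric feature-bias vector (positive for target
#'   features), or NULL.
#' @param dt time step, ms.
#' @return the updated `ventral_state`.
#' @export
extrastriate_step <- function(state, v1_input, it_feedback = NULL, dt = NULL) {
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  if (dt <= 0) stop("dt must be positive")
  a <- dt / p$tau_ex
  ex <- state$ex
  opp <- c(h = "v", v = "h", red = "green", green = "red")
  for (k in names(ex)) {
    fb <- if (is.null(it_feedback) || is.null(it_feedback[k]) ||
              is.na(it_feedback[k])) 0 else it_feedback[[k]]
    drive <- if (is.null(v1_input)) 0 else {
      if (!identical(dim(v1_input[[k]]), dim(ex[[k]])))
        stop("shape mismatch between input and extrastriate maps")
      p$ex_gain * max(0, 1 + fb) * v1_input[[k]]
    }
    lat <- 0
    if (k == "h" && state$lat_weight > 0 && !is.null(v1_input)) {
      # collinear facilitation is seeded only by suprathreshold contour
      # activity, so incidental edge responses do not ignite the relay;
      # stimulus-supported cells relay at full strength while completed
      # (illusory) segments relay attenuated, so a contour can be
      # extrapolated beyond its bottom-up support but the extrapolation
      # loses force with distance instead of running on indefinitely
      src <- ex$h
      src[src < p$lat_threshold] <- 0
      unsupported <- v1_input$h < p$lat_support
      src[unsupported] <- src[unsupported] * p$lat_relay_decay
      lat <- state$lat_weight * (state$lat_R %*% src %*% state$lat_C)
    }
    # iso-orientation surround suppression across the preferred axis keeps
    # contour activity (and its lateral relay) confined to the contour band
    surr <- 0
    if (k %in% c("h", "v")) {
      surr <- p$ex_surr_inh * cross_axis_max(ex[[k]], along_rows = (k == "h"))
    }
    new <- ex[[k]] + a * (-ex[[k]] + drive -
                            p$ex_inh * ex[[opp[[k]]]] - surr + lat)
    new[new < 0] <- 0
    new[new > p$ex_cap] <- p$ex_cap
    ex[[k]] <- new
  }
  state$ex <- ex
  state$t_ms <- state$t_ms + dt
  state
}

# strongest activity among the 2 neighbours on each side across the
# preferred axis (rows above/below for horizontal cells, columns beside for
# vertical cells); cells flanking a strong iso-orientation contour are
# suppressed, cells on the contour itself are not
cross_axis_max <- function(x, along_rows) {
  m <- nrow(x); n <- ncol(x)
  out <- matrix(0, m, n)
  for (d in c(-2L, -1L, 1L, 2L)) {
    if (along_rows) {
      src <- pmin(pmax(seq_len(m) + d, 1L), m)
      sh <- x[src, , drop = FALSE]
      sh[abs(src - seq_len(m)) != abs(d), ] <- 0
    } else {
      src <- pmin(pmax(seq_len(n) + d, 1L), n)
      sh <- x[, src, drop = FALSE]
      sh[, abs(src - seq_len(n)) != abs(d)] <- 0
    }
    out <- pmax(out, sh)
  }
  out
}

# per-object evidence: best joint colour+orientation support at any location
object_evidence <- function(ex, objects) {
  ev <- numeric(length(objects))
  names(ev) <- objects
  for (o in objects) {
    ft <- object_features(o)
    ev[o] <- max(pmin(ex[[ft[1]]], ex[[ft[2]]]))
  }
  ev
}

object_features <- function(object) {
  parts <- strsplit(object, "_", fixed = TRUE)[[1]]
  colour <- parts[1]
  orient <- c(vertical = "v", horizontal = "h")[[parts[2]]]
  c(colour, orient)
}

#' One Euler step of the IT object-competition module
#'
#' Object units accumulate evidence from the extrastriate module and
#' mutually inhibit; a frontal bias (the memorised search target) tilts the
#' competition. The winner's identity gates feature-based feedback.
#'
#' @param state a `ventral_state`.
#' @param evidence named numeric per-object evidence; defaults to
#'   [object_evidence()] of the current extrastriate maps.
#' @param frontal_bias named numeric, nonzero only for the cued target.
#' @param dt time step, ms.
#' @return the updated `ventral_state`.
#' @export
it_step <- function(state, evidence = NULL, frontal_bias = NULL, dt = NULL) {
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  u <- state$it
  if (length(u) == 0) return(state)
  if (is.null(evidence)) evidence <- object_evidence(state$ex, names(u))
  bias <- numeric(length(u)); names(bias) <- names(u)
  if (!is.null(frontal_bias)) {
    if (any(frontal_bias < 0)) stop("frontal bias must be nonnegative")
    bias[names(frontal_bias)] <- frontal_bias
  }
  inh <- p$it_inh * (sum(u) - u)
  u <- u + (dt / p$tau_it) * (-u + p$it_gain * evidence[names(u)] +
                                p$it_bias * bias - inh)
  u[u < 0] <- 0
  state$it <- u
  state
}

#' Feature feedback vector from the current IT state
#'
#' Enhances the features of the cued object (during search) or of the
#' leading object (free viewing) and suppresses the others, proportionally
#' to that object's activity.
#' @param state a `ventral_state`.
#' @param cue object name held in frontal working memory, or NULL to use
#'   the current IT leader.
#' @return named numeric over `h`, `v`, `red`, `green`.
#' @export
it_feature_feedback <- function(state, cue = NULL) {
  fb <- c(h = 0, v = 0, red = 0, green = 0)
  u <- state$it
  if (length(u) == 0) return(fb)
  if (is.null(cue)) {
    if (max(u) <= 0) return(fb)
    win <- names(u)[which.max(u)]
    amp <- max(u)
  } else {
    if (!cue %in% names(u)) stop("unknown cue object: ", cue)
    win <- cue
    # working memory keeps the bias alive even when the target is not in view
    amp <- max(u[cue], 0.5)
  }
  g <- state$params$fb_gain * amp
  fb <- fb - g / 2
  fb[object_features(win)] <- g
  fb
}

#' Peak extrastriate activity ratio with and without lateral connections
#'
#' Fixates a scene location, applies a V1 lesion, and integrates the
#' extrastriate dynamics to a probe time with the collinear lateral weight
#' enabled and disabled; returns the ratio of the peak activities of the
#' horizontal map. This is the model's signature of form completion into
#' the blind field.
#'
#' @param scene a `hemiscan_scene` (defaults to the line stimulus).
#' @param fixation scene `c(x, y)`.
#' @param lesion a [lesion_spec()] applied to V1.
#' @param probe_ms probe time after fixation onset, ms.
#' @param lat_weight lateral weight for the enabled condition.
#' @param params a [hemiscan_params()] list.
#' @return list with `ratio`, `peak_on`, `peak_off`.
#' @export
lateral_activity_ratio <- function(scene = generate_line_stimulus(),
                                   fixation = c(500, 500),
                                   lesion = lesion_spec("v1", "left_field"),
                                   probe_ms = 300,
                                   lat_weight = NULL,
                                   params = hemiscan_params()) {
  if (is.null(lat_weight)) lat_weight <- params$lat_weight
  stack <- v1_response(retina_response(
    extract_retinal_view(scene, fixation, params$retina_px), params), params)
  if (!is.null(lesion)) stack <- apply_v1_lesion(stack, lesion)
  vin <- ex_input(stack, params)
  run <- function(w) {
    st <- ventral_init(nrow(vin$h), params = params, lat_weight = w)
    steps <- round(probe_ms / params$dt)
    for (s in seq_len(steps)) {
      inp <- if (st$t_ms >= params$onset_ms) vin else NULL
      st <- extrastriate_step(st, inp)
    }
    max(st$ex$h)
  }
  on <- run(lat_weight); off <- run(0)
  list(ratio = on / off, peak_on = on, peak_off = off)
}
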