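# Retinal preprocessing and V1: centre-surround and single-opponent retinal
# channels, orientation-selective complex-cell maps at two spatial scales,
# the unilateral V1 lesion operator, and endstop (line-termination)
# detection.

#' Describe a cortical lesion
#'
#' @param site `"v1"` or `"parietal"`.
#' @param side affected visual hemifield, `"left_field"` or `"right_field"`.
#' @param profile `"step"` (activity zeroed) or `"gradient"` (activity scaled
#'   by a linear impairment ramp; parietal only).
#' @param gradient_floor multiplier at the far periphery of the affected
#'   field for the gradient profile (maximum impairment), in (0, 1].
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(site = c("v1", "parietal"),
                        side = c("left_field", "right_field"),
                        profile = c("step", "gradient"),
                        gradient_floor = 0.6) {
  site <- match.arg(site); side <- match.arg(side)
  profile <- match.arg(profile)
  if (profile == "gradient" && site != "parietal")
    stop("gradient profile is only defined for the parietal module")
  stopifnot(gradient_floor > 0, gradient_floor <= 1)
  structure(list(site = site, side = side, profile = profile,
                 gradient_floor = gradient_floor),
            class = "lesion_spec")
}

# columns of an m x n retinotopic map belonging to a hemifield; the vertical
# meridian column (odd n) belongs to the right field
hemifield_cols <- function(n, side) {
  half <- floor(n / 2)
  # for odd n the meridian column belongs to neither hemifield
  if (side == "left_field") seq_len(half) else (n - half + 1L):n
}

#' Retinal response to a view
#'
#' Broadband centre-surround (difference-of-Gaussians on luminance) plus
#' red/green single-opponent channels, block-pooled to the V1 grid and
#' rectified. A uniform field yields (numerically) zero everywhere.
#'
#' @param view a `hemiscan_retina` from [extract_retinal_view()].
#' @param params a [hemiscan_params()] list.
#' @return list with matrices `bb`, `red`, `green` (V1 grid), plus
#'   `fixation` and `cell_px`.
#' @export
retina_response <- function(view, params = hemiscan_params()) {
  stopifnot(inherits(view, "hemiscan_retina"))
  f <- params$v1_cell_px
  L <- block_mean((view$pixels[, , 1] + view$pixels[, , 2] +
                     view$pixels[, , 3]) / 3, f)
  R <- block_mean(view$pixels[, , 1], f)
  G <- block_mean(view$pixels[, , 2], f)
  kc <- gauss_taps(params$dog_sigma_c); kc <- kc / sum(kc)
  ks <- gauss_taps(params$dog_sigma_s); ks <- ks / sum(ks)
  dog <- function(x) {
    c1 <- conv_sep(x, kc, kc, pad = "replicate")
    c2 <- conv_sep(x, ks, ks, pad = "replicate")
    relu(c1 - c2)
  }
  list(bb = dog(L), red = relu(R - G), green = relu(G - R),
       fixation = view$fixation, cell_px = f)
}

# oriented complex-cell filter response: Gaussian envelope along the
# preferred orientation, centre-surround (second-derivative-like) profile
# across it
oriented_response <- function(bb, sigma_long, params) {
  kl <- gauss_taps(sigma_long); kl <- kl / sum(kl)
  kd <- dog_taps(params$v1_sigma_cross_c, params$v1_sigma_cross_s)
  # replicate padding: the view border is inert, a contour running off the
  # edge keeps its full response there (only true terminations decay)
  cross <- function(x, along_rows) {
    if (along_rows) {
      relu(conv_sep(x, kd, kl, pad = "replicate"))
    } else {
      relu(conv_sep(x, kl, kd, pad = "replicate"))
    }
  }
  list(h = cross(bb, along_rows = TRUE),   # horizontal: cross profile on rows
       v = cross(bb, along_rows = FALSE))
}

# along-axis centre-surround applied to the horizontal complex-cell map;
# line terminations survive the surround and stand out as activity
# "buttons", interior points are uniformly attenuated. Replicate padding
# keeps the view border from masquerading as a line end.
endstop_drive <- function(h_map, params) {
  kc <- gauss_taps(params$end_sigma_c); kc <- kc / sum(kc)
  ks <- gauss_taps(params$end_sigma_s); ks <- ks / sum(ks)
  c1 <- conv2d(h_map, matrix(kc, nrow = 1), oy = 1L,
               ox = (length(kc) + 1L) %/% 2L, pad = "replicate")
  c2 <- conv2d(h_map, matrix(ks, nrow = 1), oy = 1L,
               ox = (length(ks) + 1L) %/% 2L, pad = "replicate")
  relu(c1 - params$end_surround_w * c2)
}

#' V1 complex-cell feature maps
#'
#' Orientation-selective (horizontal, vertical) maps at two filter scales
#' and red/green colour maps, plus the endstop drive map used by
#' [detect_endstops()]. Responses are scaled so that a full-contrast line
#' drives the matching orientation map to approximately 1.
#'
#' @param retina output of [retina_response()].
#' @param params a [hemiscan_params()] list.
#' @return A `hemiscan_v1` stack: `maps[[r]][[k]]` for r in `r1`,`r2` and
#'   k in `h`,`v`,`red`,`green`; `endstop` map; `fixation`; `cell_px`.
#' @export
v1_response <- function(retina, params = hemiscan_params()) {
  maps <- list()
  for (r in 1:2) {
    o <- oriented_response(retina$bb, params$v1_sigma_long[r], params)
    g <- params$v1_gain[r]
    kl <- gauss_taps(params$v1_sigma_long[r]); kl <- kl / sum(kl)
    maps[[paste0("r", r)]] <- list(
      h = g * o$h, v = g * o$v,
      red = params$colour_gain * conv_sep(retina$red, kl, kl, pad = "replicate"),
      green = params$colour_gain * conv_sep(retina$green, kl, kl, pad = "replicate"))
  }
  stack <- structure(list(maps = maps,
                          endstop = endstop_drive(maps$r1$h, params),
                          fixation = retina$fixation,
                          cell_px = retina$cell_px),
                     class = "hemiscan_v1")
  stack
}

#' Apply a unilateral V1 lesion
#'
#' Sets the activity of all V1 cells in the affected hemifield to zero, for
#' every orientation, colour and resolution (and the endstop drive, which
#' originates in V1). Idempotent.
#'
#' @param stack a `hemiscan_v1` stack.
#' @param lesion a [lesion_spec()] with `site = "v1"`.
#' @return the lesioned stack.
#' @export
apply_v1_lesion <- function(stack, lesion) {
  stopifnot(inherits(stack, "hemiscan_v1"))
  if (!inherits(lesion, "lesion_spec") || lesion$site != "v1")
    stop("lesion site must be 'v1'")
  n <- ncol(stack$maps$r1$h)
  cols <- hemifield_cols(n, lesion$side)
  for (r in names(stack$maps))
    for (k in names(stack$maps[[r]]))
      stack$maps[[r]][[k]][, cols] <- 0
  stack$endstop[, cols] <- 0
  stack
}

#' Detect line-end (endstopped-cell) responses
#'
#' Finds the connected region(s) of near-maximal activity in the horizontal
#' endstop-drive map and compares summed activity in flanking column strips:
#' a right line end has more activity to its left than its right, and vice
#' versa. Returns indicator maps and scene-coordinate hits.
#'
#' @param I horizontal endstop-drive map (matrix), or a `hemiscan_v1` stack.
#' @param fixation `c(x, y)` scene coordinates of the current fixation
#'   (taken from the stack when one is supplied).
#' @param cell_px grid cell size in pixels.
#' @param params a [hemiscan_params()] list.
#' @return list with indicator matrices `R`, `L` and a data.frame `hits`
#'   with columns `x` (scene px) and `side` (`"left"`/`"right"`).
#' @export
detect_endstops <- function(I, fixation = NULL, cell_px = NULL,
                            params = hemiscan_params()) {
  if (inherits(I, "hemiscan_v1")) {
    if (is.null(fixation)) fixation <- I$fixation
    if (is.null(cell_px)) cell_px <- I$cell_px
    I <- I$endstop
  }
  if (is.null(fixation)) fixation <- c(0, 0)
  if (is.null(cell_px)) cell_px <- 5
  m <- nrow(I); n <- ncol(I)
  Rm <- matrix(FALSE, m, n); Lm <- matrix(FALSE, m, n)
  hits <- data.frame(x = numeric(0), side = character(0),
                     stringsAsFactors = FALSE)
  mx <- max(I)
  if (mx <= 1e-9)
    return(list(R = Rm, L = Lm, hits = hits))
  lab <- label_components(I >= params$end_comp_frac * mx)
  w <- params$end_win
  ctr <- (n + 1) / 2
  for (cc in seq_len(max(lab))) {
    cells <- which(lab == cc, arr.ind = TRUE)
    rows <- range(cells[, 1]); cols <- range(cells[, 2])
    rband <- max(1, rows[1] - 1):min(m, rows[2] + 1)
    lw <- (cols[1] - w):(cols[1] - 1)
    rw <- (cols[2] + 1):(cols[2] + w)
    lsum <- sum(I[rband, lw[lw >= 1 & lw <= n], drop = FALSE])
    rsum <- sum(I[rband, rw[rw >= 1 & rw <= n], drop = FALSE])
    tol <- 0.05 * (lsum + rsum)
    rmid <- round(mean(cells[, 1]))
    off <- params$end_offset_cells  # filter-inset correction, calibrated
    if (lsum > rsum + tol) {
      jc <- cols[2]
      Rm[rmid, jc] <- TRUE
      hits <- rbind(hits, data.frame(
        x = fixation[1] + (jc - ctr + off) * cell_px, side = "right"))
    } else if (rsum > lsum + tol) {
      jc <- cols[1]
      Lm[rmid, jc] <- TRUE
      hits <- rbind(hits, data.frame(
        x = fixation[1] + (jc - ctr - off) * cell_px, side = "left"))
    }
  }
  list(R = Rm, L = Lm, hits = hits)
}
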