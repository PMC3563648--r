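# Stimulus construction: conjunction-search bar arrays, the single
# horizontal line used for bisection, and gaze-contingent retinal extraction.
# Scene coordinates are 0-based pixels, origin top-left, x rightward,
# 11 px per degree of visual angle.

#' Create a stimulus item
#' @keywords internal
stimulus_item <- function(x, y, orientation, colour, length_px, width_px,
                          is_target = FALSE) {
  list(x = x, y = y, orientation = orientation, colour = colour,
       length_px = length_px, width_px = width_px, is_target = is_target)
}

item_bbox <- function(it) {
  if (it$orientation == "horizontal") {
    w <- it$length_px; h <- it$width_px
  } else {
    w <- it$width_px; h <- it$length_px
  }
  c(x0 = it$x - (w - 1) / 2, x1 = it$x + (w - 1) / 2,
    y0 = it$y - (h - 1) / 2, y1 = it$y + (h - 1) / 2)
}

colour_rgb <- function(colour) {
  switch(colour, red = c(1, 0, 0), green = c(0, 1, 0),
         stop("unknown colour: ", colour))
}

new_scene <- function(image, items, px_per_deg = 11) {
  structure(list(image = image, items = items,
                 width_px = dim(image)[2], height_px = dim(image)[1],
                 px_per_deg = px_per_deg),
            class = "hemiscan_scene")
}

paint_item <- function(image, it) {
  bb <- round(item_bbox(it))
  rows <- (bb["y0"]:bb["y1"]) + 1L
  cols <- (bb["x0"]:bb["x1"]) + 1L
  rgb <- colour_rgb(it$colour)
  for (ch in 1:3) image[rows, cols, ch] <- rgb[ch]
  image
}

#' Generate a conjunction-search scene
#'
#' Places red/green, horizontal/vertical bars uniformly at random without
#' bounding-box overlap. Exactly one bar (the target) carries a unique
#' conjunction of colour and orientation; the distractor set always contains
#' both the target's colour (with the other orientation) and the target's
#' orientation (with the other colour), so the target cannot be found by a
#' single-feature search.
#'
#' @param n_items total number of bars (>= 4 so all three distractor
#'   conjunctions can appear).
#' @param seed integer; the scene is a pure function of the arguments.
#' @param scene_size `c(width, height)` in pixels.
#' @param bar_px bar length and width in pixels (3 deg x 1 deg default).
#' @param min_spacing_px minimum centre-to-centre spacing.
#' @param target_conjunction length-2 character `c(colour, orientation)`.
#' @return A `hemiscan_scene`: list with `image` (height x width x 3 array in
#'   [0,1]), `items`, `width_px`, `height_px`, `px_per_deg`.
#' @export
generate_search_scene <- function(n_items = 40L, seed = 1L,
                                  scene_size = c(1000L, 1000L),
                                  bar_px = c(33L, 11L),
                                  min_spacing_px = 44,
                                  target_conjunction = c("red", "vertical")) {
  stopifnot(n_items >= 4, length(scene_size) == 2)
  w <- scene_size[1]; h <- scene_size[2]
  margin <- max(bar_px) / 2 + 2
  if (w <= 2 * margin || h <= 2 * margin) stop("scene too small for bars")
  tgt_col <- match.arg(target_conjunction[1], c("red", "green"))
  tgt_ori <- match.arg(target_conjunction[2], c("vertical", "horizontal"))
  other_col <- setdiff(c("red", "green"), tgt_col)
  other_ori <- setdiff(c("vertical", "horizontal"), tgt_ori)
  with_seed(seed, {
    # feature inventory: one target; distractors cycle through the other
    # three conjunctions so both target features occur among distractors
    dis <- list(c(tgt_col, other_ori), c(other_col, tgt_ori),
                c(other_col, other_ori))
    feats <- c(list(c(tgt_col, tgt_ori)),
               rep(dis, length.out = n_items - 1L))
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_items) {
      if (tries > 200L * n_items) stop("scene too crowded")
      x <- runif(1, margin, w - 1 - margin)
      y <- runif(1, margin, h - 1 - margin)
      tries <- tries + 1L
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= min_spacing_px^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    items <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      items[[i]] <- stimulus_item(round(xs[i]), round(ys[i]),
                                  orientation = feats[[i]][2],
                                  colour = feats[[i]][1],
                                  length_px = bar_px[1], width_px = bar_px[2],
                                  is_target = i == 1L)
    }
    image <- array(0, dim = c(h, w, 3))
    for (it in items) image <- paint_item(image, it)
    new_scene(image, items)
  })
}

#' Generate the horizontal line stimulus
#'
#' A single green horizontal line of 45 x 1 deg (495 x 11 px), horizontally
#' centred at scene x = 500 and vertically centred in the scene. The line
#' spans columns 253..747 inclusive.
#'
#' @param scene_size `c(width, height)` in pixels; width must be >= 1000.
#' @return A `hemiscan_scene` with a single non-target item.
#' @export
generate_line_stimulus <- function(scene_size = c(1000L, 1000L)) {
  w <- scene_size[1]; h <- scene_size[2]
  if (w < 1000) stop("scene too small: width must be >= 1000 px")
  yc <- floor(h / 2)
  it <- stimulus_item(500, yc, "horizontal", "green",
                      length_px = 495L, width_px = 11L, is_target = FALSE)
  image <- array(0, dim = c(h, w, 3))
  image <- paint_item(image, it)
  new_scene(image, list(it))
}

#' Extract the retinal view at a fixation
#'
#' Returns the square window of the scene centred on the fixation point.
#' Regions beyond the scene border are blank (zero): the scene boundary is
#' inert, it contributes no contrast.
#'
#' @param scene a `hemiscan_scene`.
#' @param fixation `c(x, y)` scene pixels (0-based).
#' @param extent_px window side in pixels (odd; default 495).
#' @return A `hemiscan_retina`: list with `pixels` (extent x extent x 3),
#'   `fixation`, `extent_px`.
#' @export
extract_retinal_view <- function(scene, fixation, extent_px = 495L) {
  stopifnot(inherits(scene, "hemiscan_scene"), length(fixation) == 2)
  fx <- fixation[1]; fy <- fixation[2]
  if (fx < 0 || fy < 0 || fx > scene$width_px - 1 || fy > scene$height_px - 1)
    stop("fixation outside the scene")
  half <- (extent_px - 1) / 2
  px <- array(0, dim = c(extent_px, extent_px, 3))
  x0 <- round(fx) - half; y0 <- round(fy) - half
  sc <- max(0, x0):min(scene$width_px - 1, x0 + extent_px - 1)
  sr <- max(0, y0):min(scene$height_px - 1, y0 + extent_px - 1)
  if (length(sc) > 0 && length(sr) > 0) {
    px[sr - y0 + 1, sc - x0 + 1, ] <- scene$image[sr + 1, sc + 1, , drop = FALSE]
  }
  structure(list(pixels = px, fixation = c(round(fx), round(fy)),
                 extent_px = extent_px),
            class = "hemiscan_retina")
}

#' Convert between pixels and degrees of visual angle
#' @param px,deg values to convert.
#' @param px_per_deg pixels per degree (default 11).
#' @export
px_to_deg <- function(px, px_per_deg = 11) px / px_per_deg

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, px_per_deg = 11) deg * px_per_deg

#' Serialize scene ground truth as JSON-compatible list
#' @param scene a `hemiscan_scene`.
#' @return list of item records.
#' @export
scene_inventory <- function(scene) {
  lapply(scene$items, function(it)
    list(x = it$x, y = it$y, orientation = it$orientation,
         colour = it$colour, length_px = it$length_px,
         width_px = it$width_px, is_target = it$is_target))
}

#' @export
print.hemiscan_scene <- function(x, ...) {
  nt <- sum(vapply(x$items, function(i) i$is_target, logical(1)))
  cat(sprintf("<hemiscan_scene> %d x %d px, %d item(s), %d target(s)\n",
              x$width_px, x$height_px, length(x$items), nt))
  invisible(x)
}
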