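test_that("lateral kernel is a 4 x 10 rightward half field with peak 1", {
  k <- lateral_kernel()
  expect_equal(dim(k$weights), c(4L, 10L))
  expect_equal(ncol(k$weights), 10L)
  expect_equal(max(k$weights), 1)
  expect_equal(k$col_offsets, 0:9)
  expect_equal(k$row_offsets, -2:1)
  # no leftward taps
  expect_true(all(k$col_offsets >= 0))
  # amplitudes decay monotonically away from the origin along the axis
  axis <- k$weights[k$row_offsets == 0, ]
  expect_true(all(diff(axis) < 0))
  expect_true(all(k$weights >= 0))
})

test_that("leftward-facing kernel is the mirror image", {
  r <- lateral_kernel(facing = "rightward")
  l <- lateral_kernel(facing = "leftward")
  expect_equal(l$col_offsets, rev(-r$col_offsets))
  expect_equal(l$weights, r$weights[, rev(seq_len(ncol(r$weights)))])
})

test_that("band_matrix implements offset gathering", {
  R <- band_matrix(5L, c(-1L, 0L), c(0.5, 1))
  x <- c(1, 2, 3, 4, 5)
  got <- as.numeric(R %*% x)
  # y[i] = 0.5 * x[i - 1] + x[i], out-of-range taps dropped
  expect_equal(got, c(1, 2 + 0.5, 3 + 1, 4 + 1.5, 5 + 2))
})

test_that("extrastriate activity is bounded and off without input", {
  p <- hemiscan_params()
  vst <- ventral_init(33L, objects = "green_horizontal", params = p,
                      lat_weight = 0)
  for (i in 1:50) vst <- extrastriate_step(vst, NULL)
  expect_true(all(vst$ex$h == 0))
  sc <- generate_line_stimulus()
  v <- extract_retinal_view(sc, c(500, 500))
  vin <- ex_input(v1_response(retina_response(v), p), p)
  for (i in 1:200) vst <- extrastriate_step(vst, vin)
  expect_true(all(vst$ex$h >= 0 & vst$ex$h <= p$ex_cap))
})

test_that("lateral propagation is strictly unidirectional and collinear", {
  p <- hemiscan_params()
  sc <- generate_line_stimulus()
  v <- extract_retinal_view(sc, c(500, 500))
  stack <- apply_v1_lesion(v1_response(retina_response(v), p),
                           lesion_spec("v1", "left_field", "step"))
  vin <- ex_input(stack, p)
  vst <- ventral_init(33L, objects = "green_horizontal", params = p,
                      lat_weight = p$lat_weight, facing = "rightward")
  for (i in 1:150) vst <- extrastriate_step(vst, vin)
  h <- vst$ex$h
  line_row <- which.max(apply(h, 1, max))
  # activity stays on the line's row band (no vertical ignition)
  off_rows <- setdiff(seq_len(nrow(h)), line_row + (-1:1))
  expect_lt(max(h[off_rows, ]), 0.5 * max(h))
  # propagation filled in toward the blind (left) side
  expect_gt(max(h[line_row, 1:16]), 0.5 * max(h))
  # with the relay off, the blind half stays silent
  vst0 <- ventral_init(33L, objects = "green_horizontal", params = p,
                       lat_weight = 0)
  for (i in 1:150) vst0 <- extrastriate_step(vst0, vin)
  expect_lt(max(vst0$ex$h[, 1:14]), 0.05)
})

test_that("activity ratio with vs without lateral input is about 3", {
  r <- lateral_activity_ratio()
  expect_gt(r$ratio, 1.5)
  expect_lt(r$ratio, 4.5)
  expect_gt(r$peak_on, r$peak_off)
})

test_that("IT competition selects the cued object", {
  p <- hemiscan_params()
  sc <- generate_search_scene(seed = 2)
  v <- extract_retinal_view(sc, c(500, 500))
  vin <- ex_input(v1_response(retina_response(v), p), p)
  objs <- c("red_vertical", "red_horizontal", "green_vertical",
            "green_horizontal")
  vst <- ventral_init(33L, objects = objs, params = p, lat_weight = 0)
  fb <- NULL
  for (i in 1:200) {
    vst <- extrastriate_step(vst, vin, it_feedback = fb)
    vst <- it_step(vst, frontal_bias = c(red_vertical = 1))
    fb <- it_feature_feedback(vst, cue = "red_vertical")
  }
  expect_equal(names(which.max(vst$it)), "red_vertical")
  # feedback favours the cue's features
  expect_gt(fb[["red"]], 0)
  expect_gt(fb[["v"]], 0)
})
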