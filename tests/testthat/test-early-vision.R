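test_that("lesion_spec validates its arguments", {
  l <- lesion_spec("v1", "left_field", "step")
  expect_s3_class(l, "lesion_spec")
  expect_error(lesion_spec("v1", "left_field", "gradient"), "parietal")
  expect_error(lesion_spec("parietal", gradient_floor = 0), "gradient_floor")
  g <- lesion_spec("parietal", "left_field", "gradient")
  expect_equal(g$gradient_floor, 0.6)
})

test_that("hemifield split is mirror-symmetric around the meridian", {
  expect_equal(hemifield_cols(45L, "left_field"), 1:22)
  expect_equal(hemifield_cols(45L, "right_field"), 24:45)
  expect_equal(hemifield_cols(4L, "left_field"), 1:2)
  expect_equal(hemifield_cols(4L, "right_field"), 3:4)
})

test_that("V1 step lesion silences the left field and is idempotent", {
  sc <- generate_line_stimulus()
  v <- extract_retinal_view(sc, c(500, 500))
  stack <- v1_response(retina_response(v), hemiscan_params())
  les <- lesion_spec("v1", "left_field", "step")
  l1 <- apply_v1_lesion(stack, les)
  n <- ncol(l1$maps$r1$h)
  left <- hemifield_cols(n, "left_field")
  for (r in names(l1$maps)) for (k in names(l1$maps[[r]])) {
    expect_true(all(l1$maps[[r]][[k]][, left] == 0))
  }
  # the intact field is untouched
  right <- hemifield_cols(n, "right_field")
  expect_equal(l1$maps$r1$h[, right], stack$maps$r1$h[, right])
  # idempotent
  l2 <- apply_v1_lesion(l1, les)
  expect_identical(l1$maps, l2$maps)
  expect_error(apply_v1_lesion(stack, lesion_spec("parietal")), "v1")
})

test_that("oriented responses separate horizontal from vertical bars", {
  sc <- generate_line_stimulus()
  v <- extract_retinal_view(sc, c(500, 500))
  stack <- v1_response(retina_response(v), hemiscan_params())
  expect_gt(max(stack$maps$r1$h), 3 * max(stack$maps$r1$v))
})

test_that("endstop detection localises a line end seen away from the view border", {
  # the line spans the full retinal width from a centre fixation, so each
  # end is probed from a fixation that brings it inside the view
  sc <- generate_line_stimulus()
  stack_l <- v1_response(retina_response(extract_retinal_view(sc, c(420, 500))),
                         hemiscan_params())
  ends_l <- detect_endstops(stack_l, fixation = c(420, 500))
  expect_true("left" %in% ends_l$hits$side)
  lx <- ends_l$hits$x[ends_l$hits$side == "left"]
  expect_lt(min(abs(lx - 253)), 11)
  stack_r <- v1_response(retina_response(extract_retinal_view(sc, c(580, 500))),
                         hemiscan_params())
  ends_r <- detect_endstops(stack_r, fixation = c(580, 500))
  expect_true("right" %in% ends_r$hits$side)
  rx <- ends_r$hits$x[ends_r$hits$side == "right"]
  expect_lt(min(abs(rx - 747)), 11)
})

test_that("endstop estimates track the end across fixations (sweep)", {
  sc <- generate_line_stimulus()
  for (fx in c(600, 700, 800)) {
    v <- extract_retinal_view(sc, c(fx, 500))
    stack <- v1_response(retina_response(v), hemiscan_params())
    ends <- detect_endstops(stack)
    rx <- ends$hits$x[ends$hits$side == "right"]
    expect_true(length(rx) > 0)
    expect_lt(abs(max(rx) - 747), 11)
  }
})

test_that("a lesioned left field carries no endstop evidence", {
  sc <- generate_line_stimulus()
  v <- extract_retinal_view(sc, c(500, 500))
  stack <- v1_response(retina_response(v), hemiscan_params())
  stack <- apply_v1_lesion(stack, lesion_spec("v1", "left_field", "step"))
  ends <- detect_endstops(stack)
  expect_false(any(ends$hits$side == "left" & ends$hits$x < 500))
})
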