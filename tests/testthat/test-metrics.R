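test_that("bisection-error conversions reproduce the reference pairs", {
  pairs <- list(
    list(x = 705, deg = 18.6, pct = 41.4),
    list(x = 645, deg = 13.2, pct = 29.3),
    list(x = 455, deg = -4.1, pct = -9.1),
    list(x = 697, deg = 17.9, pct = 39.8),
    list(x = 587, deg = 7.9, pct = 17.6),
    list(x = 685, deg = 16.8, pct = 37.4),
    list(x = 500, deg = 0, pct = 0)
  )
  for (pr in pairs) {
    e <- bisection_error(pr$x)
    expect_lt(abs(e[["offset_deg"]] - pr$deg), 0.05)
    expect_lt(abs(e[["offset_pct"]] - pr$pct), 0.05)
  }
})

test_that("offset sign convention: rightward is positive", {
  expect_gt(bisection_error(600)[["offset_deg"]], 0)
  expect_lt(bisection_error(400)[["offset_deg"]], 0)
})

make_fake_trial <- function(x, y) {
  structure(list(fixations = data.frame(
    x = x, y = y, onset_ms = seq_along(x) * 100,
    duration_ms = rep(100, length(x)))), class = "hemiscan_trial")
}

test_that("fixation density is permutation-invariant and excludes off-line", {
  x <- c(260, 400, 500, 640, 700)
  y <- c(500, 500, 520, 500, 500)
  a <- fixation_density(make_fake_trial(x, y))
  perm <- c(3, 1, 5, 2, 4)
  b <- fixation_density(make_fake_trial(x[perm], y[perm]))
  expect_identical(a$counts, b$counts)
  expect_equal(sum(a$counts), 4)  # the y=520 fixation is excluded
  expect_equal(a$n_excluded, 1)
})

test_that("near/blank fixation percentages are complementary", {
  sc <- generate_search_scene(seed = 4)
  it <- sc$items[[1]]
  on_item <- make_fake_trial(c(0, it$x, it$x + 2), c(0, it$y, it$y))
  p <- pct_fixations_on_stimuli(on_item, sc, drop_initial = FALSE)
  expect_equal(unname(p["pct_near"] + p["pct_blank"]), 100)
  # a fixation in an empty corner counts as blank
  expect_gt(p[["pct_blank"]], 0)
  expect_gt(p[["pct_near"]], 0)
})

test_that("the imposed initial fixation is excluded by default", {
  sc <- generate_search_scene(seed = 4)
  it <- sc$items[[1]]
  tr <- make_fake_trial(c(999, it$x), c(999, it$y))
  expect_equal(pct_fixations_on_stimuli(tr, sc)[["pct_near"]], 100)
  expect_equal(
    pct_fixations_on_stimuli(tr, sc, drop_initial = FALSE)[["pct_near"]], 50)
})

test_that("strays_off_line applies the one-degree rule", {
  expect_false(strays_off_line(make_fake_trial(c(400, 600), c(500, 511))))
  expect_true(strays_off_line(make_fake_trial(c(400, 600), c(500, 512))))
})
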