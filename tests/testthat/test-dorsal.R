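test_that("step parietal lesion zeroes the field and is idempotent", {
  fx <- make_unit_fixtures()
  P <- fx$two_blob
  les <- lesion_spec("parietal", "left_field", "step")
  L1 <- apply_parietal_lesion(P, les)
  expect_true(all(L1[, 1:22] == 0))
  expect_equal(L1[, 23:45], P[, 23:45])
  expect_identical(apply_parietal_lesion(L1, les), L1)
})

test_that("gradient lesion ramps from floor 0.6 to 1 at the meridian", {
  les <- lesion_spec("parietal", "left_field", "gradient")
  P <- matrix(1, 45, 45)
  L <- apply_parietal_lesion(P, les)
  expect_equal(L[1, 1], 0.6)
  expect_lt(L[1, 22], 1)
  expect_gt(L[1, 22], 0.9)
  expect_equal(L[1, 23], 1)
  expect_true(all(diff(L[1, 1:23]) > 0))
  # intact field untouched
  expect_true(all(L[, 23:45] == 1))
})

test_that("right-field lesions mirror left-field ones", {
  P <- matrix(1, 45, 45)
  l <- apply_parietal_lesion(P, lesion_spec("parietal", "left_field",
                                            "gradient"))
  r <- apply_parietal_lesion(P, lesion_spec("parietal", "right_field",
                                            "gradient"))
  expect_equal(l[1, 1:22], rev(r[1, 24:45]))
})

test_that("spatial compensation field is a ramp peaking at the lesioned side", {
  f <- spatial_compensation_field(45L, "left_field", 2)
  expect_equal(f[1, 1], 2)
  expect_equal(f[1, 45], 0)
  expect_true(all(diff(f[1, ]) < 0))
  expect_true(all(spatial_compensation_field(45L, weight = 0) == 0))
  expect_error(spatial_compensation_field(45L, weight = -1), "nonnegative")
})

test_that("bisection bias peaks at the requested centre", {
  b <- bisection_bias_field(45L, weight = 4.5, sigma = 12,
                            centre = c(30, 20))
  ij <- which(b == max(b), arr.ind = TRUE)
  expect_equal(unname(ij[1, ]), c(20, 30))
  expect_equal(max(b), 4.5)
})

test_that("saccade target is the RF centre of the peak cell (+10 deg case)", {
  p <- hemiscan_params()
  st <- parietal_init(p)
  st$P[23, 33] <- 1  # 10 cells right of centre
  tgt <- select_saccade_target(st, c(500, 500))
  expect_equal(tgt, c(610, 500))
  # empty map yields no target
  st$P[] <- 0
  expect_null(select_saccade_target(st, c(500, 500)))
  # clipping to the scene
  st$P[23, 45] <- 1
  tgt2 <- select_saccade_target(st, c(900, 500), scene_size = c(1000, 1000))
  expect_equal(tgt2[1], 999)
})

test_that("novelty marks inspected discs and compounds over visits", {
  p <- hemiscan_params()
  st <- parietal_init(p)
  nov <- novelty_field(st, c(500, 500),
                       history = rbind(c(500, 500)))
  expect_equal(nov[23, 23], p$ior_factor)
  expect_equal(nov[23, 45], 1)
  nov2 <- novelty_field(st, c(500, 500),
                        history = rbind(c(500, 500), c(500, 500)))
  expect_equal(nov2[23, 23], p$ior_factor^2)
})

test_that("parietal extent reads RF edges and needs two active columns", {
  p <- hemiscan_params()
  st <- parietal_init(p)
  st$P[23, 20:26] <- 1
  ext <- parietal_extent(st, c(500, 500))
  # columns 20..26 -> RF centres 467..533, widened by the RF radius
  expect_equal(ext$left, 467 - p$extent_rf_px)
  expect_equal(ext$right, 533 + p$extent_rf_px)
  # a single suprathreshold column is not an extent
  st$P[] <- 0
  st$P[23, 23] <- 1
  ext1 <- parietal_extent(st, c(500, 500))
  expect_true(is.na(ext1$left) && is.na(ext1$right))
})

test_that("parietal integration approaches its drive and stays nonnegative", {
  p <- hemiscan_params()
  st <- parietal_init(p)
  drv <- matrix(0, 45, 45); drv[10, 10] <- 1
  for (i in 1:400) st <- parietal_step(st, drv, noise = FALSE)
  expect_gt(st$P[10, 10], 0.9 * p$par_drive_gain)
  expect_true(all(st$P >= 0))
})
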