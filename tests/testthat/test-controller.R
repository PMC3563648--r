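test_that("trial_config validates arguments", {
  expect_error(trial_config("search", bisection_weight = 4.5), "bisection")
  expect_error(trial_config("bisection", bisection_weight = -1),
               "nonnegative")
  expect_error(trial_config("bisection", lesion = list(site = "v1")),
               "lesion")
  cfg <- trial_config("bisection", bisection_weight = 4.5, seed = 3)
  expect_s3_class(cfg, "trial_config")
})

test_that("trials are deterministic given the seed", {
  sc <- generate_line_stimulus()
  cfg <- trial_config("bisection", bisection_weight = 4.5, seed = 11)
  a <- run_trial(sc, cfg)
  b <- run_trial(sc, cfg)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$bisection, b$bisection)
  c <- run_trial(sc, trial_config("bisection", bisection_weight = 4.5,
                                  seed = 12))
  expect_false(identical(a$fixations, c$fixations))
})

test_that("running a trial does not disturb the caller's RNG stream", {
  sc <- generate_line_stimulus()
  set.seed(42)
  ref <- rnorm(3)
  set.seed(42)
  invisible(run_trial(sc, trial_config("bisection", bisection_weight = 4.5,
                                       seed = 5)))
  expect_identical(rnorm(3), ref)
})

test_that("ledger midpoint is the mean-of-sides midpoint", {
  lg <- data.frame(fix = c(1, 1, 2, 2),
                   side = c("left", "right", "left", "right"),
                   x = c(250, 750, 270, 730),
                   provenance = "endstop", stringsAsFactors = FALSE)
  expect_equal(ledger_midpoint(lg), (mean(c(250, 270)) +
                                       mean(c(750, 730))) / 2)
  expect_true(is.na(ledger_midpoint(lg[lg$side == "left", ])))
  b <- compute_bisection_point(lg)
  expect_equal(b$bisection_x, 500)
  expect_equal(b$offset_deg, 0)
  expect_error(compute_bisection_point(lg[lg$side == "left", ]),
               "insufficient evidence")
})

test_that("line-end estimates carry provenance and respect attention", {
  p <- hemiscan_params()
  pst <- parietal_init(p)
  rep_map <- matrix(0, 45, 45)
  rep_map[23, 18:28] <- 1  # attended strip around fixation
  ends <- list(hits = data.frame(x = c(253, 747),
                                 side = c("left", "right"),
                                 stringsAsFactors = FALSE))
  # endstops at 253/747 are outside the attended strip -> extents instead
  lg <- record_line_end_estimates(ends, pst, c(500, 500), line_y = 500,
                                  rep_map = rep_map)
  expect_setequal(lg$provenance, "cortical_extent")
  # widen attention to cover the endstop locations
  rep_map[23, ] <- 1
  lg2 <- record_line_end_estimates(ends, pst, c(500, 500), line_y = 500,
                                   rep_map = rep_map)
  expect_setequal(lg2$provenance, "endstop")
  expect_setequal(lg2$x, c(253, 747))
  # endstop-only mode bypasses the attention gate and the extent fallback
  rep_map[23, ] <- 0; rep_map[23, 18:28] <- 1
  lg3 <- record_line_end_estimates(ends, pst, c(500, 500), line_y = 500,
                                   endstop_only = TRUE, rep_map = rep_map)
  expect_setequal(lg3$provenance, "endstop")
})

test_that("saccades trigger on a clear IT winner or on timeout", {
  p <- hemiscan_params()
  st <- list(it = c(a = 0.5, b = 0.1), t_ms = 300)
  expect_true(trigger_saccade(st, 300, 400, p))
  # not before the minimum fixation duration
  expect_false(trigger_saccade(st, 200, 400, p))
  # no clear winner: only the timeout triggers
  st$it <- c(a = 0.5, b = 0.45)
  expect_false(trigger_saccade(st, 300, 400, p))
  expect_true(trigger_saccade(st, 400, 400, p))
})

test_that("scanpath and bisection CSVs round-trip", {
  sc <- generate_line_stimulus()
  trs <- run_trials(sc, function(s)
    trial_config("bisection", bisection_weight = 4.5, seed = s),
    n_trials = 2, base_seed = 21)
  d <- tempfile("csv")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  write_scanpaths_csv(trs, file.path(d, "s.csv"))
  write_bisections_csv(trs, file.path(d, "b.csv"))
  s <- read.csv(file.path(d, "s.csv"))
  expect_named(s, c("trial_id", "fix_index", "x_px", "y_px",
                    "onset_ms", "duration_ms"))
  expect_equal(nrow(s), sum(vapply(trs, function(tr)
    nrow(tr$fixations), integer(1))))
  b <- read.csv(file.path(d, "b.csv"))
  expect_named(b, c("trial_id", "bisection_x", "offset_deg", "offset_pct"))
  expect_equal(nrow(b), 2)
})
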