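# Deterministic experiment grids and synthetic unit fixtures, so the whole
# simulation suite reproduces from seeds with no external data.

#' Canonical line-bisection condition grid
#'
#' The 13-cell grid behind the summary bisection table: one intact control,
#' plus four bisection-bias weights (3, 4, 4.5, 5) for each of the three
#' lesion conditions — V1 step lesion with strengthened lateral
#' connectivity (chronic form completion, no spatial bias), parietal step
#' lesion and parietal gradient lesion (both with both compensation
#' mechanisms enabled).
#'
#' @param trials_per_cell seeded trials per cell.
#' @param base_seed first seed; trial `i` of every cell runs with
#'   `base_seed + i - 1`.
#' @return An `experiment_spec`: data.frame of cells (`condition`,
#'   `lesion_site`, `lesion_profile`, `compensation`, `bisection_weight`)
#'   with the trial count and base seed attached.
#' @export
make_table1_grid <- function(trials_per_cell = 10L, base_seed = 20130204L) {
  weights <- c(3, 4, 4.5, 5)
  cells <- rbind(
    data.frame(condition = "control", lesion_site = "none",
               lesion_profile = "none", compensation = "none",
               bisection_weight = 4.5, stringsAsFactors = FALSE),
    data.frame(condition = "v1_lateral", lesion_site = "v1",
               lesion_profile = "step", compensation = "lateral",
               bisection_weight = weights, stringsAsFactors = FALSE),
    data.frame(condition = "parietal_step", lesion_site = "parietal",
               lesion_profile = "step", compensation = "both",
               bisection_weight = weights, stringsAsFactors = FALSE),
    data.frame(condition = "parietal_gradient", lesion_site = "parietal",
               lesion_profile = "gradient", compensation = "both",
               bisection_weight = weights, stringsAsFactors = FALSE)
  )
  structure(list(cells = cells,
                 trials_per_cell = as.integer(trials_per_cell),
                 base_seed = as.integer(base_seed)),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %d cells x %d trials (base seed %d)\n",
              nrow(x$cells), x$trials_per_cell, x$base_seed))
  print(x$cells)
  invisible(x)
}

# build the trial_config for one grid cell and one seed
cell_config <- function(cell, seed, params = hemiscan_params()) {
  lesion <- if (cell$lesion_site == "none") NULL else
    lesion_spec(cell$lesion_site, "left_field", cell$lesion_profile,
                gradient_floor = params$gradient_floor)
  trial_config("bisection", lesion = lesion,
               compensation = cell$compensation,
               bisection_weight = cell$bisection_weight,
               seed = seed, params = params)
}

#' Run every cell of an experiment grid
#'
#' @param spec an `experiment_spec` from [make_table1_grid()].
#' @param params model parameters shared by all cells.
#' @param progress print one line per finished cell.
#' @return list with `spec`, `trials` (list of per-cell trial lists) and
#'   `table` (the per-cell summary, see [experiment_table()]).
#' @export
run_experiment <- function(spec, params = hemiscan_params(),
                           progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  scene <- generate_line_stimulus()
  trials <- vector("list", nrow(spec$cells))
  for (i in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[i, ]
    trials[[i]] <- lapply(seq_len(spec$trials_per_cell), function(k) {
      run_trial(scene, cell_config(cell, spec$base_seed + k - 1L, params))
    })
    if (progress)
      cat(sprintf("cell %d/%d (%s w=%.1f) done\n", i, nrow(spec$cells),
                  cell$condition, cell$bisection_weight))
  }
  out <- list(spec = spec, trials = trials)
  out$table <- experiment_table(out)
  out
}

#' Summarise an experiment run as a bisection table
#'
#' One row per cell: mean bisection point (scene x), mean offset in degrees
#' and in percent of line length, and the share of runs with at least one
#' fixation straying more than one degree off the line.
#'
#' @param result value of [run_experiment()].
#' @return data.frame.
#' @export
experiment_table <- function(result) {
  cells <- result$spec$cells
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    trs <- result$trials[[i]]
    bx <- vapply(trs, function(tr)
      if (is.null(tr$bisection)) NA_real_ else tr$bisection$bisection_x,
      numeric(1))
    stray <- vapply(trs, strays_off_line, logical(1))
    e <- bisection_error(mean(bx, na.rm = TRUE))
    data.frame(condition = cells$condition[i],
               lesion_profile = cells$lesion_profile[i],
               compensation = cells$compensation[i],
               bisection_weight = cells$bisection_weight[i],
               mean_bisection_x = mean(bx, na.rm = TRUE),
               offset_deg = e[["offset_deg"]],
               offset_pct = e[["offset_pct"]],
               pct_strayed = 100 * mean(stray),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the bisection summary table as CSV
#' @param table data.frame from [experiment_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_table1_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Small deterministic grids for unit tests
#'
#' All fixtures are pure functions of their construction code (no RNG, no
#' files): a uniform 64x64 grid, a half-span horizontal line grid whose
#' right end sits at a known column, and a two-blob parietal-sized map
#' whose right blob is stronger by a fixed factor.
#'
#' @return named list `uniform`, `half_line` (with attributes
#'   `end_col`, `line_row`) and `two_blob` (with attribute `asymmetry`).
#' @export
make_unit_fixtures <- function() {
  uniform <- matrix(1, 64, 64)

  half_line <- matrix(0, 64, 64)
  end_col <- 32L
  line_row <- 33L
  half_line[line_row + (-1:1), seq_len(end_col)] <- 1
  attr(half_line, "end_col") <- end_col
  attr(half_line, "line_row") <- line_row

  two_blob <- matrix(0, 45, 45)
  asym <- 2
  g <- function(c0) outer(exp(-((1:45) - 23)^2 / 18),
                          exp(-((1:45) - c0)^2 / 18))
  two_blob <- g(12) + asym * g(34)
  attr(two_blob, "asymmetry") <- asym

  list(uniform = uniform, half_line = half_line, two_blob = two_blob)
}
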