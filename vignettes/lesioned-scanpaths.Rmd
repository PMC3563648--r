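---
title: "Simulating hemianopic and hemineglect scanpaths with hemiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hemianopic and hemineglect scanpaths with hemiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model in one paragraph

`hemiscan` implements a biased-competition neurodynamic model of covert
attention and eye movements. A 1000 x 1000 px scene (1 degree = 11 px) is
sampled through a 495 x 495 px retina centred on the current fixation. A
V1-like front end computes orientation- and colour-selective maps at two
spatial scales plus end-stopped line-termination detectors. The ventral
stream pools these into 33 x 33 extrastriate feature maps — optionally
coupled by collinear lateral connections that let activity propagate along a
contour — and into object units that compete under a frontal search bias.
The dorsal stream maintains a 45 x 45 retinotopic parietal priority map (one
cell per degree) integrating stimulus drive, scene-based novelty (inhibition
of return), and task biases; its peak selects the next saccade target.
Unilateral lesions are applied either to V1 (hemianopia: the blind
hemifield's input is zeroed) or to the parietal map (hemineglect: a step or
gradient attenuation of priority).

## A healthy bisection trial

```{r}
library(hemiscan)

line <- generate_line_stimulus()
line

cfg <- trial_config("bisection", bisection_weight = 4.5, seed = 1)
trial <- run_trial(line, cfg)
summary(trial)
trial$bisection
```

The trial starts from an imposed central fixation, scans toward the line
ends, accumulates left- and right-end estimates in a ledger (each tagged
with its provenance: a veridical `endstop` detection or a coarser
`cortical_extent` readout from the parietal map), and reports the midpoint.
A healthy observer bisects within a fraction of a degree of the true centre
(500 px).

```{r}
head(trial$ledger)
```

## Lesions

Lesions are declared with `lesion_spec()` and passed to `trial_config()`:

```{r}
v1_lesion  <- lesion_spec("v1", "left_field", "step")
step_lesion <- lesion_spec("parietal", "left_field", "step")
grad_lesion <- lesion_spec("parietal", "left_field", "gradient")
```

An acute left hemianopia produces a large *rightward* (ipsilesional)
bisection error: the left half of the line is simply invisible from a
central fixation, so early evidence places the "left end" far too far to
the right.

```{r}
acute <- run_trial(line, trial_config("bisection", lesion = v1_lesion,
                                      bisection_weight = 4.5, seed = 1))
acute$bisection
```

A parietal step lesion also errs rightward, even though V1 is intact: the
lesioned priority map cannot represent — or orient to — the contralesional
line half, so extent estimates are truncated at the representational border.

```{r}
neglect <- run_trial(line, trial_config("bisection", lesion = step_lesion,
                                        bisection_weight = 4.5, seed = 1))
neglect$bisection
```

## Compensation

Two compensation mechanisms can be enabled via the `compensation` argument:

* `"spatial"` — a contralesional spatial attention bias (a ramp added to the
  parietal map) that drives exploration into the blind/neglected hemifield;
* `"lateral"` — strengthened collinear lateral connections in extrastriate
  cortex, allowing a contour to *complete* into the blind field, which is
  the model of chronic hemianopia;
* `"both"` — both at once.

Chronic hemianopia (lateral compensation) famously *overshoots*: the
completed contour makes the patient bisect slightly **left** of centre
(a contralesional error), unlike acute hemianopia:

```{r}
chronic <- run_trial(line, trial_config("bisection", lesion = v1_lesion,
                                        compensation = "lateral",
                                        bisection_weight = 3, seed = 1))
chronic$bisection
```

In contrast, the same compensation machinery does **not** rescue a parietal
lesion: the ipsilesional error persists because the deficit is in the
priority representation itself, not in the sensory input:

```{r}
run_trial(line, trial_config("bisection", lesion = step_lesion,
                             compensation = "both",
                             bisection_weight = 4.5, seed = 1))$bisection
```

## Conjunction search

The same machinery performs conjunction search (a red vertical bar among
red horizontal, green vertical and green horizontal distractors):

```{r}
scene <- generate_search_scene(seed = 1)
search <- run_trial(scene, trial_config("search", seed = 1))
summary(search)
pct_fixations_on_stimuli(search, scene)
```

A hemianopic searcher given the spatial compensation bias explores the blind
hemifield, at the cost of many fixations on blank regions:

```{r}
hemi <- run_trial(scene, trial_config("search", lesion = v1_lesion,
                                      compensation = "spatial", seed = 1))
pct_fixations_on_stimuli(hemi, scene)
```

## The full bisection experiment

`make_table1_grid()` builds the canonical 13-cell design (control; chronic
hemianopia at four bisection-task weights; compensated parietal step and
gradient lesions at four weights each) and `run_experiment()` executes it:

```{r, eval = FALSE}
spec <- make_table1_grid(trials_per_cell = 10)
res <- run_experiment(spec)
res$table
```

(Not evaluated here: the grid is 130 trials. The same table is produced by
the command-line tool: `inst/scripts/hemiscan experiments run table1 --out DIR`.)

## Reading the outputs

* `trial$fixations` — the scanpath (`x`, `y`, `onset_ms`, `duration_ms`);
* `trial$ledger` — the line-end estimate ledger (bisection task);
* `trial$bisection` — `bisection_x`, `offset_deg` (positive = rightward),
  `offset_pct` (percentage of half line length);
* `write_scanpaths_csv()` / `write_bisections_csv()` — CSV export;
* `fixation_density()`, `pct_fixations_on_stimuli()`, `strays_off_line()` —
  summary metrics.
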