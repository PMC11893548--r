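# affectdyn

Affect dynamics — how a person moves between emotional states over time —
carries clinical signal: moderate emotional variability tracks psychological
health, while rigidity or extreme lability accompanies conditions such as
eating, mood and anxiety disorders. `affectdyn` measures affect dynamics
*physiologically*, at the level of a single patient, from a heart-rate
recording taken while affective transitions are experimentally induced with
standardized emotional images.

The method, end to end:

1. **Schedule.** A 26-minute block design: 13 blocks × 120 s (12 images ×
   10 s each), whose block order is an Eulerian circuit over the four
   circumplex quadrants — stress (A), engagement (B), boredom (C),
   relaxation (D) — so each of the 12 directed transitions between distinct
   quadrants occurs exactly once. Stimuli are assigned to quadrants from
   normative valence/arousal ratings (high > 6, low < 4 on the 9-point SAM
   scale).
2. **Signal.** RR intervals are read, artifact beats (ectopic, missed) are
   corrected by a threshold rule against the local median, and RMSSD — the
   root mean square of successive RR differences,
   `sqrt(mean((RR[i+1] - RR[i])^2))` — is computed in sixteen 30-s windows:
   one straddling each block boundary (120k ± 15 s) and one inside the
   first block of each state (60 ± 15 s).
3. **Markovization.** The 4×4 window RMSSD matrix is row-relativized,
   `P[i,j] = RMSSD[i,j] / sum(RMSSD[i,])`, into a row-stochastic transition
   matrix: descriptive indexes (vertical / horizontal / oblique / self
   groups) read directly off `P`, and the predictive steady state `π`
   (`πP = π`) is computed both by 10-step power iteration from the uniform
   initial vector and by the left-eigenvector method.
4. **Report.** Tidy tibbles, ggplot2 plots, a JSON/CSV report and a
   Graphviz DOT transition graph with the field's colour conventions
   (vertical green, horizontal yellow, oblique orange, self gray).

A synthetic RR-series generator with window-specific target variability
(plus ectopic/missed-beat artifact injection) makes the whole pipeline
testable without any recording.

## Worked example

Simulate a session whose ground-truth variability profile is proportional
to a published clinical matrix, then recover it:

```r
library(affectdyn)

sch  <- generate_schedule(seed = 1)        # Eulerian circuit over A-D
sch$states
#>  [1] "A" "B" "D" "C" "B" "A" "C" "D" "B" "C" "A" "D" "A"

w    <- place_windows(sch)                 # 16 windows of 30 s
prof <- variability_profile(example_case_matrix() * 100)
rr   <- simulate_rr(sch, w, prof, seed = 7)

writeLines(format(rr$rr_ms, trim = TRUE), "rr.txt")
write_schedule(sch, "schedule.json")
report <- run_pipeline("rr.txt", "schedule.json", correction_level = "none")
report
#> Affect-dynamics analysis report
#> Transition matrix (rows = from, cols = to):
#>     to
#> from    A    B    C    D
#>    A 0.19 0.19 0.30 0.32
#>    B 0.23 0.22 0.21 0.34
#>    C 0.16 0.55 0.14 0.15
#>    D 0.16 0.24 0.39 0.21
#> Artifacts: 0 beat(s) corrected at level 'none'
#> Steady state (power, 10 steps): A=0.19 B=0.30 C=0.25 D=0.25
```

The recovered matrix sits within Monte-Carlo noise (~0.03 per cell) of the
profile's target. Each row is read clinically: from boredom (row C) this
simulated patient directs 55% of transition-linked cardiac reactivity
toward engagement (C→B), i.e. is most likely to exit boredom upward in
arousal. Results are tidy:

```r
tidy(report$transition_matrix)
#> # A tibble: 16 × 5   (from, to, pair, group, prob)
#> 1 A     A     AA    self       0.191
#> 2 A     B     AB    horizontal 0.190
#> 3 A     C     AC    vertical   0.299
#> ...

tidy(report$steady_eigen)
#> # A tibble: 4 × 2
#>   state  prob
#> 1 A     0.186
#> 2 B     0.305
#> 3 C     0.255
#> 4 D     0.254
```

After ten (indeed, infinitely many) hypothetical shifts the simulated
patient is most likely to be found engaged (B, 0.30), the long-run
signature of the matrix it was simulated from. `autoplot()` renders the
matrix heatmap, tachogram and steady-state bars; `export_graph()` writes
the DOT transition graph.

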