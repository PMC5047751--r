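#!/usr/bin/env Rscript
# Simulate two synthetic recording days and write them as text sessions:
# a "demo" day with injected cross-activation at the study's default census
# (half of the running-active cells re-expressed in the box with preserved
# order), and a "control" day with zero injected overlap. Each day has one
# Track session and Pre-/Post-box sessions, plus ground-truth sidecars.
library(crossact)

out <- "results/sessions"
for (day in list(list(name = "demo_day", f = 0.5, seed = 20260101L),
                 list(name = "control_day", f = 0, seed = 20260102L))) {
  cfg <- sim_config(cross_activation_fraction = day$f, seed = day$seed)
  pop <- assign_cell_population(cfg)
  track <- generate_track_session(pop, cfg)
  pre <- generate_box_session(pop, cfg, "pre_box")
  post <- generate_box_session(pop, cfg, "post_box")
  for (ses in list(track, pre, post))
    write_session(ses, file.path(out, day$name, ses$id))
  lab <- table(pop$labels)
  cat(sprintf("%s (overlap %.0f%%): %d cells -> %s\n", day$name, 100 * day$f,
              cfg$n_cells,
              paste(names(lab), lab, sep = "=", collapse = ", ")))
}
cat("sessions written under", out, "\n")
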