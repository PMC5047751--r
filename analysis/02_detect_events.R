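#!/usr/bin/env Rscript
# Detect behavioural events in the simulated sessions: laps on the track,
# rotation events and stop periods in the box, and summarise box behaviour.
library(crossact)

rows <- list(); beh <- list()
for (day in c("demo_day", "control_day")) {
  track <- read_session(file.path("results/sessions", day, "track"))
  laps <- detect_lap_events(track$position)
  rows[[length(rows) + 1]] <- data.frame(day = day, session = "track",
                                         type = "lap", label = laps$trajectory,
                                         start_s = laps$start_s, end_s = laps$end_s)
  for (sid in c("pre_box", "post_box")) {
    box <- read_session(file.path("results/sessions", day, sid))
    rot <- detect_rotation_events(box$position)
    stp <- detect_stop_periods(box$position)
    rows[[length(rows) + 1]] <- data.frame(day = day, session = sid,
                                           type = "rotation", label = rot$direction,
                                           start_s = rot$start_s, end_s = rot$end_s)
    if (nrow(stp))
      rows[[length(rows) + 1]] <- data.frame(day = day, session = sid,
                                             type = "stop", label = "",
                                             start_s = stp$start_s, end_s = stp$end_s)
    b <- behavior_summary(box$position, rot)
    beh[[length(beh) + 1]] <- cbind(day = day, session = sid, b)
    cat(sprintf("%s/%s: %d rotation events (mean %.1f s), %.0f%% facing opening\n",
                day, sid, b$n_rotation_events, b$mean_rotation_duration_s,
                b$pct_time_facing_opening))
  }
  cat(sprintf("%s/track: %d laps\n", day, sum(rows[[1]]$type == "lap")))
}
ev <- do.call(rbind, rows)
write.table(ev, "results/events.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, beh), "results/behavior_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/events.tsv and results/behavior_summary.tsv\n")
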