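#!/usr/bin/env Rscript

# Simulate a small cohort to disk: stimulus + press events tables and
# float32 source waveforms per sequence, following the session structure
# (blocks of five sequences: two neutral, attempt integration, attend high,
# attend low; delta-f alternating between 4 and 6 semitones).
#
# The on-disk cohort is deliberately small (4 participants, 2 blocks); the
# statistical analyses in the later scripts resimulate in memory at the
# sizes they need.

library(bistream)

cfg <- cohort_config(n_participants = 4, n_blocks = 2, seed = 20260901)
out <- "results/cohort"
unlink(out, recursive = TRUE)
generate_cohort(cfg, out, overwrite = TRUE)
write_config(cfg, "results/cohort_config.json")

# summarize what was written
dirs <- list.dirs(out, recursive = FALSE)
rows <- lapply(dirs, function(d) {
  ev_files <- list.files(d, pattern = "events\\.tsv$", full.names = TRUE)
  n_press <- sum(vapply(ev_files, function(f) {
    sum(read_events(f)$event_type == "press")
  }, numeric(1)))
  data.frame(participant = basename(d), sequences = length(ev_files),
             total_presses = n_press)
})
summary <- do.call(rbind, rows)
write.table(summary, "results/dataset_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(summary)
cat("Each sequence:", cfg$n_triplets, "triplets =",
    cfg$n_triplets * 0.6, "s of stimulation\n")
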