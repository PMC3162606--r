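#!/usr/bin/env Rscript

# Stage 1: the imaging pipeline on synthetic ground truth.
#
# Real SCN bioluminescence movies are not distributed with this project,
# so the pipeline is exercised on synthetic recordings whose cell-scale
# phase jitter (0.017 rad/2pi), wave velocity (0.2 mm/h) and defect
# structure are known exactly.  This stage checks that envelope-based
# phase extraction recovers all three, and records the per-movie
# synchronization index R.
#
# Runtime: ~1 min.  Outputs: results/01_pipeline_recovery.csv

library(scnwave)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

seeds <- 1:5
rows <- lapply(seeds, function(s) {
  spec <- synthetic_movie_spec(seed = s)          # 40 x 40 px, 120 h, 0.5 h
  mv <- generate_movie(spec)
  pf <- extract_phase_amplitude(mv$movie)
  st <- movie_sync_stats(pf)                      # 7 x 7 detrending window
  wv <- wave_velocity(pf, line = list(type = "row", index = 1))
  data.frame(seed = s,
             delta_true_rad_per_2pi = mv$truth$true_delta,
             delta_recovered_rad_per_2pi = st$delta_mean,
             delta_sd_over_frames = st$delta_sd,
             velocity_true_mm_per_h = mv$truth$true_velocity,
             velocity_recovered_mm_per_h = wv$velocity,
             R_mean = st$R_mean,
             fluctuation_minutes = phase_to_time(st$delta_mean, 24) * 60)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "01_pipeline_recovery.csv"),
          row.names = FALSE)

cat("Recovered vs true, averaged over", length(seeds), "movies:\n")
cat(sprintf("  Delta: %.4f vs %.4f rad/2pi (%.1f min of a 24 h cycle)\n",
            mean(tab$delta_recovered_rad_per_2pi),
            mean(tab$delta_true_rad_per_2pi),
            mean(tab$fluctuation_minutes)))
cat(sprintf("  velocity: %.3f vs %.3f mm/h\n",
            mean(tab$velocity_recovered_mm_per_h), 0.2))
cat(sprintf("  synchronization index R: %.3f\n", mean(tab$R_mean)))

run_manifest(config = unclass(synthetic_movie_spec(seed = seeds[1])),
             seeds = seeds,
             files = file.path(out_dir, "01_pipeline_recovery.csv"),
             path = file.path(out_dir, "01_manifest.json"))
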