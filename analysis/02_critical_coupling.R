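#!/usr/bin/env Rscript

# Stage 2: critical coupling of the lattice model.
#
# Sweeps the coupling constant K over the study grid for the defect-free
# surface (gamma = 0) and for a surface with half the cells deleted
# (gamma = 0.5), classifies every run as synchronized (bounded Delta,
# fully frequency-entrained) or not, and reports the smallest coupling
# that sustains synchronization, K_c, for each defect level.
#
# Runtime: ~6 min (110 simulations of a 20 x 20 x 10 lattice to t = 500).
# Outputs: results/02_coupling_sweeps.csv, results/02_kc.csv

library(scnwave)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1

template <- sim_config(K = 0.1, seed = seed)
grid_K <- c(0, 0.02, 0.04, 0.045, 0.05, 0.07, 0.09, 0.12, 0.16, 0.2, 0.3)

kc_g0 <- estimate_kc(template, grid_K, replicates = 5,
                     refine_step = 0.005, base_seed = seed)

template_g5 <- template
template_g5$gamma <- 0.5
kc_g5 <- estimate_kc(template_g5, c(0.05, 0.07, 0.09, 0.12, 0.16, 0.2, 0.3),
                     replicates = 5, refine_step = 0.01,
                     base_seed = seed + 1)

tab <- rbind(cbind(gamma = 0, kc_g0$sweep$summary),
             cbind(gamma = 0.5, kc_g5$sweep$summary))
names(tab)[names(tab) == "value"] <- "K"
names(tab)[names(tab) == "delta_mean"] <- "steady_delta_rad_per_2pi"
write.csv(tab, file.path(out_dir, "02_coupling_sweeps.csv"),
          row.names = FALSE)
write.csv(data.frame(gamma = c(0, 0.5), Kc = c(kc_g0$Kc, kc_g5$Kc)),
          file.path(out_dir, "02_kc.csv"), row.names = FALSE)

cat(sprintf("K_c = %.3f for a defect-free surface\n", kc_g0$Kc))
cat(sprintf("K_c = %.3f with half the surface deleted\n", kc_g5$Kc))
cat("Steady-state Delta declines roughly as 1/K on the synchronized branch;\n")
cat("see 02_coupling_sweeps.csv for the full curves.\n")

run_manifest(config = unclass(template), seeds = seed,
             files = file.path(out_dir, c("02_coupling_sweeps.csv", "02_kc.csv")),
             path = file.path(out_dir, "02_manifest.json"))
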