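#!/usr/bin/env Rscript

# Stage 5: sensitivity to the pacemaker frequency advantage.
#
# The wave is initiated by a plane of cells running faster than the rest
# of the tissue.  This stage compares a 4 percent advantage with a 2.7
# percent one: both produce a wave, the faster pacemaker a steeper
# steady phase gradient, while the fluctuation statistic Delta(K) is
# nearly unchanged - the wave and the roughness are set by different
# parameters.
#
# Runtime: ~4 min.  Outputs: results/05_pacemaker_variant.csv

library(scnwave)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1
template <- sim_config(K = 0.1, seed = seed)

pv <- pacemaker_variant(template, boosts = c(1.04, 1.027),
                        K_values = c(0.07, 0.12, 0.22),
                        replicates = 3, base_seed = seed)

tab <- do.call(rbind, lapply(names(pv$sweeps), function(b) {
  s <- pv$sweeps[[b]]$summary
  data.frame(boost = as.numeric(b), K = s$value,
             steady_delta_rad_per_2pi = s$delta_mean,
             delta_sd = s$delta_sd, majority = s$majority)
}))
tab <- merge(tab, pv$gradients, by = c("boost", "K"))
names(tab)[names(tab) == "gradient"] <- "mean_gradient_cycles_per_site"
write.csv(tab, file.path(out_dir, "05_pacemaker_variant.csv"),
          row.names = FALSE)

print(tab, row.names = FALSE)
g40 <- tab$mean_gradient_cycles_per_site[tab$boost == 1.04 & tab$K == 0.12]
g27 <- tab$mean_gradient_cycles_per_site[tab$boost == 1.027 & tab$K == 0.12]
cat(sprintf("\nAt K = 0.12 the steady x-gradient is %.4f cycles/site at +4%%\n", g40))
cat(sprintf("vs %.4f cycles/site at +2.7%%: the faster pacemaker steepens the wave.\n", g27))
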