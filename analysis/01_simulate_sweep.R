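#!/usr/bin/env Rscript
# Monte Carlo dose/feasibility study: contrast-induced dR2 (spin echo) and
# dR2* (gradient echo) over random-cylinder substrates across vessel radii
# 2-10 um and blood volume fractions 2/4/6%, with the derived VSI, Q and
# MVD compared against the known substrate truth.
#
# Reduced desk scale: 128^3 grid at 1 um, 2e5 walkers, 3 repetitions per
# condition (a few minutes on one CPU). Writes results/sweep_*.csv and a
# summary figure.

library(vsimri)
suppressPackageStartupMessages(library(ggplot2))

seed <- as.integer(Sys.getenv("SWEEP_SEED", "1"))
dir.create("results", showWarnings = FALSE)

message("running radius x Bvf sweep (this takes a few minutes) ...")
sw <- run_sweep(radii = c(2, 4, 6, 8, 10), bvfs = c(0.02, 0.04, 0.06),
                sim = reduced_sim_profile(), seed = seed)

write.csv(sw$per_rep, "results/sweep_per_rep.csv", row.names = FALSE)
write.csv(sw$summary, "results/sweep_summary.csv", row.names = FALSE)

s <- sw$summary
p1 <- ggplot(s, aes(radius_um, d_r2_mean, colour = factor(bvf * 100))) +
  geom_line() + geom_point() +
  geom_errorbar(aes(ymin = d_r2_mean - d_r2_sd, ymax = d_r2_mean + d_r2_sd),
                width = 0.2) +
  labs(x = "vessel radius (um)", y = expression(Delta * R[2] ~ (s^-1)),
       colour = "Bvf (%)") + theme_bw()
p2 <- ggplot(s, aes(radius_um, d_r2star_mean, colour = factor(bvf * 100))) +
  geom_line() + geom_point() +
  labs(x = "vessel radius (um)", y = expression(Delta * R[2]^"*" ~ (s^-1)),
       colour = "Bvf (%)") + theme_bw()
p3 <- ggplot(s, aes(radius_um, vsi_um, colour = factor(bvf * 100))) +
  geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
  geom_line() + geom_point() +
  labs(x = "true vessel radius (um)", y = "derived VSI (um)",
       colour = "Bvf (%)") + theme_bw()
p4 <- ggplot(s, aes(true_density_mm2, mvd_mm2, colour = factor(bvf * 100))) +
  geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
  geom_point() + scale_x_log10() + scale_y_log10() +
  labs(x = expression("true cylinder density" ~ (mm^-2)),
       y = expression("derived MVD" ~ (mm^-2)), colour = "Bvf (%)") +
  theme_bw()
ggsave("results/fig_sweep.pdf",
       cowplot::plot_grid(p1, p2, p3, p4, labels = "AUTO"),
       width = 9, height = 7)

# narrative summary
for (b in unique(s$bvf)) {
  ss <- s[s$bvf == b, ]
  message(sprintf(
    "Bvf %.0f%%: dR2 falls %.1f -> %.1f 1/s from r=2 to r=10 um; dR2* stays %.0f +/- %.0f 1/s; VSI tracks radius (%.1f..%.1f um)",
    b * 100, max(ss$d_r2_mean), min(ss$d_r2_mean),
    mean(ss$d_r2star_mean), sd(ss$d_r2star_mean),
    min(ss$vsi_um), max(ss$vsi_um)))
}
message(sprintf(
  "small radii (2-4 um) at Bvf 2%%: dR2 = %.1f 1/s (spin-echo plateau used for dosing)",
  mean(s$d_r2_mean[s$bvf == 0.02 & s$radius_um <= 4])))
message("wrote results/sweep_per_rep.csv, results/sweep_summary.csv, results/fig_sweep.pdf")
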