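#!/usr/bin/env Rscript

# Step 4 — quality-control figures from the tables written by steps 2 and 3:
# the fitted calibration curve with its per-cell points, the per-condition
# pH ECDFs, and the dose-response of the measured current inhibition.

suppressMessages({
  library(lysoratio)
  library(ggplot2)
})

indir <- "results/imaging_wt"
if (!file.exists(file.path(indir, "calibration_points.csv"))) {
  stop("run analysis/02_quantify_ph.R first")
}
figdir <- "results/figures"
dir.create(figdir, recursive = TRUE, showWarnings = FALSE)

pts <- read.csv(file.path(indir, "calibration_points.csv"))
cal <- jsonlite::read_json(file.path(indir, "calibration.json"),
                           simplifyVector = TRUE)
curve <- structure(
  list(r_min = cal$r_min, r_max = cal$r_max, ph50 = cal$ph50,
       slope_h = cal$slope_h, valid_range = cal$valid_range),
  class = c("calibration_curve", "ratio_ph_law")
)
grid <- data.frame(ph = seq(cal$valid_range[1], cal$valid_range[2],
                            length.out = 200))
grid$ratio <- ratio_from_ph(curve, grid$ph)

p1 <- ggplot(pts, aes(buffer_ph, cell_mean_ratio)) +
  geom_point(shape = 1, size = 2) +
  geom_line(data = grid, aes(ph, ratio), colour = "firebrick") +
  labs(x = "buffer pH", y = "488/445 ratio",
       title = sprintf("Four-parameter calibration (pH50 = %.2f)", cal$ph50)) +
  theme_classic()
ggsave(file.path(figdir, "calibration_curve.pdf"), p1, width = 4, height = 3)

ecdf_tab <- read.csv(file.path(indir, "ecdf.csv"))
p2 <- ggplot(ecdf_tab, aes(ph, fraction, colour = condition)) +
  geom_step() +
  labs(x = "lysosomal pH", y = "fraction of lysosomes below",
       title = "Cumulative distribution of single-lysosome pH") +
  theme_classic()
ggsave(file.path(figdir, "ph_ecdf.pdf"), p2, width = 4.5, height = 3)

met <- read.csv("results/ephys/ephys_metrics.csv")
dr <- jsonlite::read_json("results/ephys/dose_response.json",
                          simplifyVector = TRUE)
cgrid <- data.frame(conc = exp(seq(log(1), log(300), length.out = 200)))
cgrid$inh <- dr$floor + (dr$ceiling - dr$floor) * cgrid$conc^dr$hill_n /
  (cgrid$conc^dr$hill_n + dr$ec50^dr$hill_n)
p3 <- ggplot(met[met$conc_um > 0, ],
             aes(conc_um, 1 - max_ratio)) +
  geom_jitter(width = 0.02, shape = 1) +
  geom_line(data = cgrid, aes(conc, inh), colour = "firebrick") +
  scale_x_log10() +
  labs(x = "pipette concentration (uM)", y = "fractional inhibition",
       title = sprintf("Dose-response (EC50 = %.0f uM)", dr$ec50)) +
  theme_classic()
ggsave(file.path(figdir, "dose_response.pdf"), p3, width = 4, height = 3)

message("Figures written under ", figdir)
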