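#!/usr/bin/env Rscript
# Stage 6: figures — Kaplan-Meier curves with the selected parametric
# extrapolations for OS and TTNT, and state-occupancy traces per
# structure with the brain-metastasis states folded into their phases.

library(oncostm)

out <- "results"
sel <- jsonlite::read_json(file.path(out, "selected_curves.json"),
                           simplifyVector = FALSE)
curve <- function(endpoint, arm) {
  s <- sel[[paste(endpoint, arm, sep = ":")]]
  survmodel(s$family, unlist(s$params))
}

png(file.path(out, "fig_km_fits.png"), width = 1400, height = 1000, res = 150)
op <- par(mfrow = c(2, 2))
for (ep in c("os", "ttnt")) {
  d <- read.csv(file.path(out, sprintf("endpoint_%s.csv", ep)))
  d$event <- as.logical(d$event)
  for (arm in c("A", "B")) {
    m <- curve(ep, arm)
    plot_km_fit(d[d$arm == arm, ], stats::setNames(list(m), m$family),
                main = sprintf("%s, arm %s", toupper(ep), arm), xmax = 2556.75)
  }
}
par(op); dev.off()

read_trace <- function(structure, arm) {
  df <- read.csv(file.path(out, sprintf("trace_%s_%s.csv", structure, arm)),
                 check.names = FALSE)
  states <- setdiff(names(df), c("cycle", "time_days"))
  structure(list(structure = toupper(structure), time = df$time_days,
                 cycle_days = 21, states = states,
                 occupancy = as.matrix(df[states]), tunnels = NULL,
                 events = c()), class = "cohort_trace")
}
png(file.path(out, "fig_occupancy.png"), width = 1500, height = 1000, res = 150)
op <- par(mfrow = c(2, 3))
for (arm in c("A", "B")) {
  for (st in c("psm", "stm3", "stm5")) {
    tr <- read_trace(st, arm)
    plot(tr, combine_bm = TRUE)
    title(sub = sprintf("arm %s", arm))
  }
}
par(op); dev.off()
cat("wrote fig_km_fits.png and fig_occupancy.png\n")
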