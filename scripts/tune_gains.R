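#!/usr/bin/env Rscript
# Re-derives control parameters of the kind shipped in tuned_gains():
# per-variant mixed-integer GA (movement criterion) warm-started from the
# published reference gains, followed by Nelder-Mead polish. Run from the
# repository root:
#
#   Rscript scripts/tune_gains.R [--out tuned_gains.csv]
#
# Takes a few hours on one CPU. The table shipped in R/model.R is the best
# result of a multi-restart campaign of exactly these runs (population
# 32-48, 40-80 generations, seeds 20, 21, 40-42, polish budget 500-800,
# warm-start pools grown across restarts); a single run of this script
# reproduces its quality for the well-behaved variants, while FMAX+O1
# benefits from the additional restarts (see the package vignette on
# plant-specific optima).
suppressPackageStartupMessages(library(reacharm))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 2 && args[1] == "--out") args[2] else "tuned_gains.csv"

plan <- data.frame(
  variant = muscle_variants(),
  tau_steps_max = c(10L, 10L, 10L, 30L, 30L))

rows <- NULL
for (i in seq_len(nrow(plan))) {
  v <- plan$variant[i]
  warm <- list(
    reference_gains(v, "stabilisation"),
    reference_gains(v, "movement"),
    control_params(c(5190.51, 5031.46, 2621.26), c(79.52, 0.74, 1.28), 0),
    control_params(c(500, 150, 10), c(60, 15, 0.5), 0))
  warm <- lapply(warm, function(w)
    control_params(w$Kp, w$Kv, min(w$tau_steps, plan$tau_steps_max[i]) * 0.002))
  pr <- optimization_problem(v, "movement",
                             tau_steps_max = plan$tau_steps_max[i],
                             pop_size = 40L, generations = 50L,
                             seed = 40L, init = warm)
  r <- optimize_gains(pr, polish = TRUE, polish_budget = 600L)
  res <- evaluate_controller(arm_model(v), r$best)
  message(sprintf("%s: e_st_bar %.3f um, e_mv_bar %.3f um, tau %d ms",
                  v, res$e_st_bar * 1e6, res$e_mv_bar * 1e6,
                  r$best$tau_steps * 2))
  rows <- rbind(rows, data.frame(
    variant = v,
    Kp1 = r$best$Kp[1], Kp2 = r$best$Kp[2], Kp3 = r$best$Kp[3],
    Kv1 = r$best$Kv[1], Kv2 = r$best$Kv[2], Kv3 = r$best$Kv[3],
    tau_ms = r$best$tau * 1000,
    e_st_mm = res$e_st_bar * 1000, e_mv_mm = res$e_mv_bar * 1000))
}
write.csv(rows, out, row.names = FALSE)
message("written: ", out)
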