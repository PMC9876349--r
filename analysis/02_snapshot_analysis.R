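#!/usr/bin/env Rscript
# Per-spheroid snapshot analysis on synthetic end-point measurements:
# estimates of the critical radius, oxygen consumption rate, inhibition
# threshold pressure and inhibition-onset radius, plus the measured vs
# predicted hypoxic-radius check.

library(spheroidadapt)
dir.create("results", showWarnings = FALSE)

constants <- oxygen_constants()
sets <- list(normoxia = ground_truth_bundle("normoxia_like"),
             hypoxia = ground_truth_bundle("hypoxia_like"))

all_snaps <- list()
for (cond in names(sets)) {
  b <- sets[[cond]]
  tab <- filter_outliers(generate_dataset(b$params, b$design,
                                          constants = constants))
  p_inf <- b$design$p_inf[[1]]
  snaps <- snapshot_estimates_table(tab, p_inf, constants)
  snaps$condition <- cond
  all_snaps[[cond]] <- snaps
  ok <- is.finite(snaps$R_c)
  cat(sprintf("%s: median R_c = %.1f um (truth %.0f), median Rbar = %.1f um (truth %.0f), n(phase iii) = %d\n",
              cond, median(snaps$R_c[ok]), b$params$R_c,
              median(snaps$Rbar, na.rm = TRUE), b$params$Rbar, sum(ok)))

  # measured vs predicted hypoxic radius
  pred <- vapply(seq_len(nrow(tab)), function(i) {
    if (!is.finite(snaps$R_c[i])) return(NA_real_)
    oxy <- oxygen_params(p_inf = p_inf, R_c = snaps$R_c[i])
    predict_hypoxic_radius(tab$R_o_um[i], tab$R_n_um[i], oxy,
                           constants$p_hyp)
  }, numeric(1))
  keep <- is.finite(pred) & is.finite(tab$R_p_um) & tab$R_p_um > 0
  if (sum(keep) > 3) {
    r2 <- 1 - sum((tab$R_p_um[keep] - pred[keep])^2) /
      sum((tab$R_p_um[keep] - mean(tab$R_p_um[keep]))^2)
    cat(sprintf("  measured vs predicted R_p: R^2 = %.3f on %d spheroids\n",
                r2, sum(keep)))
  }
}
snaps <- do.call(rbind, all_snaps)
write.csv(snaps, "results/snapshot_estimates.csv", row.names = FALSE)
cat("wrote results/snapshot_estimates.csv\n")
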