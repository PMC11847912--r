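#!/usr/bin/env Rscript
# Stage 4: threshold sensitivity analysis — sweep the rule-out probability
# cut-off for both automated strategies and track the failure rate and the
# staffing burden (annual FTE per 1000-patient caseload).

suppressMessages(library(ssitriage))

r <- read_responses("results/cohort/responses.csv")
predictions <- read_predictions("results/predictions.csv")
sm <- staffing_model()
grid <- seq(0, 0.5, by = 0.025)

sweep <- rbind(
  threshold_sweep(r, predictions, "hybrid", grid, sm, nrow(r)),
  threshold_sweep(r, predictions, "full_auto", grid, sm, nrow(r)))
write.csv(sweep, "results/threshold_sweep.csv", row.names = FALSE)

at20 <- subset(sweep, abs(threshold - 0.2) < 1e-9)
cat("at the exemplar 20% threshold:\n")
print(at20[, c("strategy", "n_clinician_reviewed", "failure_rate",
               "staff_hours", "fte_per_caseload")], digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  p <- plot_threshold_sweep(sweep)
  ggplot2::ggsave("results/figures/threshold_sweep.png", p,
                  width = 8, height = 4, dpi = 150)
  cat("figure written to results/figures/threshold_sweep.png\n")
}
cat("sweep written to results/threshold_sweep.csv\n")
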