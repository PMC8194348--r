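# Stage 2: synthetic participants.
#
# Simulates the two-session study over the designed stimuli: 17 Familiar and
# 21 Unfamiliar learners, bridge-session accuracy at the configured cell
# means (34.03 / 16.16 percent), terminus accuracy conditioned on each
# simulated learner's realized bridge-word knowledge, letters-correct drawn
# Binomial(5, p), and responses realized as strings so they pass through the
# same scorer as real data. Writes responses.csv and ground_truth.json.
source("analysis/00_common.R")

cfg <- pipeline_config()
design <- run_design(cfg)   # deterministic: same seed as stage 1
study <- run_simulate(cfg, design)

r <- study$responses
cat("\n-- simulated study --\n")
cat("participants:", length(unique(r$participant)), " trials:", nrow(r), "\n")
cat("observed cell means (percent):\n")
print(round(xtabs(accuracy ~ condition + session, aggregate(
  accuracy ~ condition + session, r, mean)), 2))
cat("generating cell means implied by the configuration:\n")
print(round(study$truth$cell_means, 2))
cat("share of latent means clamped to [0, 100]:",
    round(study$clamp_fraction, 3), "\n")
cat("wrote", file.path(results_dir, "responses.csv"), "\n")
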