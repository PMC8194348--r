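# Stage 1: similarity-controlled stimulus design.
#
# Builds positional bigram and pooled biphone probability models from the
# bundled 500-word synthetic reference lexicon, scores 10,000 random CVCVC
# candidates on composite English similarity, and selects the two-session
# word lists: 48 onset-balanced high-similarity (Familiar) and 48
# low-similarity (Unfamiliar) bridge words, plus 48 terminus words per
# condition, each a below-threshold substitution neighbor of a distinct
# bridge word, matched on mean bigram/biphone probability (Welch p > 0.1).
# Writes familiar_stimuli.csv, unfamiliar_stimuli.csv, and
# constraint_report.json under results/.
source("analysis/00_common.R")

cfg <- pipeline_config()
design <- run_design(cfg)

rep <- design$report
cat("\n-- stimulus design --\n")
cat("similarity thresholds: high", round(design$model$high_threshold, 3),
    "low", round(design$model$low_threshold, 3), "\n")
cat("terminus matching p-values (all must exceed 0.1):\n")
print(round(rep$matching_p_values, 3))
cat("accepted after", rep$terminus_iterations, "rejection-sampling iterations\n")
cat("meaning A/B matching p-values (all must exceed 0.05):\n")
print(round(rep$meaning_p_values, 3))
cat("novel-word/meaning bigram overlaps per list:\n")
print(rep$bigram_overlap)
cat("wrote", file.path(results_dir, "familiar_stimuli.csv"), "and",
    file.path(results_dir, "unfamiliar_stimuli.csv"), "\n")
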