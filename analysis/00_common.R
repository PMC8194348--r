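# Shared setup for the analysis drivers: bundled synthetic inputs, a common
# output directory, and one master seed for the whole workflow.
suppressMessages(library(bridgelearn))

extdata <- function(file) {
  p <- system.file("extdata", file, package = "bridgelearn")
  if (!nzchar(p)) p <- file.path("inst/extdata", file)  # source-tree fallback
  p
}

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

master_seed <- 1

pipeline_config <- function() {
  run_config(
    lexicon_path = extdata("synthetic_lexicon.tsv"),
    pronunciations_path = extdata("synthetic_pronunciations.tsv"),
    norms_path = extdata("synthetic_norms.csv"),
    outdir = results_dir,
    seed = master_seed)
}
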