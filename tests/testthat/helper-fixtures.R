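# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "bridgelearn")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", file)
  path
}

bundled_lexicon <- function() {
  cached("lexicon", function()
    load_lexicon(extdata("synthetic_lexicon.tsv"), length_filter = 5,
                 min_freq = 0.33))
}

bundled_pron <- function() {
  cached("pron", function() load_pronunciations(extdata("synthetic_pronunciations.tsv")))
}

bundled_norms <- function() {
  cached("norms", function()
    utils::read.csv(extdata("synthetic_norms.csv"), stringsAsFactors = FALSE))
}

# the full stimulus design on the bundled inputs (used across test files)
bundled_design <- function() {
  cached("design", function()
    design_stimuli(bundled_lexicon(), bundled_pron(), bundled_norms(), seed = 1))
}

bundled_model <- function() {
  cached("model", function() similarity_model(bundled_lexicon(), bundled_pron()))
}

# reduced-random-structure spec used for simulation studies: the generator has
# no meaning/form slope variance, so intercepts plus the participant session
# slope match the generative model and keep repeated fits tractable
simulation_spec <- function() {
  model_spec(random = c("(1 + session | participant)", "(1 | form)",
                        "(1 | meaning)"),
             reduction_policy = list(
               c("(1 | participant)", "(1 | form)", "(1 | meaning)"),
               c("(1 | participant)")))
}

toy_bigram_lexicon <- function() lexicon(c("bab", "bob"), c(3, 1))
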