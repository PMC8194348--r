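#' Pipeline run configuration
#'
#' Validated configuration tying the pipeline stages together: input paths,
#' template and threshold settings, list sizes, the simulation and power
#' configurations, and the mandatory master seed (fanned out to per-stage
#' seeds).
#'
#' @param lexicon_path,pronunciations_path,norms_path Input file paths.
#' @param outdir Output directory.
#' @param seed Master integer seed (mandatory).
#' @param word_length Reference word length (default 5).
#' @param min_freq Minimum frequency-per-million for the reference set
#'   (default 0.33).
#' @param n_candidates Generated candidates (default 10000).
#' @param k List size per role and condition (default 48).
#' @param high_pct,low_pct Similarity threshold percentiles (20 and 99).
#' @param max_iters Rejection-sampling cap.
#' @param sim A `sim_config`.
#' @param power A `power_config`.
#' @return A `run_config` list.
#' @export
run_config <- function(lexicon_path, pronunciations_path, norms_path,
                       outdir = ".", seed, word_length = 5, min_freq = 0.33,
                       n_candidates = 10000, k = 48, high_pct = 20,
                       low_pct = 99, max_iters = 10000,
                       sim = sim_config(), power = power_config()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!(high_pct > 0 && high_pct < low_pct && low_pct <= 100))
    stop("need 0 < high_pct < low_pct <= 100")
  if (k < 1 || n_candidates < 1 || word_length < 2)
    stop("sizes must be positive (k, n_candidates, word_length)")
  stopifnot(inherits(sim, "sim_config"), inherits(power, "power_config"))
  structure(list(lexicon_path = lexicon_path,
                 pronunciations_path = pronunciations_path,
                 norms_path = norms_path, outdir = outdir, seed = seed,
                 word_length = word_length, min_freq = min_freq,
                 n_candidates = n_candidates, k = k, high_pct = high_pct,
                 low_pct = low_pct, max_iters = max_iters,
                 sim = sim, power = power),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; `sim` and `power` blocks
#' map to [sim_config()] and [power_config()] arguments. Unknown keys are an
#' error, so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, fn, label) {
    allowed <- setdiff(names(formals(fn)), "")
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("unknown ", label, " key(s): ", paste(unknown, collapse = ", "))
  }
  check_keys(raw, run_config, "config")
  if (!is.null(raw$sim)) {
    check_keys(raw$sim, sim_config, "sim")
    raw$sim <- do.call(sim_config, raw$sim)
  }
  if (!is.null(raw$power)) {
    check_keys(raw$power, power_config, "power")
    raw$power <- do.call(power_config, raw$power)
  }
  do.call(run_config, raw)
}

# run manifest: seed, config hash, input checksums, versions
write_manifest <- function(config, outdir, stage) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(unclass(config), function(x)
    if (is.matrix(x)) as.vector(x) else unclass(x)), tmp, auto_unbox = TRUE,
    force = TRUE, digits = NA)
  inputs <- c(config$lexicon_path, config$pronunciations_path, config$norms_path)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(stage = stage, seed = config$seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   input_md5 = as.list(tools::md5sum(inputs)),
                   package_version = as.character(utils::packageVersion("bridgelearn")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the stimulus-design stage
#'
#' Loads the reference lexicon, pronunciations, and norms named in the
#' configuration, runs [design_stimuli()], and writes the two per-condition
#' stimulus CSVs, the constraint report, and a run manifest to
#' `config$outdir`.
#'
#' @param config A `run_config`.
#' @return The `stimulus_design`, invisibly.
#' @export
run_design <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lex <- load_lexicon(config$lexicon_path, length_filter = config$word_length,
                      min_freq = config$min_freq)
  pron <- load_pronunciations(config$pronunciations_path)
  norms <- utils::read.csv(config$norms_path, stringsAsFactors = FALSE)
  design <- design_stimuli(lex, pron, norms, n_candidates = config$n_candidates,
                           k = config$k, high_pct = config$high_pct,
                           low_pct = config$low_pct, seed = config$seed,
                           max_iters = config$max_iters)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_stimulus_design(design, config$outdir)
  write_manifest(config, config$outdir, "design")
  invisible(design)
}

#' Run the participant-simulation stage
#'
#' Simulates the configured number of synthetic participants over a stimulus
#' design and writes the scored response log (CSV) plus the ground-truth
#' parameters (JSON) and a manifest.
#'
#' @param config A `run_config`.
#' @param design A `stimulus_design` (e.g. from [run_design()]).
#' @return The `simulated_study`, invisibly.
#' @export
run_simulate <- function(config, design) {
  stopifnot(inherits(config, "run_config"), inherits(design, "stimulus_design"))
  sim <- config$sim
  sim$seed <- unname(fan_out_seeds(config$seed, c("design", "simulate"))["simulate"])
  study <- simulate_study(sim, design)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$responses, file.path(config$outdir, "responses.csv"),
                   row.names = FALSE)
  truth <- list(config = lapply(unclass(sim), function(x)
    if (is.matrix(x)) list(values = as.vector(x), dim = dim(x),
                           dimnames = dimnames(x)) else unclass(x)),
    clamp_fraction = study$clamp_fraction,
    cell_means = as.vector(study$truth$cell_means),
    contrasts = study$truth$contrasts)
  jsonlite::write_json(truth, file.path(config$outdir, "ground_truth.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  write_manifest(config, config$outdir, "simulate")
  invisible(study)
}

#' Run the analysis stage
#'
#' Fits the Similarity-by-Session model on the full scored response log and
#' the Similarity-by-Bridge-Knowledge model on the terminus session, computes
#' estimated marginal means and Tukey-corrected pairwise contrasts for both,
#' tabulates bridge-knowledge categories per condition with a chi-square test
#' of independence, and writes JSON and human-readable text reports (both
#' always include the convergence log).
#'
#' @param responses Scored response data frame or path to a response CSV. Must
#'   carry `score`/`accuracy` columns (run scoring first if absent) and
#'   `category` for terminus rows.
#' @param outdir Output directory.
#' @param spec,knowledge_spec Model specifications (defaults: the study's two
#'   models).
#' @return List with both fitted models, EMM and contrast tables, the category
#'   table, and the chi-square result, invisibly.
#' @export
run_analyze <- function(responses, outdir = ".", spec = model_spec(),
                        knowledge_spec = knowledge_model_spec()) {
  if (is.character(responses)) {
    if (!file.exists(responses)) stop("response log not found: ", responses)
    responses <- utils::read.csv(responses, stringsAsFactors = FALSE)
  }
  if (nrow(responses) == 0) stop("response log is empty")
  if (!all(c("score", "accuracy") %in% names(responses)))
    stop("response log is unscored; run score_log() first")
  fit1 <- fit_lmm(responses, spec)
  emm1 <- marginal_means(fit1)
  con1 <- pairwise_contrasts(emm1)

  term <- responses[responses$session == "Terminus" & !is.na(responses$category), ,
                    drop = FALSE]
  fit2 <- NULL; emm2 <- NULL; con2 <- NULL; cat_tab <- NULL; chisq <- NULL
  if (nrow(term)) {
    term$category <- factor(term$category,
                            levels = c("Known", "PartlyKnown", "Unknown"))
    fit2 <- fit_lmm(term, knowledge_spec)
    emm2 <- marginal_means(fit2)
    con2 <- pairwise_contrasts(emm2)
    cat_tab <- category_table(term)
    chisq <- chi_square_independence(cat_tab$counts)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    similarity_session = list(
      coefficients = fit1$coefficients, random_used = fit1$random_used,
      convergence_log = fit1$convergence_log,
      emm = as.data.frame(emm1), contrasts = as.data.frame(con1)),
    similarity_knowledge = if (!is.null(fit2)) list(
      coefficients = fit2$coefficients, random_used = fit2$random_used,
      convergence_log = fit2$convergence_log,
      emm = as.data.frame(emm2), contrasts = as.data.frame(con2)),
    category_table = if (!is.null(cat_tab)) list(
      counts = as.data.frame(cat_tab$counts),
      percent = as.data.frame(round(cat_tab$percent, 1))),
    chi_square = if (!is.null(chisq)) chisq[c("statistic", "df", "p")])
  jsonlite::write_json(payload, file.path(outdir, "model_report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)

  txt <- c("Similarity x Session model",
           "==========================",
           utils::capture.output(print(fit1$coefficients, digits = 4)),
           "", "Convergence log:", paste(" ", fit1$convergence_log),
           "", "Estimated marginal means:",
           utils::capture.output(print(as.data.frame(emm1), digits = 4)),
           "", "Pairwise contrasts (Tukey):",
           utils::capture.output(print(as.data.frame(con1), digits = 4)))
  if (!is.null(fit2)) {
    txt <- c(txt, "", "Similarity x Bridge-Knowledge model",
             "===================================",
             utils::capture.output(print(fit2$coefficients, digits = 4)),
             "", "Convergence log:", paste(" ", fit2$convergence_log),
             "", "Estimated marginal means:",
             utils::capture.output(print(as.data.frame(emm2), digits = 4)),
             "", "Pairwise contrasts (Tukey):",
             utils::capture.output(print(as.data.frame(con2), digits = 4)),
             "", "Bridge-knowledge category table (row %):",
             utils::capture.output(print(round(cat_tab$percent, 1))),
             sprintf("chi-square(%d) = %.2f, p = %.3g", chisq$df,
                     chisq$statistic, chisq$p))
  }
  writeLines(txt, file.path(outdir, "model_report.txt"))
  invisible(list(similarity_session = list(fit = fit1, emm = emm1, contrasts = con1),
                 similarity_knowledge = if (!is.null(fit2))
                   list(fit = fit2, emm = emm2, contrasts = con2),
                 category_table = cat_tab, chi_square = chisq))
}

#' Run the power-analysis stage
#'
#' Runs [power_simulation()] with the configured settings and writes the power
#' curve as CSV plus a manifest.
#'
#' @param config A `run_config`.
#' @return The `power_curve`, invisibly.
#' @export
run_power <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pw <- config$power
  pw$seed <- unname(fan_out_seeds(config$seed, c("design", "simulate", "power"))["power"])
  curve <- power_simulation(pw, config$sim)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(curve, file.path(config$outdir, "power_curve.csv"),
                   row.names = FALSE)
  write_manifest(config, config$outdir, "power")
  invisible(curve)
}
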