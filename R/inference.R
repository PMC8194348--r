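#' Mixed-model specification
#'
#' Describes the fixed and random structure of the study's accuracy models.
#' The default is the Similarity-by-Session model: fixed effects of condition
#' and session plus their interaction, mean-centered covariates (imageability,
#' AoA, familiarity, zipf of the paired meanings), and the maximal random
#' structure (participant intercept + session slope, form intercept, meaning
#' intercept + session and condition slopes). `reduction_policy` is an ordered
#' list of successively simpler random structures tried on non-convergence;
#' every drop is logged in the fit.
#'
#' @param outcome Outcome column (accuracy percent).
#' @param fixed Character vector of fixed factor names (interaction included
#'   whenever there are two).
#' @param covariates Character vector of covariate columns (centered at their
#'   sample means before fitting).
#' @param random Character vector of `lme4` random-effect terms (the maximal
#'   structure).
#' @param reduction_policy List of random-term vectors, in the order they are
#'   attempted after the maximal structure fails.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = "accuracy",
                       fixed = c("condition", "session"),
                       covariates = c("imageability", "aoa", "familiarity", "zipf"),
                       random = c("(1 + session | participant)", "(1 | form)",
                                  "(1 + session + condition | meaning)"),
                       reduction_policy = list(
                         c("(1 + session | participant)", "(1 | form)",
                           "(1 | meaning)"),
                         c("(1 | participant)", "(1 | form)", "(1 | meaning)"),
                         c("(1 | participant)", "(1 | form)"),
                         c("(1 | participant)"))) {
  stopifnot(length(fixed) >= 1)
  structure(list(outcome = outcome, fixed = fixed, covariates = covariates,
                 random = random, reduction_policy = reduction_policy),
            class = "model_spec")
}

#' Specification of the Similarity-by-Bridge-Knowledge model
#'
#' Terminus-session model: fixed effects of condition and bridge-knowledge
#' category (treatment-coded against Known, giving the Known-vs-Partly-Known
#' and Known-vs-Unknown contrasts) plus interactions and covariates; random
#' intercepts for participant, form, and meaning with by-participant and
#' by-form knowledge slopes and by-meaning knowledge and condition slopes.
#'
#' @return A `model_spec`.
#' @export
knowledge_model_spec <- function() {
  model_spec(fixed = c("condition", "category"),
             random = c("(1 + category | participant)", "(1 + category | form)",
                        "(1 + category + condition | meaning)"),
             reduction_policy = list(
               c("(1 + category | participant)", "(1 | form)", "(1 | meaning)"),
               c("(1 | participant)", "(1 | form)", "(1 | meaning)"),
               c("(1 | participant)", "(1 | form)"),
               c("(1 | participant)")))
}

spec_formula <- function(spec, random_terms) {
  fixed_part <- paste(spec$fixed, collapse = " * ")
  cov_part <- if (length(spec$covariates))
    paste(paste0(spec$covariates, "_c"), collapse = " + ") else NULL
  rhs <- paste(c(fixed_part, cov_part, random_terms), collapse = " + ")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

#' Fit a linear mixed-effects accuracy model
#'
#' REML fit via `lmerTest` with Satterthwaite degrees of freedom for the
#' fixed-effect tests. Covariates are centered at their sample means (so
#' interaction estimates match the marginal-means parameterization); the
#' centers are stored with the fit. Factors among the fixed terms must have at
#' least two levels, and a rank-deficient fixed design is an error naming the
#' aliased columns. On non-convergence the random structure is reduced along
#' `spec$reduction_policy`, with every attempt logged; singular fits are
#' logged but accepted.
#'
#' @param data Trial-level data frame (e.g. `simulate_study()$responses`).
#' @param spec A `model_spec`.
#' @return A `fitted_lmm`: list with the `lmerModLmerTest` `model`, the
#'   `coefficients` table (estimate, SE, df, t, p, 95 percent CI),
#'   `varcorr`, `random_used`, `convergence_log`, `centers`, and `spec`.
#' @export
fit_lmm <- function(data, spec = model_spec()) {
  needed <- c(spec$outcome, spec$fixed, spec$covariates,
              unique(unlist(regmatches(spec$random,
                                       gregexpr("[A-Za-z_.]+", spec$random)))))
  needed <- setdiff(needed, c("1"))
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  for (f in spec$fixed) {
    data[[f]] <- droplevels(factor(data[[f]]))
    if (nlevels(data[[f]]) < 2)
      stop("fixed factor '", f, "' has fewer than 2 levels")
  }
  centers <- numeric(0)
  for (v in spec$covariates) {
    centers[v] <- mean(data[[v]])
    data[[paste0(v, "_c")]] <- data[[v]] - centers[v]
  }
  fixed_form <- stats::as.formula(paste(
    "~", paste(c(paste(spec$fixed, collapse = " * "),
                 if (length(spec$covariates)) paste0(spec$covariates, "_c")),
               collapse = " + ")))
  X <- stats::model.matrix(fixed_form, data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  structures <- c(list(spec$random), spec$reduction_policy)
  log_lines <- character(0)
  fit <- NULL; used <- NULL
  last_fit <- NULL; last_used <- NULL
  for (i in seq_along(structures)) {
    form <- spec_formula(spec, structures[[i]])
    msgs <- character(0)
    m <- tryCatch(
      withCallingHandlers(
        lmerTest::lmer(form, data = data, REML = TRUE),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(cn) {
          msgs <<- c(msgs, conditionMessage(cn))
          invokeRestart("muffleMessage")
        }),
      error = function(e) e)
    tag <- paste(structures[[i]], collapse = " + ")
    if (inherits(m, "error")) {
      log_lines <- c(log_lines, paste0("structure [", tag, "]: error: ",
                                       conditionMessage(m)))
      next
    }
    failed <- any(grepl("failed to converge", msgs))
    if (failed) {
      log_lines <- c(log_lines, paste0("structure [", tag,
                                       "]: did not converge; reducing"))
      last_fit <- m; last_used <- structures[[i]]
      next
    }
    if (lme4::isSingular(m))
      log_lines <- c(log_lines, paste0("structure [", tag,
                                       "]: singular fit (accepted)"))
    log_lines <- c(log_lines, paste0("structure [", tag, "]: converged"))
    fit <- m; used <- structures[[i]]
    break
  }
  if (is.null(fit) && !is.null(last_fit)) {
    # every structure warned (typical for degenerate, e.g. noise-free, data):
    # keep the simplest structure that produced estimates, with the warnings
    # on record
    fit <- last_fit; used <- last_used
    log_lines <- c(log_lines, paste0(
      "no structure converged cleanly; accepted simplest fitted structure [",
      paste(used, collapse = " + "), "] with convergence warnings logged"))
  }
  if (is.null(fit))
    stop("no random-effects structure converged; log:\n",
         paste(log_lines, collapse = "\n"))
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  tcrit <- stats::qt(0.975, co$df)
  co$ci_low <- co$estimate - tcrit * co$se
  co$ci_high <- co$estimate + tcrit * co$se
  co$term <- rownames(co)
  rownames(co) <- NULL
  co <- co[, c("term", "estimate", "se", "df", "t", "p", "ci_low", "ci_high")]
  structure(list(model = fit, coefficients = co,
                 varcorr = as.data.frame(lme4::VarCorr(fit)),
                 random_used = used, convergence_log = log_lines,
                 centers = centers, spec = spec),
            class = "fitted_lmm")
}

#' Estimated marginal means
#'
#' Model-predicted cell means over the fixed-factor grid with covariates held
#' at their sample means (covariates are centered before fitting, so the
#' reference grid's zero is the sample mean), with Satterthwaite degrees of
#' freedom.
#'
#' @param fit A `fitted_lmm`.
#' @param specs Right-hand-side formula of grid factors; defaults to the
#'   interaction of the spec's fixed factors.
#' @return An `emm_table` data frame (factor columns, `M`, `SE`, `df`,
#'   `ci_low`, `ci_high`) with the underlying `emmGrid` in attribute `grid`.
#' @export
marginal_means <- function(fit, specs = NULL) {
  if (is.null(specs))
    specs <- stats::as.formula(paste("~", paste(fit$spec$fixed, collapse = " * ")))
  # keep Satterthwaite df even on datasets above emmeans' default size cutoff
  old <- emmeans::emm_options(lmerTest.limit = 1e7)
  on.exit(emmeans::emm_options(old))
  grid <- emmeans::emmeans(fit$model, specs, lmer.df = "satterthwaite")
  df <- as.data.frame(grid)
  names(df)[names(df) == "emmean"] <- "M"
  names(df)[names(df) == "lower.CL"] <- "ci_low"
  names(df)[names(df) == "upper.CL"] <- "ci_high"
  structure(df, class = c("emm_table", "data.frame"), grid = grid)
}

#' Tukey-corrected pairwise contrasts of marginal means
#'
#' All pairwise differences between the cells of an [marginal_means()] table,
#' with family-wise adjusted p-values (Tukey studentized-range adjustment on a
#' balanced grid; `emmeans` substitutes the single-step multivariate-t
#' adjustment where the studentized range does not apply). Unadjusted p-values
#' are reported alongside; the adjusted value is never smaller.
#'
#' @param emms An `emm_table`.
#' @param correction Adjustment passed to `emmeans` (default `"tukey"`).
#' @return A `contrast_table` data frame: `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p_raw`, `p_adj`.
#' @export
pairwise_contrasts <- function(emms, correction = "tukey") {
  grid <- attr(emms, "grid")
  if (is.null(grid)) stop("emms must come from marginal_means()")
  adj <- as.data.frame(emmeans::contrast(grid, method = "pairwise",
                                         adjust = correction))
  raw <- as.data.frame(emmeans::contrast(grid, method = "pairwise",
                                         adjust = "none"))
  out <- data.frame(contrast = as.character(adj$contrast),
                    estimate = adj$estimate, se = adj$SE, df = adj$df,
                    t = adj$t.ratio, p_raw = raw$p.value,
                    p_adj = pmax(adj$p.value, raw$p.value),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contrast_table", "data.frame"))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' as used for the stimulus matching checks.
#'
#' @param x,y Numeric samples of size >= 2; at least one must have positive
#'   variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must have at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate samples: both have zero variance")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic on an r-by-c count table with
#' `(r-1)(c-1)` degrees of freedom; zero marginals are an error.
#'
#' @param tab Matrix (or table) of counts.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column marginal in contingency table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = res$expected)
}
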