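# hand-computed Welch statistic for x = {1,2,3}, y = {1,2,3,4,5,6}:
# se^2 = 1/3 + 3.5/6, t = -1.5/sqrt(se^2), df = se^4 / ((1/3)^2/2 + (3.5/6)^2/5)
test_that("welch_t matches the hand-computed statistic and is antisymmetric", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  res <- welch_t(x, y)
  expect_equal(res$t, -1.5 / sqrt(1 / 3 + 3.5 / 6), tolerance = 1e-12)
  expect_equal(res$df, (1 / 3 + 3.5 / 6)^2 / ((1 / 3)^2 / 2 + (3.5 / 6)^2 / 5),
               tolerance = 1e-12)
  swapped <- welch_t(y, x)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("chi-square independence matches closed forms", {
  prop <- matrix(c(10, 20, 30, 5, 10, 15), nrow = 2, byrow = TRUE)
  res <- chi_square_independence(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$df, 2)

  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(chi_square_independence(diag2)$statistic, 20, tolerance = 1e-12)

  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("noise-free simulated data yield exact fixed-effect estimates and EMMs", {
  design <- bundled_design()
  cfg <- sim_config(n_familiar = 4, n_unfamiliar = 4,
                    sd_participant_intercept = 0, sd_participant_slope = 0,
                    sd_form = 0, sd_meaning = 0,
                    condition_on_knowledge = FALSE, response_noise = "none",
                    seed = 7)
  dat <- simulate_study(cfg, design)$responses
  fit <- fit_lmm(dat, simulation_spec())
  co <- fit$coefficients
  est <- function(term) co$estimate[co$term == term]
  cm <- cfg$cell_means_pct
  expect_equal(est("(Intercept)"), cm["Familiar", "Bridge"], tolerance = 1e-6)
  expect_equal(est("conditionUnfamiliar"),
               cm["Unfamiliar", "Bridge"] - cm["Familiar", "Bridge"],
               tolerance = 1e-6)
  expect_equal(est("sessionTerminus"),
               cm["Familiar", "Terminus"] - cm["Familiar", "Bridge"],
               tolerance = 1e-6)
  expect_equal(est("conditionUnfamiliar:sessionTerminus"),
               (cm["Unfamiliar", "Terminus"] - cm["Unfamiliar", "Bridge"]) -
                 (cm["Familiar", "Terminus"] - cm["Familiar", "Bridge"]),
               tolerance = 1e-6)
  emm <- marginal_means(fit)
  for (i in seq_len(nrow(emm))) {
    expect_equal(emm$M[i], cm[as.character(emm$condition[i]),
                              as.character(emm$session[i])], tolerance = 1e-6)
  }
})

test_that("marginal means and Tukey contrasts are mutually consistent", {
  design <- bundled_design()
  dat <- simulate_study(sim_config(n_familiar = 5, n_unfamiliar = 5, seed = 9),
                        design)$responses
  fit <- fit_lmm(dat, simulation_spec())
  emm <- marginal_means(fit)
  expect_equal(nrow(emm), 4)
  con <- pairwise_contrasts(emm)
  expect_equal(nrow(con), 6)  # all pairs of 4 cells
  cell <- paste(emm$condition, emm$session)
  for (i in seq_len(nrow(con))) {
    parts <- strsplit(con$contrast[i], " - ", fixed = TRUE)[[1]]
    expect_equal(con$estimate[i],
                 emm$M[cell == parts[1]] - emm$M[cell == parts[2]],
                 tolerance = 1e-9)
  }
  expect_true(all(con$p_adj >= con$p_raw - 1e-12))
})

test_that("identical cells produce a zero contrast with adjusted p of one", {
  # two exactly equal groups, no noise
  dat <- data.frame(
    participant = rep(sprintf("p%d", 1:6), each = 4),
    condition = rep(c("A", "B"), each = 12),
    form = rep(sprintf("w%d", 1:4), 6),
    accuracy = rep(c(10, 20, 30, 40), 6))
  spec <- model_spec(fixed = "condition", covariates = character(0),
                     random = c("(1 | participant)"),
                     reduction_policy = list())
  fit <- fit_lmm(dat, spec)
  con <- pairwise_contrasts(marginal_means(fit, ~condition))
  expect_equal(con$estimate, 0, tolerance = 1e-9)
  expect_equal(con$p_adj, 1, tolerance = 1e-9)
})

test_that("the reduction policy logs failures and falls back deterministically", {
  design <- bundled_design()
  dat <- simulate_study(sim_config(n_familiar = 3, n_unfamiliar = 3, seed = 13),
                        design)$responses
  # first structure references a constant grouping column: unfittable, logged,
  # and the policy's next structure takes over
  dat$badgroup <- "only-one-level"
  spec <- model_spec(random = c("(1 | badgroup)"),
                     reduction_policy = list(
                       c("(1 | participant)", "(1 | form)")))
  fit <- fit_lmm(dat, spec)
  expect_equal(fit$random_used, c("(1 | participant)", "(1 | form)"))
  expect_true(any(grepl("badgroup.*error", fit$convergence_log)))
  expect_true(any(grepl("converged", fit$convergence_log)))
  # refitting directly with the reduced structure reproduces the estimates
  spec2 <- model_spec(random = c("(1 | participant)", "(1 | form)"),
                      reduction_policy = list())
  fit2 <- fit_lmm(dat, spec2)
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-9)
})

test_that("degenerate fixed designs are rejected with informative errors", {
  design <- bundled_design()
  dat <- simulate_study(sim_config(n_familiar = 2, n_unfamiliar = 2, seed = 14),
                        design)$responses
  one_level <- dat[dat$condition == "Familiar", ]
  expect_error(fit_lmm(one_level, simulation_spec()), "fewer than 2 levels")

  dat$dup <- dat$imageability  # aliased covariate
  spec <- model_spec(covariates = c("imageability", "dup"),
                     random = c("(1 | participant)"),
                     reduction_policy = list())
  expect_error(fit_lmm(dat, spec), "aliased")
  expect_error(fit_lmm(dat[, setdiff(names(dat), "accuracy")],
                       simulation_spec()), "missing column")
})

test_that("power simulation is seeded, bounded, and saturates for huge effects", {
  cfg <- power_config(effect_pct = 50, n_grid = c(16), nsim = 20, seed = 3)
  base <- sim_config(sd_participant_intercept = 5, sd_form = 2)
  curve <- power_simulation(cfg, base)
  expect_equal(nrow(curve), 1)
  expect_gte(curve$power, 0.9)  # 50-point effect with small variance
  expect_true(all(curve$power >= 0 & curve$power <= 1))
  expect_equal(curve$mc_se, sqrt(curve$power * (1 - curve$power) / 20),
               tolerance = 1e-12)
  curve2 <- power_simulation(cfg, base)
  expect_identical(curve, curve2)
  expect_error(power_config(nsim = 0), "nsim")
})
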