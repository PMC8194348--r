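test_that("sim_config validates its fields and names the offenders", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(sd_form = -1), "sd_form")
  expect_error(sim_config(n_familiar = -2), "n_familiar")
  bad_means <- matrix(c(34, 16, 150, 18), 2, 2,
                      dimnames = list(c("Familiar", "Unfamiliar"),
                                      c("Bridge", "Terminus")))
  expect_error(sim_config(cell_means_pct = bad_means), "cell_means_pct")
})

test_that("degenerate configurations reproduce configured means", {
  design <- bundled_design()
  ceiling_cfg <- sim_config(
    n_familiar = 4, n_unfamiliar = 2,
    cell_means_pct = matrix(c(100, 100, 100, 100), 2, 2,
                            dimnames = dimnames(sim_config()$cell_means_pct)),
    knowledge_means_pct = matrix(100, 2, 3,
                                 dimnames = dimnames(sim_config()$knowledge_means_pct)),
    sd_participant_intercept = 0, sd_participant_slope = 0, sd_form = 0,
    sd_meaning = 0, seed = 2)
  study <- simulate_study(ceiling_cfg, design)
  expect_true(all(study$responses$score == 1))

  flat_cfg <- sim_config(sd_participant_intercept = 0, sd_participant_slope = 0,
                         sd_form = 0, sd_meaning = 0, seed = 3)
  study2 <- simulate_study(flat_cfg, design)
  fam_bridge <- study2$responses$score[study2$responses$condition == "Familiar" &
                                         study2$responses$session == "Bridge"]
  p <- 0.3403
  se <- sqrt(p * (1 - p) / 5 / length(fam_bridge))
  expect_lt(abs(mean(fam_bridge) - p), 3 * se)
})

test_that("simulation is deterministic given the seed and flows through the scorer", {
  design <- bundled_design()
  cfg <- sim_config(n_familiar = 3, n_unfamiliar = 3, seed = 11)
  s1 <- simulate_study(cfg, design)
  s2 <- simulate_study(cfg, design)
  expect_identical(s1$responses, s2$responses)
  s3 <- simulate_study(sim_config(n_familiar = 3, n_unfamiliar = 3, seed = 12),
                       design)
  expect_false(identical(s1$responses, s3$responses))
  # rescoring the emitted responses reproduces the stored scores
  re <- score_response(s1$responses$response_clean, s1$responses$target)
  expect_equal(re$score, s1$responses$score)
  # bridge rows precede terminus rows per participant, and terminus categories
  # partition the 48 items
  one <- s1$responses[s1$responses$participant == "F01", ]
  expect_equal(as.integer(table(one$session)), c(48L, 48L))
  expect_false(anyNA(one$category[one$session == "Terminus"]))
})

test_that("terminus accuracy conditions on realized bridge knowledge", {
  design <- bundled_design()
  base_km <- sim_config()$knowledge_means_pct
  high_km <- base_km; high_km[, "Known"] <- pmin(base_km[, "Known"] + 30, 100)
  gap <- function(km, seed) {
    cfg <- sim_config(n_familiar = 4, n_unfamiliar = 4,
                      cell_means_pct = matrix(c(60, 60, 30, 30), 2, 2,
                                              dimnames = dimnames(sim_config()$cell_means_pct)),
                      knowledge_means_pct = km, seed = seed)
    r <- simulate_study(cfg, design)$responses
    term <- r[r$session == "Terminus", ]
    mean(term$accuracy[term$category == "Known"]) -
      mean(term$accuracy[term$category == "Unknown"])
  }
  gaps <- vapply(1:20, function(s) gap(high_km, s) - gap(base_km, s), numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gt(mean(gaps > 0), 0.6)
})

test_that("generating truth matches configured means when conditioning is off", {
  cfg <- sim_config(sd_participant_intercept = 0, sd_participant_slope = 0,
                    sd_form = 0, sd_meaning = 0, condition_on_knowledge = FALSE)
  tr <- truth_cell_means(cfg)
  expect_equal(tr$cell_means, cfg$cell_means_pct, tolerance = 1e-9)
  # noise-free latent path reproduces the truth exactly
  design <- bundled_design()
  cfg2 <- sim_config(n_familiar = 2, n_unfamiliar = 2,
                     sd_participant_intercept = 0, sd_participant_slope = 0,
                     sd_form = 0, sd_meaning = 0,
                     condition_on_knowledge = FALSE, response_noise = "none")
  r <- simulate_study(cfg2, design)$responses
  ag <- aggregate(accuracy ~ condition + session, r, mean)
  for (i in seq_len(nrow(ag))) {
    expect_equal(ag$accuracy[i],
                 cfg$cell_means_pct[ag$condition[i], ag$session[i]],
                 tolerance = 1e-9)
  }
})

test_that("the synthetic lexicon generator meets its contract", {
  syn <- make_synthetic_lexicon(200, seed = 21)
  expect_equal(nrow(syn$lexicon), 200)
  expect_false(anyDuplicated(syn$lexicon$word) > 0)
  expect_true(all(nchar(syn$lexicon$word) == 5))
  expect_true(all(syn$lexicon$freq_per_million > 0))
  model <- similarity_model(syn$lexicon, syn$pronunciations)
  expect_gt(sd(model$reference_scores), 0)
  syn2 <- make_synthetic_lexicon(200, seed = 22)
  expect_false(identical(syn$lexicon$word, syn2$lexicon$word))
  expect_identical(make_synthetic_lexicon(200, seed = 21)$lexicon, syn$lexicon)
})

test_that("the synthetic norms generator balances classes deterministically", {
  norms <- make_synthetic_norms(96, seed = 31)
  expect_equal(nrow(norms), 96)
  expect_equal(sum(norms$class == "concrete"), 48)
  expect_equal(sum(norms$class == "abstract"), 48)
  expect_identical(norms, make_synthetic_norms(96, seed = 31))
  two <- make_synthetic_norms(2, seed = 1)
  expect_setequal(two$class, c("concrete", "abstract"))
  expect_error(make_synthetic_norms(95, seed = 1), "even")
})
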