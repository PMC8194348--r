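#' Power-analysis configuration
#'
#' @param effect_pct Fixed-effect size on learning accuracy, percent (the
#'   study's planning value was 10).
#' @param n_grid Total sample sizes to simulate (the study scanned 20 to 40).
#' @param nsim Simulated datasets per sample size.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return A `power_config` list.
#' @export
power_config <- function(effect_pct = 10, n_grid = seq(20, 40, by = 5),
                         nsim = 200, alpha = 0.05, seed = 1) {
  if (nsim < 1) stop("nsim must be at least 1")
  if (any(n_grid < 4)) stop("sample sizes must be at least 4")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(effect_pct = effect_pct, n_grid = n_grid, nsim = nsim,
                 alpha = alpha, seed = seed), class = "power_config")
}

# light two-group single-session generator used by the power loop: latent
# accuracy = group mean + participant intercept + form intercept, clamped,
# letters ~ Binomial(5, p); group 2 carries the planned effect
simulate_two_group <- function(n1, n2, mean1, mean2, sd_participant, sd_form,
                               n_items = 48, seed = 1) {
  with_seed(seed, {
    n <- n1 + n2
    grp <- rep(c("g1", "g2"), c(n1, n2))
    mu <- rep(c(mean1, mean2), c(n1, n2))
    b <- stats::rnorm(n, 0, sd_participant)
    # separate stimulus lists per group, as in the two-condition design
    u_form <- stats::rnorm(2 * n_items, 0, sd_form)
    form_ids <- paste0("w", seq_len(2 * n_items))
    idx <- lapply(seq_len(n), function(j)
      if (grp[j] == "g1") seq_len(n_items) else n_items + seq_len(n_items))
    latent <- unlist(lapply(seq_len(n), function(j) mu[j] + b[j] + u_form[idx[[j]]]))
    p <- pmin(pmax(latent / 100, 0), 1)
    letters <- stats::rbinom(length(p), 5, p)
    data.frame(participant = rep(sprintf("p%03d", seq_len(n)), each = n_items),
               group = rep(grp, each = n_items),
               form = form_ids[unlist(idx)],
               accuracy = 100 * letters / 5,
               stringsAsFactors = FALSE)
  })
}

#' Monte-Carlo power analysis for the similarity effect
#'
#' For each total sample size in `config$n_grid`, simulates `config$nsim`
#' two-group single-session datasets in which the groups differ by
#' `config$effect_pct` on latent accuracy (variance components from
#' `base_sim`), fits the similarity model `accuracy ~ group +
#' (1 | participant) + (1 | form)` by REML, tests the group effect with
#' Satterthwaite degrees of freedom, and records the rejection rate at
#' `config$alpha`.
#'
#' @param config A `power_config`.
#' @param base_sim A `sim_config`; supplies the baseline mean (the Unfamiliar
#'   bridge cell) and the participant/form variance components.
#' @return A `power_curve` data frame: `n`, `power`, `mc_se`, `nsim`,
#'   `effect_pct`, `alpha`.
#' @export
power_simulation <- function(config = power_config(), base_sim = sim_config()) {
  baseline <- base_sim$cell_means_pct["Unfamiliar", "Bridge"]
  seeds <- matrix(
    with_seed(config$seed,
              sample.int(.Machine$integer.max - 1L,
                         length(config$n_grid) * config$nsim)),
    nrow = length(config$n_grid))
  res <- lapply(seq_along(config$n_grid), function(i) {
    n <- config$n_grid[i]
    n1 <- floor(n / 2); n2 <- n - n1
    reject <- vapply(seq_len(config$nsim), function(s) {
      dat <- simulate_two_group(n1, n2, baseline, baseline + config$effect_pct,
                                base_sim$sd_participant_intercept,
                                base_sim$sd_form, seed = seeds[i, s])
      p <- tryCatch({
        m <- suppressMessages(suppressWarnings(
          lmerTest::lmer(accuracy ~ group + (1 | participant) + (1 | form),
                         data = dat, REML = TRUE)))
        summary(m)$coefficients["groupg2", "Pr(>|t|)"]
      }, error = function(e) NA_real_)
      !is.na(p) && p < config$alpha
    }, logical(1))
    power <- mean(reject)
    data.frame(n = n, power = power,
               mc_se = sqrt(power * (1 - power) / config$nsim),
               nsim = config$nsim, effect_pct = config$effect_pct,
               alpha = config$alpha)
  })
  structure(do.call(rbind, res), class = c("power_curve", "data.frame"))
}
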