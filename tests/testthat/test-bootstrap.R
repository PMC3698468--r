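boot_fixture <- function(seed = 51, beta_sr = 0.23) {
  cfg <- sim_config(n_pool = 12, n_plots = 8, richness = c(3L, 6L),
                    n_phytometers = 6, plants_per = 3, beta_sr = beta_sr)
  sim <- simulate_study(cfg, seed = seed)
  build_model_data(sim$plants, sim$predictors)
}

test_that("the bootstrap p-value follows the stated counting rule", {
  expect_equal(bootstrap_pvalue(2.0, c(1.1, 2.5, 0.3, 2.0)), 0.5)
  expect_equal(bootstrap_pvalue(-2.0, c(1.1, 2.5, 0.3, 2.0)), 0.5)  # two-sided
  expect_equal(bootstrap_pvalue(0, c(1, 2)), 1)
  expect_equal(bootstrap_pvalue(10, c(1, 2)), 0)
  # failed fits (NA) leave the denominator
  expect_equal(bootstrap_pvalue(2.0, c(2.5, NA, 0.3, NA)), 0.5)
})

test_that("simulate_response is seeded, reproducible, and refuses to run unseeded", {
  md <- boot_fixture()
  fit <- fit_laplace(md)
  expect_error(simulate_response(fit), "seed is required")
  y1 <- simulate_response(fit, seed = 9)
  y2 <- simulate_response(fit, seed = 9)
  expect_identical(y1, y2)
  expect_true(all(y1 >= 0 & y1 <= md$N))
})

test_that("with all parameters zero the simulated damage is Binomial(N, 1/2)", {
  md <- boot_fixture()
  fit <- fit_laplace(md, fixed_sigma = c(species = 0, plot = 0, obs = 0))
  fit$coefficients$estimate[] <- 0
  y <- simulate_response(fit, seed = 10)
  phat <- sum(y) / sum(md$N)
  se <- sqrt(0.25 / sum(md$N))
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("simulated damage matches the brute-force marginal mean of the model", {
  # 2-group toy with known parameters: marginal mean by quadrature
  md <- model_data(c(5, 6, 7, 8), c(12, 12, 12, 12),
                   matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
                   species = c("a", "a", "b", "b"), plot = rep("p", 4))
  fit <- fit_laplace(md, fixed_terms = "(Intercept)", re_terms = "species")
  a <- coef(fit)[[1]]; s2 <- fit$sigma[["species"]]^2
  truth <- marginal_mean_logit(a, s2)
  set.seed(12)
  draws <- replicate(500, mean(herbdiv:::simulate_response_(fit) / md$N))
  mc_se <- sd(draws) / sqrt(500)
  expect_lt(abs(mean(draws) - truth), 5 * mc_se + 1e-3)
})

test_that("refit efficiency devices do not distort the simulated z distribution", {
  # warm-started, restart-free, 1e-6-tolerance refits (what bootstrap_p uses)
  # must give the same z as cold production-tolerance fits on matched data
  md <- boot_fixture(53)
  full <- fit_laplace(md)
  reduced <- fit_laplace(md, fixed_terms = setdiff(full$fixed_terms, "SR"),
                         start = list(sigma = full$sigma, beta = coef(full)))
  warm <- list(sigma = full$sigma, beta = coef(full))
  short_ctl <- glmm_control(outer_reltol = 1e-6)
  short_ctl$restarts <- 0
  z_short <- z_prod <- numeric(20)
  set.seed(2)
  for (b in 1:20) {
    md_b <- md
    md_b$y <- as.numeric(herbdiv:::simulate_response_(reduced))
    f1 <- fit_laplace(md_b, start = warm, control = short_ctl)
    f2 <- fit_laplace(md_b)
    z_short[b] <- f1$coefficients$z[f1$coefficients$term == "SR"]
    z_prod[b] <- f2$coefficients$z[f2$coefficients$term == "SR"]
  }
  expect_gt(cor(z_short, z_prod), 0.95)
  expect_lt(abs(sd(z_short) / sd(z_prod) - 1), 0.1)
  expect_lt(abs(mean(z_short - z_prod)), 0.1)
})

test_that("bootstrap_p tests a factor, keeps the interaction, and is bit-reproducible", {
  md <- boot_fixture(52)
  full <- fit_laplace(md)
  b1 <- bootstrap_p(md, "SR", B = 19, seed = 5, full = full)
  b2 <- bootstrap_p(md, "SR", B = 19, seed = 5, full = full)
  expect_identical(b1$z_sim, b2$z_sim)
  expect_identical(b1$p, b2$p)
  expect_equal(b1$z_obs, full$coefficients$z[full$coefficients$term == "SR"])
  expect_gte(b1$p, 0)
  expect_lte(b1$p, 1)
  expect_equal(b1$p, bootstrap_pvalue(b1$z_obs, b1$z_sim))
  expect_error(bootstrap_p(md, "SR", B = 5), "seed is required")
})
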