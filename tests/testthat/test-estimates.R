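est_fixture <- function(seed = 61, ...) {
  cfg <- sim_config(n_pool = 16, n_plots = 12, richness = c(3L, 8L),
                    n_phytometers = 8, plants_per = 4, leaf_mean = 10, ...)
  sim <- simulate_study(cfg, seed = seed)
  fit_laplace(build_model_data(sim$plants, sim$predictors))
}

test_that("damage estimates agree exactly with predict_linear + inverse logit", {
  fit <- est_fixture()
  pd <- plot_damage(fit)
  pred <- fit$data$predictors
  nd <- data.frame(SR = pred$SR, PD = pred$PD, plot = pred$plot)
  eta <- predict_linear(fit, nd, include_fixed = c("(Intercept)", "SR", "PD", "SR:PD"),
                        include_ranef = "plot")
  expect_equal(pd$estimate[match(pred$plot, pd$plot)], plogis(eta))

  sp <- species_damage(fit)
  eta_k <- coef(fit)[["(Intercept)"]] + fit$ranef$species$mode
  expect_equal(sp$estimate, plogis(eta_k))

  # all estimates strictly inside (0,1) with ordered bounds
  for (d in list(pd, sp)) {
    expect_true(all(d$estimate > 0 & d$estimate < 1))
    expect_true(all(d$lower <= d$estimate & d$estimate <= d$upper))
  }
})

test_that("zeroed parameters give 0.5 everywhere; modes move estimates monotonically", {
  fit <- est_fixture(62)
  fit0 <- fit
  fit0$coefficients$estimate[] <- 0
  fit0$ranef$plot$mode[] <- 0
  fit0$ranef$species$mode[] <- 0
  expect_true(all(abs(plot_damage(fit0)$estimate - 0.5) < 1e-12))
  expect_true(all(abs(species_damage(fit0)$estimate - 0.5) < 1e-12))

  bumped <- fit
  bumped$ranef$plot$mode[3] <- bumped$ranef$plot$mode[3] + 0.7
  expect_gt(plot_damage(bumped)$estimate[3], plot_damage(fit)$estimate[3])
  expect_equal(plot_damage(bumped)$estimate[-3], plot_damage(fit)$estimate[-3])
})

test_that("exchangeable species with identical data get identical estimates", {
  div <- data.frame(plot = c("p1", "p2"), SR = c(3L, 5L), PSE = c(0.5, 0.8))
  dates <- data.frame(plot = c("p1", "p2"), date = c(0L, 3L))
  pr <- build_predictors(div, dates)
  plants <- data.frame(plot = rep(c("p1", "p2"), each = 4),
                       species = rep(c("A", "B"), 4),
                       damaged = rep(c(2L, 2L, 9L, 9L), 2),
                       total = rep(10L, 8))
  fit <- fit_laplace(build_model_data(plants, pr),
                     fixed_terms = c("(Intercept)", "SR"))
  sp <- species_damage(fit)
  expect_equal(sp$estimate[sp$species == "A"], sp$estimate[sp$species == "B"],
               tolerance = 1e-6)
})

test_that("species-level contrasts span low to high damage under strong species effects", {
  fit <- est_fixture(63, sigma2_species = 1.5^2)
  sp <- species_damage(fit)
  expect_lt(min(sp$estimate), 0.35)
  expect_gt(max(sp$estimate), 0.65)
})

test_that("plot damage ranking recovers the true plot effects", {
  cfg <- sim_config(sigma2_plot = 1)
  sim <- simulate_study(cfg, seed = 64)
  fit <- fit_laplace(build_model_data(sim$plants, sim$predictors))
  pd <- plot_damage(fit)
  # the true analogue of p_j: intercept + plot-level fixed terms + plot effect
  pr <- sim$predictors
  i <- match(pd$plot, pr$plot)
  truth_lp <- cfg$alpha + cfg$beta_sr * pr$SR_c[i] + cfg$beta_pd * pr$PD_c[i] +
    cfg$beta_srpd * pr$SRPD_c[i] + sim$truth$u_plot[pd$plot]
  expect_gt(cor(pd$estimate, truth_lp, method = "spearman"), 0.8)
})

test_that("the fitted surface reflects the interaction structure", {
  fit <- est_fixture(65)
  sr <- c(3, 6, 12, 17)
  expect_warning(M <- fitted_surface(fit, sr = sr), "hull")
  expect_equal(dim(M), c(25L, 4L))
  expect_true(all(M > 0 & M < 1))
  grid <- attr(M, "grid")
  expect_equal(nrow(grid), 100L)

  # zero interaction -> parallel on the logit scale
  fit0 <- fit
  fit0$coefficients$estimate[fit0$coefficients$term == "SR:PD"] <- 0
  M0 <- suppressWarnings(fitted_surface(fit0, sr = c(3, 10)))
  slopes <- apply(qlogis(M0), 1, diff)
  expect_lt(diff(range(slopes)), 1e-10)

  # the mixed partial of the logit surface has the interaction's sign, everywhere
  b_int <- coef(fit)[["SR:PD"]]
  L <- qlogis(suppressWarnings(fitted_surface(fit, sr = c(4, 5),
                                              pd = seq(0.3, 0.9, 0.1))))
  dd <- diff(L[, 2] - L[, 1])      # change of the SR slope across PD
  expect_true(all(sign(dd) == sign(b_int)))
})
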