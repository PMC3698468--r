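# small crossed-design simulation used by several blocks
glmm_fixture <- function(seed = 21) {
  cfg <- sim_config(n_pool = 20, n_plots = 15, richness = c(3L, 8L),
                    n_phytometers = 10, plants_per = 4, leaf_mean = 10)
  sim <- simulate_study(cfg, seed = seed)
  build_model_data(sim$plants, sim$predictors)
}

test_that("model data assembles crossed factors with one obs level per plant", {
  div <- data.frame(plot = c("p1", "p2"), SR = c(3L, 5L), PSE = c(0.5, 0.8))
  dates <- data.frame(plot = c("p1", "p2"), date = c(0L, 3L))
  pr <- build_predictors(div, dates)
  plants <- data.frame(plot = rep(c("p1", "p2"), each = 2),
                       species = rep(c("A", "B"), 2),
                       damaged = c(1L, 2L, 3L, 4L), total = c(5L, 6L, 7L, 8L))
  md <- build_model_data(plants, pr)
  expect_equal(md$n, 4L)
  expect_equal(nlevels(md$species), 2L)
  expect_equal(nlevels(md$plot), 2L)
  expect_equal(colnames(md$X), c("(Intercept)", "DATE", "SR", "PD", "SR:PD"))
  # plot predictors broadcast to plants
  expect_equal(md$X[, "SR"], pr$SR_c[match(plants$plot, pr$plot)])

  orphan <- transform(plants, plot = sub("p2", "p9", plot))
  expect_error(build_model_data(orphan, pr), "p9")
})

test_that("full-size synthetic data has the study's dimensions", {
  sim <- simulate_study(sim_config(), seed = 302)
  md <- build_model_data(sim$plants, sim$predictors)
  expect_equal(length(sim$tree$tip.label), 52L)
  expect_lte(nlevels(md$species), 27L)
  expect_gte(nlevels(md$species), 25L)
  expect_gte(nlevels(md$plot), 36L)
  expect_gte(md$n, 1500L)
  expect_true(all(sim$diversity$SR >= 3 & sim$diversity$SR <= 17))
})

test_that("the sigma = 0 limit reproduces an independent IRLS GLM fit", {
  md <- glmm_fixture(22)
  fit0 <- fit_laplace(md, fixed_sigma = c(species = 0, plot = 0, obs = 0))
  g <- stats::glm(cbind(md$y, md$N - md$y) ~ md$X - 1, family = stats::binomial())
  expect_lt(max(abs(coef(fit0) - unname(coef(g)))), 1e-6)
  dev_mine <- -2 * fit0$logLik +
    2 * sum(stats::dbinom(md$y, md$N, md$y / md$N, log = TRUE))
  expect_lt(abs(dev_mine - stats::deviance(g)), 1e-6)
  # Wald z is exactly estimate / SE
  expect_equal(fit0$coefficients$z,
               fit0$coefficients$estimate / fit0$coefficients$se)
})

test_that("an intercept-only model on pooled 30/60 damage recovers logit(1/2) = 0", {
  md <- model_data(30, 60, matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")),
                   species = "s", plot = "p")
  fit <- fit_laplace(md, fixed_terms = "(Intercept)", re_terms = character(0))
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(plogis(unname(coef(fit))), 0.5, tolerance = 1e-8)
})

test_that("the Laplace fit agrees with lme4's equivalent formulation", {
  skip_if_not_installed("lme4")
  md <- glmm_fixture(23)
  fit <- fit_laplace(md)
  df <- data.frame(y = md$y, N = md$N, md$X[, -1], sp = md$species,
                   pl = md$plot, ob = seq_len(md$n))
  gm <- lme4::glmer(cbind(y, N - y) ~ DATE + SR + PD + SR.PD +
                      (1 | sp) + (1 | pl) + (1 | ob),
                    data = df, family = stats::binomial(), nAGQ = 1)
  # agreement scaled by SE: flat likelihood directions (e.g. PD here) admit
  # optimizer-level wobble that is meaningless on the inferential scale
  expect_lt(max(abs(coef(fit) - unname(lme4::fixef(gm))) / fit$coefficients$se),
            0.05)
  vc <- as.data.frame(lme4::VarCorr(gm))
  ref <- setNames(vc$sdcor, vc$grp)
  expect_equal(unname(fit$sigma[c("species", "plot", "obs")]),
               unname(ref[c("sp", "pl", "ob")]), tolerance = 2e-2)
  expect_equal(fit$logLik, as.numeric(stats::logLik(gm)), tolerance = 1e-3)
  # SEs from the joint-Hessian block match lme4's
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(as.matrix(vcov(gm))))), tolerance = 2e-2)
})

test_that("Laplace log-likelihood matches adaptive quadrature on a single-factor toy", {
  set.seed(31)
  g <- 8; per <- 6
  group <- factor(rep(seq_len(g), each = per))
  N <- 1 + rpois(g * per, 10)
  b <- rnorm(g, 0, 1.2)
  y <- rbinom(g * per, N, plogis(0.3 + b[as.integer(group)]))
  md <- model_data(y, N, matrix(1, g * per, 1, dimnames = list(NULL, "(Intercept)")),
                   species = group, plot = rep("p", g * per))
  fit <- fit_laplace(md, fixed_terms = "(Intercept)", re_terms = "species")
  ll_agq <- agq_loglik(md$y, md$N, rep(coef(fit)[[1]], md$n), group,
                       fit$sigma[["species"]])
  expect_lt(abs(fit$logLik - ll_agq), 0.1)
})

test_that("predict_linear is additive over its included components", {
  md <- glmm_fixture(24)
  fit <- fit_laplace(md)
  nd <- data.frame(SR = 5, PD = 0.7, DATE = 4,
                   plot = levels(md$plot)[2], species = levels(md$species)[1])
  none <- predict_linear(fit, nd, include_fixed = character())
  expect_equal(none, 0)
  all_terms <- predict_linear(fit, nd, include_ranef = c("species", "plot"))
  parts <- sum(vapply(fit$fixed_terms, function(tm)
    predict_linear(fit, nd, include_fixed = tm), 0)) +
    predict_linear(fit, nd, include_fixed = character(), include_ranef = "species") +
    predict_linear(fit, nd, include_fixed = character(), include_ranef = "plot")
  expect_equal(all_terms, parts, tolerance = 1e-12)

  expect_error(predict_linear(fit, transform(nd, plot = "nope"),
                              include_ranef = "plot"), "unknown plot")
})

test_that("conditional modes center near zero and shrink toward it", {
  set.seed(33)
  g <- 12; per <- 8
  group <- factor(rep(sprintf("s%02d", seq_len(g)), each = per))
  N <- 1 + rpois(g * per, 12)
  b <- rnorm(g, 0, 1.0)
  y <- rbinom(g * per, N, plogis(0.2 + b[as.integer(group)]))
  md <- model_data(y, N, matrix(1, g * per, 1, dimnames = list(NULL, "(Intercept)")),
                   species = group, plot = rep("p", g * per))
  fit <- fit_laplace(md, fixed_terms = "(Intercept)", re_terms = "species")
  re <- fit$ranef$species
  expect_lt(abs(mean(re$mode)), 0.05 * fit$sigma[["species"]])
  # shrinkage: each mode lies strictly between 0 and the group's raw
  # residual logit offset (interior groups only)
  alpha <- coef(fit)[[1]]
  pool <- tapply(y, group, sum) / tapply(N, group, sum)
  interior <- pool > 0 & pool < 1
  raw <- qlogis(pool[interior]) - alpha
  modes <- re$mode[match(names(raw), re$level)]
  expect_true(all(sign(modes) == sign(raw)))
  expect_true(all(abs(modes) < abs(raw)))
  expect_true(all(abs(modes) > 0))
})

test_that("the outer optimizer's incumbent objective never increases", {
  md <- glmm_fixture(25)
  fit <- fit_laplace(md)
  best <- cummin(fit$opt_trace)
  expect_true(all(diff(best) <= 0))
  expect_lt(fit$objective, fit$opt_trace[1] + 1e-9)
  expect_lt(abs(fit$objective - min(fit$opt_trace)), 1e-6)
})
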