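#' Simulate a fresh damage response from a fitted model
#'
#' Parametric simulation under a fitted (typically reduced) model: fresh
#' random effects are drawn from `Normal(0, sigma_hat^2)` for every level of
#' every fitted random factor, the linear predictor is formed with the fitted
#' fixed effects, and damaged-leaf counts are drawn
#' `Binomial(N_i, logit^-1(eta_i))`. Leaf totals and all predictors are held
#' fixed. A seed is required: reproducibility is mandatory for the bootstrap.
#'
#' @param fit a converged `"herb_glmm"` (usually the reduced model).
#' @param seed integer seed for the simulation (required).
#' @return integer vector of simulated damaged counts, one per plant.
#' @export
simulate_response <- function(fit, seed) {
  stopifnot(inherits(fit, "herb_glmm"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required: bootstrap simulations must be reproducible")
  set.seed(seed)
  simulate_response_(fit)
}

# draws from the current RNG stream (internal; callers manage the seed)
simulate_response_ <- function(fit) {
  data <- fit$data
  b <- coef(fit)
  eta <- drop(data$X[, fit$fixed_terms, drop = FALSE] %*% b)
  sig <- fit$sigma
  if ("species" %in% names(sig))
    eta <- eta + rnorm(nlevels(data$species), 0, sig[["species"]])[as.integer(data$species)]
  if ("plot" %in% names(sig))
    eta <- eta + rnorm(nlevels(data$plot), 0, sig[["plot"]])[as.integer(data$plot)]
  if ("obs" %in% names(sig))
    eta <- eta + rnorm(data$n, 0, sig[["obs"]])
  rbinom(data$n, size = data$N, prob = plogis(eta))
}

#' Two-sided parametric-bootstrap p-value from z statistics
#'
#' The proportion of simulated z statistics at least as extreme (in absolute
#' value) as the observed one: `p = #\{|z_sim| >= |z_obs|\} / B`. A p of 0 is
#' stored as 0 and displayed as `< 1/B`.
#'
#' @param z_obs observed z statistic.
#' @param z_sim vector of simulated z statistics (NAs, from failed fits,
#'   are excluded from the denominator).
#' @return the p-value in `[0, 1]`.
#' @export
bootstrap_pvalue <- function(z_obs, z_sim) {
  z_sim <- z_sim[!is.na(z_sim)]
  if (!length(z_sim)) stop("no converged simulations")
  mean(abs(z_sim) >= abs(z_obs))
}

#' Parametric bootstrap test of one fixed effect
#'
#' Implements the simulation-based significance assessment of a fixed factor:
#' the reduced model (the factor's column removed; all other columns —
#' including the interaction — retained) is fitted to the observed data, `B`
#' datasets are simulated under it, the FULL model is refitted to each, and
#' the observed Wald z is referred to the simulated |z| distribution.
#' Simulation refits are warm-started from the observed-data full fit (an
#' efficiency device only). Non-converged refits are recorded, excluded from
#' the denominator, and trigger a warning when they exceed 2% of `B`.
#'
#' @param data a `"herb_model_data"`.
#' @param factor the fixed factor under test: one of `"DATE"`, `"SR"`,
#'   `"PD"`, `"SR:PD"`.
#' @param B number of bootstrap simulations (study default 1000).
#' @param seed integer seed (required).
#' @param re_terms random terms for both models.
#' @param control a [glmm_control()] list.
#' @param full optional pre-computed full-model fit on `data` (saves one fit).
#' @return an object of class `"herb_bootstrap"`: observed z, simulated z
#'   values, p-value, failure count, seed.
#' @export
bootstrap_p <- function(data, factor = c("DATE", "SR", "PD", "SR:PD"),
                        B = 1000, seed, re_terms = c("species", "plot", "obs"),
                        control = glmm_control(), full = NULL) {
  factor <- match.arg(factor)
  if (missing(seed) || is.null(seed))
    stop("a seed is required: bootstrap simulations must be reproducible")
  stopifnot(B >= 1)
  if (is.null(full))
    full <- fit_laplace(data, re_terms = re_terms, control = control)
  z_obs <- full$coefficients$z[full$coefficients$term == factor]
  if (!length(z_obs)) stop("factor '", factor, "' not in the full model")

  reduced_terms <- setdiff(full$fixed_terms, factor)
  reduced <- tryCatch(
    fit_laplace(data, fixed_terms = reduced_terms, re_terms = re_terms,
                control = control,
                start = list(sigma = full$sigma, beta = coef(full))),
    error = function(e) stop("reduced model failed to fit: ",
                             conditionMessage(e), call. = FALSE))

  warm <- list(sigma = full$sigma, beta = coef(full))
  # Refit efficiency devices (no statistical content): simulation refits are
  # warm-started at the observed-data optimum, skip the simplex restart, and
  # run at an outer tolerance of 1e-6 — z precision far below the Monte
  # Carlo resolution of the simulated |z| distribution. The observed-data
  # fits themselves use the caller's (default 1e-8) tolerance.
  refit_control <- control
  refit_control$restarts <- 0
  refit_control$outer_reltol <- max(control$outer_reltol, 1e-6)
  set.seed(seed)
  z_sim <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    y_b <- simulate_response_(reduced)
    data_b <- data
    data_b$y <- as.numeric(y_b)
    fit_b <- tryCatch(
      fit_laplace(data_b, fixed_terms = full$fixed_terms, re_terms = re_terms,
                  start = warm, control = refit_control),
      error = function(e) NULL)
    if (!is.null(fit_b) && isTRUE(fit_b$converged))
      z_sim[b] <- fit_b$coefficients$z[fit_b$coefficients$term == factor]
  }
  n_failed <- sum(is.na(z_sim))
  if (n_failed > 0.02 * B)
    warning(n_failed, " of ", B, " simulation fits failed to converge (> 2%)")
  structure(list(factor = factor, z_obs = z_obs, z_sim = z_sim,
                 p = bootstrap_pvalue(z_obs, z_sim),
                 B = B, n_failed = n_failed, seed = seed),
            class = "herb_bootstrap")
}

#' @export
print.herb_bootstrap <- function(x, ...) {
  pshow <- if (x$p == 0) paste0("< ", format(1 / (x$B - x$n_failed), digits = 3))
           else format(x$p, digits = 3)
  cat(sprintf("Parametric bootstrap for '%s': z_obs = %.3f, p = %s (B = %d, %d failed)\n",
              x$factor, x$z_obs, pshow, x$B, x$n_failed))
  invisible(x)
}

#' Serialize a bootstrap result as JSON
#' @param boot a `"herb_bootstrap"`.
#' @param file output path.
#' @param meta optional named list prepended to the output.
#' @param keep_z also include the full vector of simulated z values.
#' @export
write_bootstrap_json <- function(boot, file, meta = list(), keep_z = FALSE) {
  out <- c(meta, list(factor = boot$factor, z_obs = boot$z_obs, p = boot$p,
                      B = boot$B, n_failed = boot$n_failed, seed = boot$seed))
  if (keep_z) out$z_sim <- boot$z_sim
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
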