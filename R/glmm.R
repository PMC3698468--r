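#' Assemble model data for the leaf-damage GLMM
#'
#' Combines per-plant damage records with the centered plot-level predictor
#' table into the unit-of-analysis structure the fitter consumes: response
#' pairs (damaged, total), the fixed design matrix with columns
#' `(Intercept)`, `DATE`, `SR`, `PD`, `SR:PD` (all centered), and the three
#' crossed grouping factors — species, plot, and an observation factor with
#' one level per plant (the overdispersion device).
#'
#' @param plants data frame with columns `plot`, `species`, `damaged`,
#'   `total` (one row per plant).
#' @param predictors a `"herb_predictors"` table from [build_predictors()].
#' @return an object of class `"herb_model_data"`.
#' @export
build_model_data <- function(plants, predictors) {
  plants <- validate_plants(plants)
  if (!inherits(predictors, "herb_predictors"))
    stop("`predictors` must come from build_predictors()")
  orphan <- setdiff(unique(plants$plot), predictors$plot)
  if (length(orphan))
    stop("plant record(s) in plot(s) absent from predictor table: ",
         paste(orphan, collapse = ", "))
  idx <- match(plants$plot, predictors$plot)
  n <- nrow(plants)
  X <- cbind("(Intercept)" = rep(1, n),
             DATE = predictors$DATE_c[idx],
             SR = predictors$SR_c[idx],
             PD = predictors$PD_c[idx],
             "SR:PD" = predictors$SRPD_c[idx])
  model_data(plants$damaged, plants$total, X,
             species = factor(plants$species),
             plot = factor(plants$plot, levels = predictors$plot),
             predictors = predictors)
}

#' Low-level model-data constructor
#'
#' Builds a `"herb_model_data"` object directly from vectors and a design
#' matrix — useful for toy models, oracle tests, and simulation studies that
#' bypass the survey file formats.
#'
#' @param y damaged-leaf counts.
#' @param N total-leaf counts (same length).
#' @param X fixed-effect design matrix with column names.
#' @param species,plot grouping factors (coerced with [factor()]).
#' @param predictors optional `"herb_predictors"` table (needed by the
#'   estimate/surface functions).
#' @return an object of class `"herb_model_data"`.
#' @export
model_data <- function(y, N, X, species, plot, predictors = NULL) {
  y <- as.numeric(y); N <- as.numeric(N)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(length(N) == n, nrow(X) == n, !is.null(colnames(X)))
  if (any(N < 1) || any(y < 0) || any(y > N) || any(y != round(y)) ||
      any(N != round(N)))
    stop("need integer counts with 0 <= damaged <= total and total >= 1")
  structure(list(
    y = y, N = N, X = X,
    species = factor(species), plot = factor(plot),
    predictors = predictors,
    means = if (!is.null(predictors)) attr(predictors, "means"),
    n = n), class = "herb_model_data")
}

#' @export
print.herb_model_data <- function(x, ...) {
  cat("Leaf-damage model data: ", x$n, " plants, ",
      nlevels(x$species), " species, ", nlevels(x$plot), " plots\n", sep = "")
  invisible(x)
}

#' Control parameters for the Laplace fit
#'
#' @param outer_reltol relative tolerance on the Laplace objective for the
#'   outer variance-parameter optimization (Nelder-Mead on the log-SD scale).
#' @param outer_maxit maximum outer function evaluations per start.
#' @param inner_tol relative convergence tolerance of the penalized IRLS
#'   inner loop.
#' @param inner_maxit maximum inner iterations.
#' @param sigma_start starting value for each random-effect SD.
#' @param restarts number of restarts from the incumbent optimum.
#' @param boundary_tol SD estimates below this are reported as 0 with a
#'   boundary flag.
#' @export
glmm_control <- function(outer_reltol = 1e-8, outer_maxit = 2000,
                         inner_tol = 1e-12, inner_maxit = 60,
                         sigma_start = 1, restarts = 1,
                         boundary_tol = 1e-6) {
  list(outer_reltol = outer_reltol, outer_maxit = outer_maxit,
       inner_tol = inner_tol, inner_maxit = inner_maxit,
       sigma_start = sigma_start, restarts = restarts,
       boundary_tol = boundary_tol)
}

RE_TERMS <- c("species", "plot", "obs")

# low-level engine call; sigma named over RE_TERMS (0 = absent/fixed at zero).
# When `offset` is given the fixed part enters through it and X has zero
# columns (the solve is over random effects only); maxit = 0 evaluates the
# joint Hessian at `start` without iterating.
engine_call <- function(data, fixed_terms, sigma, start = NULL,
                        u_obs_start = NULL, control, compute_se = FALSE,
                        offset = NULL, maxit = control$inner_maxit) {
  X <- data$X[, fixed_terms, drop = FALSE]
  if (!is.null(offset)) X <- X[, integer(0), drop = FALSE]
  else offset <- numeric(data$n)
  fidx <- cbind(as.integer(data$species) - 1L, as.integer(data$plot) - 1L)
  nlev <- c(nlevels(data$species), nlevels(data$plot))
  k <- ncol(X) + sum(nlev)
  if (is.null(start)) start <- numeric(k)
  if (is.null(u_obs_start)) u_obs_start <- numeric(data$n)
  .pirls_engine(X, data$y, data$N, offset, fidx, nlev,
                c(sigma[["species"]], sigma[["plot"]]), sigma[["obs"]],
                start, u_obs_start, control$inner_tol, maxit,
                compute_se)
}

#' Fit the logit-normal-binomial mixed model by Laplace approximation
#'
#' Maximizes the Laplace-approximated marginal likelihood of the crossed
#' random-effects binomial model in two stages. Stage one profiles the fixed
#' effects through the inner penalized iteratively reweighted least squares
#' (PIRLS) solve for the joint (beta, u) mode and searches the log
#' random-effect SDs alone — a fast approximation used only for starting
#' values. Stage two is the production fit: a derivative-free Nelder-Mead
#' search (with a restart from the incumbent) moves the log-SDs and the fixed
#' effects jointly while PIRLS solves for the random-effect modes only, so
#' the objective — binomial deviance + |u|^2 + log-determinant of the scaled
#' penalized information — accounts for the determinant's dependence on the
#' fixed effects, as in the Laplace fit of lme4's `glmer`. The
#' observation-level factor's diagonal structure is exploited by a Schur
#' complement, so each inner step costs O(n k^2) with a small dense core.
#'
#' Standard errors of the fixed effects come from the corresponding block of
#' the inverse joint Hessian at the optimum; conditional modes and
#' conditional SDs of every random-effect level come from the random-effect
#' blocks of the same inverse.
#'
#' @param data a `"herb_model_data"` object.
#' @param fixed_terms columns of the design matrix to include (default all).
#' @param re_terms random terms to include, a subset of
#'   `c("species", "plot", "obs")`.
#' @param fixed_sigma optional named vector fixing some random-effect SDs
#'   (e.g. `c(species = 0, plot = 0, obs = 0)` for the plain-GLM limit);
#'   the remaining SDs are estimated.
#' @param start optional named list with elements `sigma` (named SD starting
#'   values) and/or `beta` (fixed-effect starting values) — used e.g. to warm
#'   start bootstrap refits.
#' @param control a [glmm_control()] list.
#' @return an object of class `"herb_glmm"`: coefficient table (estimate,
#'   SE, z), variance components, conditional modes and SDs per factor,
#'   Laplace log-likelihood, and a convergence record.
#' @export
fit_laplace <- function(data, fixed_terms = colnames(data$X),
                        re_terms = c("species", "plot", "obs"),
                        fixed_sigma = NULL, start = NULL,
                        control = glmm_control()) {
  stopifnot(inherits(data, "herb_model_data"))
  fixed_terms <- match.arg(fixed_terms, colnames(data$X), several.ok = TRUE)
  re_terms <- if (length(re_terms)) match.arg(re_terms, RE_TERMS, several.ok = TRUE)
              else character(0)
  if (qr(data$X[, fixed_terms, drop = FALSE])$rank < length(fixed_terms))
    stop("fixed design matrix is rank deficient for terms: ",
         paste(fixed_terms, collapse = ", "))
  if (!is.null(fixed_sigma) &&
      length(bad <- setdiff(names(fixed_sigma), RE_TERMS)))
    stop("unknown random term(s) in fixed_sigma: ", paste(bad, collapse = ", "))

  sigma <- setNames(numeric(3), RE_TERMS)
  active <- intersect(RE_TERMS, re_terms)
  if (!is.null(fixed_sigma)) sigma[names(fixed_sigma)] <- fixed_sigma
  free <- setdiff(active, names(fixed_sigma))
  sigma[setdiff(active, names(fixed_sigma))] <- control$sigma_start
  if (!is.null(start$sigma)) {
    ok <- intersect(names(start$sigma), free)
    sigma[ok] <- pmax(start$sigma[ok], control$boundary_tol)
  }

  p <- length(fixed_terms)
  nlev_small <- c(nlevels(data$species), nlevels(data$plot))
  k <- p + sum(nlev_small)

  # warm-start cache shared across outer evaluations
  cache <- new.env(parent = emptyenv())
  cache$start <- numeric(k)
  if (!is.null(start$beta)) {
    b <- start$beta[fixed_terms]
    b[is.na(b)] <- 0
    cache$start[seq_len(p)] <- b
  }
  cache$u_obs <- numeric(data$n)
  trace_obj <- numeric(0)

  run_engine <- function(sig, se = FALSE) {
    engine_call(data, fixed_terms, as.list(sig), start = cache$start,
                u_obs_start = cache$u_obs, control = control, compute_se = se)
  }

  # Outer optimizations run on the SD scale directly: the objective is even
  # in each SD (the design columns, penalty, and log-determinant all depend
  # on sigma^2), so sign-free search with |.| handles the boundary at 0 as a
  # smooth interior point instead of an infinitely flat log-scale tail.
  # The cap keeps the normal equations well-conditioned while exploring.
  objective <- function(theta) {
    sig <- sigma
    sig[free] <- pmin(abs(theta), 50)
    res <- run_engine(sig)
    cache$start <- c(res$coef, res$u)
    cache$u_obs <- res$u_obs
    trace_obj <<- c(trace_obj, res$objective)
    res$objective
  }

  # ---- stage 1: profiled PIRLS over the log-SDs only (fast starting values;
  # beta rides along at the joint penalized mode) -------------------------
  warm_supplied <- !is.null(start$sigma) && !is.null(start$beta) && length(free)
  opt_evals <- 0L
  if (length(free) && !warm_supplied) {
    reltol1 <- max(control$outer_reltol, 1e-6)
    if (length(free) == 1L) {
      opt <- stats::optimize(function(th) objective(th), c(0, 50), tol = 1e-4)
      sigma[free] <- opt$minimum
    } else {
      opt <- stats::optim(sigma[free], objective, method = "Nelder-Mead",
                          control = list(reltol = reltol1,
                                         maxit = control$outer_maxit))
      sigma[free] <- pmin(abs(opt$par), 50)
    }
  }
  beta_hat <- {
    r <- run_engine(sigma)
    cache$start <- c(r$coef, r$u); cache$u_obs <- r$u_obs
    drop(r$coef)
  }

  # ---- stage 2: true Laplace — the outer optimizer moves (log sigma, beta)
  # jointly while the inner PIRLS solves for the random-effect modes only,
  # so the objective accounts for the log-determinant's dependence on beta --
  Xsel <- data$X[, fixed_terms, drop = FALSE]
  fidx <- cbind(as.integer(data$species) - 1L, as.integer(data$plot) - 1L)
  nf <- length(free)
  u_cache <- cache$start[p + seq_len(sum(nlev_small))]
  free_idx <- match(free, RE_TERMS) - 1L
  # when every SD is (fixed at) zero the penalized mode IS the ML solution
  # and the log-determinant vanishes, so the joint stage has nothing to add
  do_joint <- nf > 0 || any(sigma[active] > 0)
  if (do_joint) {
    psi0 <- c(sigma[free], beta_hat)
    # warm starts (bootstrap refits) begin near the optimum, so the initial
    # simplex is kept small there; cold fits explore with the usual 0.1 step
    step0 <- if (warm_supplied) 0.02 else 0.1
    opt <- .laplace_nm(Xsel, data$y, data$N, fidx, nlev_small,
                       sigma[RE_TERMS], free_idx, psi0,
                       control$inner_tol, control$inner_maxit,
                       control$outer_reltol, control$outer_maxit, step0)
    trace_obj <- c(trace_obj, opt$trace)
    for (r in seq_len(control$restarts)) {
      opt2 <- .laplace_nm(Xsel, data$y, data$N, fidx, nlev_small,
                          sigma[RE_TERMS], free_idx, drop(opt$par),
                          control$inner_tol, control$inner_maxit,
                          control$outer_reltol, control$outer_maxit, 0.05)
      trace_obj <- c(trace_obj, opt2$trace)
      if (opt2$value <= opt$value) opt <- opt2
    }
    psi_hat <- drop(opt$par)
    if (nf) sigma[free] <- pmin(abs(psi_hat[seq_len(nf)]), 50)
    beta_hat <- psi_hat[nf + seq_len(p)]
    u_cache <- drop(opt$u)
    cache$u_obs <- drop(opt$u_obs)
  }
  opt_evals <- length(trace_obj)

  boundary <- setNames(sigma < control$boundary_tol & sigma > 0, RE_TERMS)
  sigma[sigma < control$boundary_tol] <- 0
  sigma[setdiff(RE_TERMS, active)] <- 0

  # random-effect modes at the reported estimates, then the joint Hessian
  # evaluated there (maxit = 0) for SEs and conditional SDs
  fin_u <- engine_call(data, fixed_terms, as.list(sigma), start = u_cache,
                       u_obs_start = cache$u_obs, control = control,
                       offset = drop(Xsel %*% beta_hat))
  if (!isTRUE(fin_u$converged)) {  # retry once from a cold start
    fin_u <- engine_call(data, fixed_terms, as.list(sigma),
                         control = control, offset = drop(Xsel %*% beta_hat))
  }
  if (!isTRUE(fin_u$converged))
    stop("inner PIRLS failed to converge at the outer optimum (",
         fin_u$iter, " iterations; sigma = ",
         paste(signif(sigma, 4), collapse = "/"),
         "); objective trace length ", length(trace_obj))
  fin <- engine_call(data, fixed_terms, as.list(sigma),
                     start = c(beta_hat, drop(fin_u$u)),
                     u_obs_start = drop(fin_u$u_obs),
                     control = control, compute_se = TRUE, maxit = 0L)
  fin$objective <- fin_u$objective
  if (max(abs(fin$eta)) > 25)
    warning("extreme linear predictor values (|eta| > 25): possible complete separation; estimates flagged")

  est <- drop(fin$coef)
  se <- drop(fin$se_beta)
  coefs <- data.frame(term = fixed_terms, estimate = est, se = se,
                      z = est / se, row.names = NULL)

  u <- drop(fin$u)
  csd <- drop(fin$cond_sd_u)
  split_u <- function(which) {
    offs <- c(species = 0L, plot = nlev_small[1])[[which]]
    len <- c(species = nlev_small[1], plot = nlev_small[2])[[which]]
    lev <- if (which == "species") levels(data$species) else levels(data$plot)
    sig_f <- sigma[[which]]
    data.frame(level = lev,
               mode = sig_f * u[offs + seq_len(len)],
               cond_sd = csd[offs + seq_len(len)], row.names = NULL)
  }
  ranef <- list()
  if ("species" %in% active) ranef$species <- split_u("species")
  if ("plot" %in% active) ranef$plot <- split_u("plot")
  if ("obs" %in% active)
    ranef$obs <- data.frame(level = seq_len(data$n),
                            mode = sigma[["obs"]] * drop(fin$u_obs),
                            cond_sd = drop(fin$cond_sd_obs), row.names = NULL)

  const <- sum(lchoose(data$N, data$y))
  structure(list(
    coefficients = coefs,
    vcov = fin$vcov_beta,
    sigma = sigma[active],
    vc = setNames(sigma[active]^2, active),
    boundary = boundary[active],
    ranef = ranef,
    logLik = -fin$objective / 2 + const,
    objective = fin$objective,
    fixed_terms = fixed_terms,
    re_terms = active,
    converged = TRUE,
    n_outer_evals = opt_evals,
    inner_iter_final = fin$iter,
    opt_trace = trace_obj,
    data = data,
    control = control), class = "herb_glmm")
}

#' @export
print.herb_glmm <- function(x, ...) {
  cat("Logit-normal-binomial mixed model (Laplace approximation)\n")
  cat("  n =", x$data$n, "plants; log-likelihood", format(x$logLik, digits = 7), "\n")
  cat("Fixed effects:\n")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 3)), row.names = FALSE)
  cat("Variance components (latent logit scale):\n")
  for (t in names(x$vc))
    cat(sprintf("  sigma^2_%s = %.4g%s\n", t, x$vc[[t]],
                if (isTRUE(x$boundary[[t]])) " (boundary)" else ""))
  invisible(x)
}

#' @export
coef.herb_glmm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.herb_glmm <- function(object, ...) {
  structure(object$logLik, df = length(object$fixed_terms) + length(object$sigma),
            class = "logLik")
}

#' Laplace log-likelihood at given parameter values
#'
#' Evaluates the Laplace-approximated marginal log-likelihood (including the
#' binomial normalizing constant) at user-supplied fixed effects and
#' random-effect SDs, solving only for the random-effect modes. Useful for
#' likelihood surface exploration and for validating the approximation
#' against quadrature.
#'
#' @param data a `"herb_model_data"`.
#' @param beta named vector of fixed effects (names must be design columns).
#' @param sigma named vector of SDs over a subset of
#'   `c("species", "plot", "obs")`; omitted terms are 0.
#' @param control a [glmm_control()] list.
#' @return the log-likelihood value.
#' @export
laplace_loglik <- function(data, beta, sigma = c(species = 0, plot = 0, obs = 0),
                           control = glmm_control()) {
  stopifnot(inherits(data, "herb_model_data"),
            all(names(beta) %in% colnames(data$X)),
            all(names(sigma) %in% RE_TERMS))
  sig <- setNames(numeric(3), RE_TERMS)
  sig[names(sigma)] <- sigma
  off <- drop(data$X[, names(beta), drop = FALSE] %*% beta)
  res <- engine_call(data, names(beta), as.list(sig), control = control,
                     offset = off)
  if (!isTRUE(res$converged))
    stop("random-effect mode search failed to converge at these parameters")
  -res$objective / 2 + sum(lchoose(data$N, data$y))
}

#' Linear predictor for new plot-level predictor rows
#'
#' Assembles the logit-scale prediction from an explicit choice of fixed
#' terms and random-effect conditional modes; components not requested are
#' simply omitted. Predictors are supplied on the original scale and centered
#' internally with the means stored at model-building time.
#'
#' @param fit a fitted `"herb_glmm"`.
#' @param newdata data frame; needs original-scale columns `SR`, `PD`,
#'   `DATE` for whichever fixed terms are requested, and `plot` / `species`
#'   columns for requested random terms.
#' @param include_fixed fixed terms to include (default: all fitted).
#' @param include_ranef random terms whose conditional modes to add
#'   (subset of `c("species", "plot")`); unknown levels are an error, never
#'   an implicit zero.
#' @return numeric vector of logit-scale values.
#' @export
predict_linear <- function(fit, newdata, include_fixed = fit$fixed_terms,
                           include_ranef = character()) {
  stopifnot(inherits(fit, "herb_glmm"))
  if (length(include_fixed))
    include_fixed <- match.arg(include_fixed, fit$fixed_terms, several.ok = TRUE)
  if (length(include_ranef))
    include_ranef <- match.arg(include_ranef, c("species", "plot"), several.ok = TRUE)
  b <- coef(fit)
  mns <- fit$data$means
  n <- nrow(newdata)
  eta <- numeric(n)
  for (term in include_fixed) {
    val <- switch(term,
      "(Intercept)" = rep(1, n),
      "DATE" = newdata$DATE - mns[["DATE"]],
      "SR" = newdata$SR - mns[["SR"]],
      "PD" = newdata$PD - mns[["PD"]],
      "SR:PD" = (newdata$SR - mns[["SR"]]) * (newdata$PD - mns[["PD"]]))
    if (is.null(val) || anyNA(val))
      stop("newdata lacks values needed for term '", term, "'")
    eta <- eta + b[[term]] * val
  }
  for (rt in include_ranef) {
    if (is.null(fit$ranef[[rt]])) stop("model has no '", rt, "' random term")
    lev <- as.character(newdata[[rt]])
    if (is.null(newdata[[rt]])) stop("newdata lacks column '", rt, "'")
    hit <- match(lev, fit$ranef[[rt]]$level)
    if (anyNA(hit))
      stop("unknown ", rt, " level(s): ",
           paste(unique(lev[is.na(hit)]), collapse = ", "))
    eta <- eta + fit$ranef[[rt]]$mode[hit]
  }
  unname(eta)
}

#' Serialize a fit summary as JSON
#'
#' Coefficients with SEs and z, variance components, convergence record, and
#' optional metadata (seed, config hash). Deterministic: no timestamps.
#'
#' @param fit a `"herb_glmm"`.
#' @param file output path.
#' @param meta optional named list prepended to the output.
#' @export
write_fit_json <- function(fit, file, meta = list()) {
  out <- c(meta, list(
    coefficients = fit$coefficients,
    variance_components = as.list(fit$vc),
    boundary = as.list(fit$boundary),
    logLik = fit$logLik,
    converged = fit$converged,
    n_outer_evals = fit$n_outer_evals))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write conditional modes of one factor as TSV
#' @param fit a `"herb_glmm"`.
#' @param factor one of the fitted random terms.
#' @param file output path.
#' @export
write_ranef_tsv <- function(fit, factor, file) {
  if (is.null(fit$ranef[[factor]])) stop("no such random term: ", factor)
  write.table(fit$ranef[[factor]], file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
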