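#' Plot-level estimated proportional leaf damage
#'
#' For plot *j*, after accounting for species-level variation, sampling date,
#' and observation-level dispersion:
#' \deqn{p_j = \mathrm{logit}^{-1}(\alpha + \hat\mu_j^{plot} + \beta_{pd} PD_j
#'   + \beta_{sr} SR_j + \beta_{pd*sr}(PD*SR)_j)}
#' using the plot's conditional mode and the centered plot predictors; the
#' DATE, species, and observation terms are excluded. Display bounds are the
#' back-transformed conditional mode +/- 1 conditional SD (asymmetric on the
#' probability scale).
#'
#' @param fit a converged `"herb_glmm"` fitted with a `plot` random term and
#'   model data carrying a predictor table.
#' @return data frame: `plot`, `estimate`, `lower`, `upper` (probabilities).
#' @export
plot_damage <- function(fit) {
  stopifnot(inherits(fit, "herb_glmm"))
  if (is.null(fit$ranef$plot)) stop("model has no plot random term")
  pred <- fit$data$predictors
  if (is.null(pred)) stop("model data carries no predictor table")
  re <- fit$ranef$plot
  hit <- match(re$level, as.character(pred$plot))
  if (anyNA(hit)) stop("plot level(s) missing from predictor table: ",
                       paste(re$level[is.na(hit)], collapse = ", "))
  b <- coef(fit)
  fx <- intersect(c("SR", "PD", "SR:PD"), fit$fixed_terms)
  eta_fix <- b[["(Intercept)"]] +
    drop(as.matrix(cbind(SR = pred$SR_c, PD = pred$PD_c,
                         "SR:PD" = pred$SRPD_c)[hit, fx, drop = FALSE]) %*% b[fx])
  data.frame(plot = re$level,
             estimate = plogis(eta_fix + re$mode),
             lower = plogis(eta_fix + re$mode - re$cond_sd),
             upper = plogis(eta_fix + re$mode + re$cond_sd),
             row.names = NULL)
}

#' Species-level estimated proportional leaf damage
#'
#' For species *k*, after accounting for plot-level variation, sampling date,
#' and observation: \eqn{p_k = \mathrm{logit}^{-1}(\alpha + \hat\mu_k^{species})},
#' with bounds from the conditional mode +/- 1 conditional SD.
#'
#' @param fit a converged `"herb_glmm"` fitted with a `species` random term.
#' @return data frame: `species`, `estimate`, `lower`, `upper`.
#' @export
species_damage <- function(fit) {
  stopifnot(inherits(fit, "herb_glmm"))
  if (is.null(fit$ranef$species)) stop("model has no species random term")
  re <- fit$ranef$species
  a <- coef(fit)[["(Intercept)"]]
  data.frame(species = re$level,
             estimate = plogis(a + re$mode),
             lower = plogis(a + re$mode - re$cond_sd),
             upper = plogis(a + re$mode + re$cond_sd),
             row.names = NULL)
}

#' Fixed-effects response surface over species richness and PSE
#'
#' Back-transformed fixed-effects-only predictions (no random terms, no DATE)
#' on a grid of original-scale species richness and phylogenetic diversity
#' values; centering uses the stored means, under which omitting DATE equals
#' evaluating it at its mean. Default `sr` values 3, 6, 12, 17 span the
#' richness range of the study design this mirrors.
#'
#' @param fit a converged `"herb_glmm"`.
#' @param sr species-richness values (original scale).
#' @param pd PSE grid (original scale); default: 25 points over the observed
#'   PD range.
#' @return matrix of fitted probabilities, rows indexed by `pd`, columns by
#'   `sr`, with a `grid` attribute holding the long-format data frame
#'   (`sr`, `pd`, `fitted_p`).
#' @export
fitted_surface <- function(fit, sr = c(3, 6, 12, 17), pd = NULL) {
  stopifnot(inherits(fit, "herb_glmm"))
  pred <- fit$data$predictors
  if (is.null(pd)) {
    if (is.null(pred)) stop("supply `pd` explicitly: no predictor table stored")
    pd <- seq(min(pred$PD), max(pred$PD), length.out = 25)
  }
  if (!is.null(pred)) {
    rg <- attr(pred, "ranges")
    if (!is.null(rg) && (any(sr < rg$SR[1] | sr > rg$SR[2]) ||
                         any(pd < rg$PD[1] | pd > rg$PD[2])))
      warning("grid extends outside the observed predictor hull; extrapolating")
  }
  grid <- expand.grid(pd = pd, sr = sr)
  eta <- predict_linear(fit, data.frame(SR = grid$sr, PD = grid$pd),
                        include_fixed = intersect(c("(Intercept)", "SR", "PD", "SR:PD"),
                                                  fit$fixed_terms))
  M <- matrix(plogis(eta), nrow = length(pd), ncol = length(sr),
              dimnames = list(pd = format(pd, digits = 6),
                              sr = format(sr, digits = 6)))
  attr(M, "grid") <- data.frame(sr = grid$sr, pd = grid$pd, fitted_p = plogis(eta))
  M
}

#' Write damage estimates / surface grids as TSV
#' @param x a data frame from [plot_damage()] or [species_damage()], or a
#'   matrix from [fitted_surface()] (its long-format grid is written).
#' @param file output path.
#' @export
write_estimates_tsv <- function(x, file) {
  if (is.matrix(x)) x <- attr(x, "grid")
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
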