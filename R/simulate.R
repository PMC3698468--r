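#' Configuration of a synthetic herbivory study
#'
#' Defaults describe the field design this package emulates: a 52-species
#' forb pool (27 phytometer species whose damage is measured plus 25 others),
#' 38 plots with 3-17 species each, quadrat abundances 1-4, 10 sampled plants
#' per phytometer species per plot, sampling spread over a two-week window,
#' and damage generated under the logit-normal-binomial model at its reported
#' operating point (fixed effects 0.15, 0.10, 0.23, -0.19, -0.28 for
#' intercept, date, SR, PD, SR:PD; latent variances 2.4, 0.26, 0.82 for
#' species, plot, observation). Leaf counts are 1 + Poisson(`leaf_mean`),
#' a declared convention of the generator.
#'
#' @param n_pool species-pool size (tips of the simulated tree).
#' @param n_plots number of plots.
#' @param richness integer range (low, high) of per-plot species richness.
#' @param lambda phylogenetic clustering strength (>= 0): species join a plot
#'   with probability proportional to `exp(-lambda * patristic distance)` to
#'   a random focal species. 0 gives uniform assembly (PSE independent of
#'   SR); large values give phylogenetically clustered, low-PSE plots.
#' @param n_phytometers number of species for which damage is recorded (the
#'   most frequently occurring species across plots).
#' @param plants_per plants sampled per phytometer species per plot.
#' @param leaf_mean mean of the Poisson part of the leaf-count distribution.
#' @param date_range integer day-offset range of sampling dates.
#' @param alpha,beta_date,beta_sr,beta_pd,beta_srpd true fixed effects
#'   (logit scale, on centered predictors).
#' @param sigma2_species,sigma2_plot,sigma2_obs true latent variances.
#' @return a list of class `"herb_sim_config"`.
#' @export
sim_config <- function(n_pool = 52, n_plots = 38, richness = c(3L, 17L),
                       lambda = 0, n_phytometers = 27, plants_per = 10,
                       leaf_mean = 15, date_range = c(0L, 13L),
                       alpha = 0.15, beta_date = 0.10, beta_sr = 0.23,
                       beta_pd = -0.19, beta_srpd = -0.28,
                       sigma2_species = 2.4, sigma2_plot = 0.26,
                       sigma2_obs = 0.82) {
  cfg <- list(n_pool = n_pool, n_plots = n_plots, richness = as.integer(richness),
              lambda = lambda, n_phytometers = n_phytometers,
              plants_per = plants_per, leaf_mean = leaf_mean,
              date_range = as.integer(date_range), alpha = alpha,
              beta_date = beta_date, beta_sr = beta_sr, beta_pd = beta_pd,
              beta_srpd = beta_srpd, sigma2_species = sigma2_species,
              sigma2_plot = sigma2_plot, sigma2_obs = sigma2_obs)
  stopifnot(cfg$n_pool >= cfg$richness[2], cfg$richness[1] >= 1,
            cfg$n_phytometers <= cfg$n_pool, cfg$plants_per >= 1,
            cfg$lambda >= 0, cfg$sigma2_species >= 0, cfg$sigma2_plot >= 0,
            cfg$sigma2_obs >= 0)
  class(cfg) <- "herb_sim_config"
  cfg
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' A Yule (pure-birth) tree with depth normalized to 1 and tips labeled
#' `sp01`, `sp02`, ... Identical seeds give identical trees.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(tip_depths(tr))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

#' Assemble plot communities on a phylogeny
#'
#' Per plot: richness is drawn uniformly from the configured range, a focal
#' tip is picked at random, and species are sampled without replacement with
#' probability proportional to `exp(-lambda * patristic distance to focal)`;
#' abundances are uniform on 1-4 and sampling dates uniform over the date
#' range.
#'
#' @param tree the species-pool phylogeny.
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `composition` (long data frame), `dates` (plot, date),
#'   and `diversity` (realized per-plot SR/PSV/PSE from [plot_diversity()]).
#' @export
assemble_communities <- function(tree, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$richness[2] > length(tree$tip.label))
    stop("richness exceeds species pool")
  D <- stats::cophenetic(tree)
  tips <- tree$tip.label
  plots <- sprintf("plot%02d", seq_len(config$n_plots))
  comp <- vector("list", config$n_plots)
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L  # safe for lo == hi
  for (i in seq_len(config$n_plots)) {
    rich <- rint(config$richness[1], config$richness[2])
    focal <- sample(tips, 1)
    w <- exp(-config$lambda * D[focal, tips])
    sp <- sample(tips, rich, prob = w)
    comp[[i]] <- data.frame(plot = plots[i], species = sort(sp),
                            abundance = sample(1:4, rich, replace = TRUE))
  }
  composition <- do.call(rbind, comp)
  dates <- data.frame(
    plot = plots,
    date = config$date_range[1] +
      sample.int(config$date_range[2] - config$date_range[1] + 1L,
                 config$n_plots, replace = TRUE) - 1L)
  list(composition = composition, dates = dates,
       diversity = plot_diversity(tree, composition))
}

#' Simulate per-plant binomial leaf damage under the latent logit model
#'
#' Phytometer species are the `n_phytometers` most frequently occurring
#' species across plots (ties broken by label). For every phytometer species
#' present in a plot, `plants_per` plants are sampled; each plant's leaf
#' count is `1 + Poisson(leaf_mean)` and its damaged-leaf count is binomial
#' with success probability `logit^-1` of the configured linear predictor
#' (centered predictors computed from the generated plots themselves) plus
#' species, plot, and per-plant Gaussian effects.
#'
#' @param tree the species-pool phylogeny.
#' @param composition,dates generated by [assemble_communities()].
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `plants` (plot, species, damaged, total), `predictors`
#'   (the centered table), and `truth` (realized random effects and the
#'   config) — everything a recovery test needs.
#' @export
simulate_damage <- function(tree, composition, dates, config = sim_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  diversity <- plot_diversity(tree, composition)
  predictors <- build_predictors(diversity, dates)

  freq <- table(composition$species[composition$abundance > 0])
  ord <- order(-as.integer(freq), names(freq))
  phyto <- names(freq)[ord][seq_len(min(config$n_phytometers, length(freq)))]

  pres <- composition[composition$abundance > 0 & composition$species %in% phyto &
                        composition$plot %in% predictors$plot, ]
  pres <- pres[order(pres$plot, pres$species), ]
  skel <- pres[rep(seq_len(nrow(pres)), each = config$plants_per),
               c("plot", "species")]
  rownames(skel) <- NULL
  n <- nrow(skel)

  u_species <- setNames(rnorm(length(phyto), 0, sqrt(config$sigma2_species)),
                        sort(phyto))
  u_plot <- setNames(rnorm(nrow(predictors), 0, sqrt(config$sigma2_plot)),
                     predictors$plot)
  u_obs <- rnorm(n, 0, sqrt(config$sigma2_obs))
  total <- 1L + rpois(n, config$leaf_mean)

  ip <- match(skel$plot, predictors$plot)
  eta <- config$alpha +
    config$beta_date * predictors$DATE_c[ip] +
    config$beta_sr * predictors$SR_c[ip] +
    config$beta_pd * predictors$PD_c[ip] +
    config$beta_srpd * predictors$SRPD_c[ip] +
    u_species[skel$species] + u_plot[skel$plot] + u_obs
  damaged <- rbinom(n, size = total, prob = plogis(eta))

  plants <- data.frame(plot = skel$plot, species = skel$species,
                       damaged = damaged, total = total)
  list(plants = plants, predictors = predictors,
       truth = list(config = config, phytometers = phyto,
                    u_species = u_species, u_plot = u_plot, u_obs = u_obs,
                    diversity = diversity))
}

#' Simulate a complete synthetic study
#'
#' Tree, communities, and damage in one call, with all randomness derived
#' from one root seed (split per stage).
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (required for reproducibility).
#' @return a list of class `"herb_sim"`: `tree`, `composition`, `dates`,
#'   `diversity`, `predictors`, `plants`, `truth`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("a root seed is required")
  seed <- as.integer(seed)
  tree <- simulate_tree(config$n_pool, seed = seed + 1L)
  comm <- assemble_communities(tree, config, seed = seed + 2L)
  dmg <- simulate_damage(tree, comm$composition, comm$dates, config,
                         seed = seed + 3L)
  structure(list(tree = tree, composition = comm$composition,
                 dates = comm$dates, diversity = comm$diversity,
                 predictors = dmg$predictors, plants = dmg$plants,
                 truth = dmg$truth, config = config, seed = seed),
            class = "herb_sim")
}

#' @export
print.herb_sim <- function(x, ...) {
  cat("Synthetic herbivory study (seed ", x$seed, "): ",
      nrow(x$predictors), " plots, ", length(x$truth$phytometers),
      " phytometer species, ", nrow(x$plants), " plants, mean damage ",
      round(100 * sum(x$plants$damaged) / sum(x$plants$total), 1), "%\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic study in the pipeline's input formats
#'
#' `tree.nwk` (Newick), `composition.tsv`, `dates.tsv`, `plants.tsv`, and
#' `truth.json` (generating parameters and realized random effects).
#'
#' @param sim a `"herb_sim"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_composition_table(sim$composition, file.path(dir, "composition.tsv"))
  write.table(sim$dates, file.path(dir, "dates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$plants, file.path(dir, "plants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(sim$config), seed = sim$seed,
         phytometers = sim$truth$phytometers,
         u_species = as.list(sim$truth$u_species),
         u_plot = as.list(sim$truth$u_plot)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Deterministic hash of a synthetic study
#'
#' MD5 of the serialized tree, composition, dates, and plant table; equal
#' configs and seeds give equal hashes.
#'
#' @param sim a `"herb_sim"`.
#' @return a length-1 character MD5 string.
#' @export
study_hash <- function(sim) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  payload <- list(tree = ape::write.tree(sim$tree),
                  composition = sim$composition, dates = sim$dates,
                  plants = sim$plants)
  writeBin(serialize(payload, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}
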