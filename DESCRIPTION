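Package: herbdiv
Title: Phylogenetic Diversity and Invertebrate Herbivory in Plant Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community-phylogenetic analyses of invertebrate leaf
    herbivory in plant communities. Computes abundance-weighted phylogenetic
    diversity (Phylogenetic Species Evenness, PSE, and its equal-abundance
    special case PSV) for survey plots from a dated phylogeny and quadrat
    presence data; fits a logit-normal-binomial generalized linear mixed model
    of per-plant leaf damage with crossed species, plot, and observation-level
    random effects by Laplace approximation (penalized iteratively reweighted
    least squares with profiled fixed effects); derives plot- and species-level
    damage estimates from conditional modes; and assesses fixed effects with a
    parametric bootstrap of the Wald z statistic. Includes a synthetic-data
    generator that simulates complete studies (pure-birth trees, community
    assembly with controllable phylogenetic clustering, and binomial damage
    under the fitted model) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
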