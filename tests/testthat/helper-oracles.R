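# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: correlation matrices come straight from ape::vcv,
# quadratic forms are brute-forced by explicit loops, and the mixed-model
# likelihood oracle integrates by adaptive Gauss-Hermite quadrature with
# nodes derived from the Golub-Welsch eigenproblem.

# Abundance-weighted evenness by individual expansion: each species present
# becomes m_i individuals joined by zero-length branches (so same-species
# individuals have correlation 1), the Brownian trait variance term is
# accumulated pair by pair over individuals, and the index's evenness
# standardization N(N - mbar) is applied.
pse_expansion_oracle <- function(tree, m) {
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0) V <- V + tree$root.edge
  C <- stats::cov2cor(V)
  m <- m[m > 0]
  sp <- names(m)
  ind <- rep(sp, times = m)        # one entry per individual
  N <- length(ind)
  S <- 0
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      S <- S + if (ind[a] == ind[b]) 1 else C[ind[a], ind[b]]
    }
  }
  mbar <- mean(m)
  (N * N - S) / (N^2 - N * mbar)
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch).
gauss_hermite <- function(nq) {
  i <- seq_len(nq - 1)
  J <- matrix(0, nq, nq)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

# Marginal log-likelihood of a single-factor binomial logit mixed model by
# adaptive Gauss-Hermite quadrature (includes the binomial lchoose constant).
agq_loglik <- function(y, size, eta_fixed, group, sigma, nq = 25) {
  gh <- gauss_hermite(nq)
  groups <- split(seq_along(y), group)
  ll <- sum(lchoose(size, y))
  for (idx in groups) {
    yi <- y[idx]; ni <- size[idx]; oi <- eta_fixed[idx]
    lint <- function(b) {   # log integrand
      eta <- oi + b
      sum(yi * eta - ni * log1p(exp(pmin(eta, 700)))) +
        stats::dnorm(b, 0, sigma, log = TRUE)
    }
    bhat <- stats::optimize(lint, c(-10 * sigma - 5, 10 * sigma + 5),
                            maximum = TRUE, tol = 1e-10)$maximum
    p <- stats::plogis(oi + bhat)
    curv <- sum(ni * p * (1 - p)) + 1 / sigma^2
    tau <- 1 / sqrt(curv)
    b_j <- bhat + sqrt(2) * tau * gh$nodes
    lv <- vapply(b_j, lint, 0) + gh$nodes^2 + log(sqrt(2) * tau * gh$weights)
    mx <- max(lv)
    ll <- ll + mx + log(sum(exp(lv - mx)))
  }
  ll
}

# E[plogis(a + Z)], Z ~ N(0, s2), by Gauss-Hermite (for marginal-mean checks)
marginal_mean_logit <- function(a, s2, nq = 40) {
  gh <- gauss_hermite(nq)
  sum(gh$weights / sqrt(pi) * stats::plogis(a + sqrt(2 * s2) * gh$nodes))
}

prune_phylogeny_or_self <- function(tree, keep) {
  if (length(setdiff(tree$tip.label, keep))) prune_phylogeny(tree, keep) else tree
}

# random ultrametric tree + integer abundances for property tests
random_tree_abund <- function(n_tips, max_abund = 4) {
  tr <- ape::rcoal(n_tips)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  m <- setNames(sample(0:max_abund, n_tips, replace = TRUE), tr$tip.label)
  if (sum(m > 0) < 2) m[sample(n_tips, 2)] <- 1L
  list(tree = tr, m = m)
}
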