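# Shared fixture builders. Everything is generated in code so the suite is
# self-contained.

# Fully crossed individual x year Bernoulli design with known parameters.
glmm_fixture <- function(n_ind, n_yr, seed, beta = c(0.2, 0.4),
                         sigma_ind = 0.3, sigma_year = 0.2) {
  set.seed(seed)
  g_ind <- factor(rep(seq_len(n_ind), each = n_yr))
  g_year <- factor(rep(seq_len(n_yr), n_ind))
  x <- rnorm(n_ind * n_yr)
  u <- rnorm(n_ind, 0, sigma_ind)
  v <- rnorm(n_yr, 0, sigma_year)
  eta <- beta[1] + beta[2] * x + u[as.integer(g_ind)] + v[as.integer(g_year)]
  y <- rbinom(length(eta), 1, plogis(eta))
  list(y = y, X = cbind(`(Intercept)` = 1, x = x),
       groups = list(individual = g_ind, year = g_year),
       beta = beta, sigma2 = c(individual = sigma_ind^2, year = sigma_year^2))
}

# Independent iteratively-reweighted least-squares logistic fit, used as the
# oracle for the zero-variance limit of the mixed model.
irls_logistic <- function(y, X, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# Single-random-intercept marginal log-likelihood by adaptive 1-D quadrature,
# independent of the package's Gauss-Hermite implementation.
loglik_1d_adaptive <- function(y, X, beta, sigma2, g) {
  eta0 <- drop(X %*% beta)
  g <- as.factor(g)
  sgn <- ifelse(y == 1, 1, -1)
  total <- 0
  for (lev in levels(g)) {
    sel <- g == lev
    f <- function(u) {
      vapply(u, function(ui) {
        exp(sum(plogis(sgn[sel] * (eta0[sel] + ui), log.p = TRUE))) *
          dnorm(ui, 0, sqrt(sigma2))
      }, numeric(1))
    }
    total <- total + log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  total
}

# Tiny hand-built raw records table (one bird unless stated).
tiny_raw_records <- function() {
  data.frame(
    individual_id = "b1", species = "WA", sex = "F",
    season = c(2000, 2001, 2003), age = c(10, 11, 13),
    outcome = c(0, 1, 1), partner_id = c("A", "A", "B"),
    stringsAsFactors = FALSE
  )
}

# Small annotated simulation shared by decomposition tests.
sim_annotated <- function(n = 250, seed = 1, profile = "biennial_short", ...) {
  cfg <- simulation_config(n_individuals = n, species_profile = profile,
                           n_years = 35, seed = seed, ...)
  sim <- simulate_population(cfg)
  list(cfg = cfg,
       records = annotate_records(sim$records, study_end = cfg$n_years),
       truth = sim$truth)
}
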