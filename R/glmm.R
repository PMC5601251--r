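#' Fit a Bernoulli GLMM with up to two crossed random intercepts
#'
#' Binomial (0/1) mixed model with logit link, maximising the
#' Laplace-approximated marginal likelihood over the fixed effects and the
#' random-intercept variances, via `lme4::glmer` (`nAGQ = 1`). With an empty
#' `groups` list the model reduces to ordinary logistic regression
#' (`stats::glm`), which is also the exact sigma^2 = 0 limit of the mixed
#' model.
#'
#' The AIC is `-2 * logLik + 2 * k` with `k` counting one parameter per fixed
#' effect and one per random-effect variance; variances estimated at the
#' boundary are reported as 0 (with `boundary = TRUE`) but still counted in
#' `k`. A fixed-effect estimate exceeding 15 in absolute value on the logit
#' scale is treated as complete separation and raised as an error.
#'
#' @param y Binary response vector.
#' @param X Design matrix (include an intercept column explicitly); must be
#'   full column rank.
#' @param groups Named list of 0-2 grouping factors (e.g.
#'   `list(individual = ..., year = ...)`), each aligned with `y`.
#' @return Object of class `glmm_fit`: `beta` (named), `se`, `vcov`,
#'   `sigma2` (named per grouping factor), `boundary`, `loglik`, `k`, `aic`,
#'   `n_obs`, `converged`, plus the data (`y`, `X`, `groups`) retained for
#'   refits, and the underlying `merMod`/`glm` object as `engine`.
#' @export
fit_glmm <- function(y, X, groups = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (all(y == 1) || all(y == 0)) stop("complete separation: response is constant")
  groups <- lapply(groups, function(g) {
    g <- droplevels(as.factor(g))
    stopifnot(length(g) == length(y))
    g
  })
  if (length(groups) > 2) stop("at most two grouping factors are supported")
  for (nm in names(groups)) {
    if (nlevels(groups[[nm]]) < 2) {
      stop("grouping factor '", nm, "' needs >= 2 levels for a variance")
    }
  }

  p <- ncol(X)
  if (length(groups) == 0) {
    eng <- stats::glm.fit(X, y, family = stats::binomial())
    beta <- eng$coefficients
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    vc <- solve(crossprod(X, X * W))
    ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
    sigma2 <- numeric(0)
    boundary <- logical(0)
    converged <- eng$converged
  } else {
    dat <- data.frame(.y = y, check.names = FALSE)
    xn <- paste0(".x", seq_len(p))
    for (j in seq_len(p)) dat[[xn[j]]] <- X[, j]
    gn <- paste0(".g", seq_along(groups))
    for (j in seq_along(groups)) dat[[gn[j]]] <- groups[[j]]
    fml <- stats::as.formula(paste(
      ".y ~ 0 +", paste(xn, collapse = " + "), "+",
      paste(sprintf("(1 | %s)", gn), collapse = " + ")
    ))
    eng <- suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = dat, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))
    ))
    beta <- lme4::fixef(eng)
    names(beta) <- colnames(X)
    vc <- as.matrix(stats::vcov(eng))
    dimnames(vc) <- list(colnames(X), colnames(X))
    vcomp <- as.data.frame(lme4::VarCorr(eng))
    sigma2 <- vcomp$vcov[match(gn, vcomp$grp)]
    names(sigma2) <- names(groups)
    boundary <- sigma2 < 1e-8
    sigma2[boundary] <- 0
    ll <- as.numeric(stats::logLik(eng))
    converged <- length(eng@optinfo$conv$lme4) == 0 && eng@optinfo$conv$opt == 0
  }
  if (any(abs(beta) > 15)) stop("complete separation detected (|beta| > 15)")
  k <- p + length(groups)
  fit <- list(
    beta = beta, se = sqrt(diag(vc)), vcov = vc,
    sigma2 = sigma2, boundary = boundary,
    loglik = ll, k = k, aic = -2 * ll + 2 * k,
    n_obs = length(y), converged = converged,
    y = y, X = X, groups = groups, engine = eng
  )
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Bernoulli GLMM (logit link), n =", x$n_obs, "\n")
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$beta / x$se)
  print(round(tab, 4))
  if (length(x$sigma2) > 0) {
    cat("Random-intercept variances:\n")
    print(round(x$sigma2, 4))
  }
  cat(sprintf("logLik (Laplace) = %.3f, k = %d, AIC = %.2f\n", x$loglik, x$k, x$aic))
  invisible(x)
}

#' AIC of a fitted model
#'
#' @param fit A `glmm_fit`.
#' @return `-2 * logLik + 2 * k`, `k` counting fixed effects plus one per
#'   random-effect variance (boundary variances included).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  fit$aic
}

#' AIC difference between two fits of the same response
#'
#' @param fit_a,fit_b `glmm_fit` objects fitted to the identical response
#'   vector (checked).
#' @return `aic(fit_a) - aic(fit_b)`.
#' @export
delta_aic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "glmm_fit"), inherits(fit_b, "glmm_fit"))
  if (length(fit_a$y) != length(fit_b$y) || !all(fit_a$y == fit_b$y)) {
    stop("models were fitted to different responses; AIC not comparable")
  }
  fit_a$aic - fit_b$aic
}

#' Fixed-effect predictions on the probability scale
#'
#' Point predictions `plogis(X_new %*% beta)` with delta-method standard
#' errors propagated from the fixed-effect covariance, not accounting for the
#' random effects (i.e. predictions for an average individual in an average
#' year).
#'
#' @param fit A `glmm_fit`.
#' @param X_new New design matrix with the same columns as the fit.
#' @return Data frame with columns `fit` and `se`.
#' @export
predict_fixed <- function(fit, X_new) {
  stopifnot(inherits(fit, "glmm_fit"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$beta)) stop("X_new column count does not match fit")
  if (!is.null(colnames(X_new)) && !identical(colnames(X_new), names(fit$beta))) {
    stop("X_new columns do not match the fitted design")
  }
  eta <- drop(X_new %*% fit$beta)
  se_eta <- sqrt(rowSums((X_new %*% fit$vcov) * X_new))
  p <- stats::plogis(eta)
  data.frame(fit = p, se = p * (1 - p) * se_eta)
}

bernoulli_loglik <- function(y, eta) {
  sum(stats::plogis(ifelse(y == 1, 1, -1) * eta, log.p = TRUE))
}

#' Laplace-approximate marginal log-likelihood at given parameters
#'
#' Standalone evaluator of the Laplace approximation for the Bernoulli GLMM
#' with up to two crossed random intercepts: Newton iteration to the joint
#' conditional mode of the random effects, then the usual
#' `penalised loglik - 0.5 * log det` correction. At the fitted optimum this
#' reproduces the `logLik` reported by [fit_glmm()]. Variances of exactly 0
#' drop the corresponding factor from the integral.
#'
#' @param y,X Response and design.
#' @param beta Fixed effects.
#' @param sigma2 Named/ordered numeric vector of variances, one per grouping
#'   factor in `groups`.
#' @param groups Named list of grouping factors (0-2).
#' @return Scalar log-likelihood.
#' @export
laplace_loglik <- function(y, X, beta, sigma2, groups) {
  X <- as.matrix(X)
  keep <- sigma2 > 0
  groups <- groups[keep]
  sigma2 <- sigma2[keep]
  eta0 <- drop(X %*% beta)
  if (length(groups) == 0) return(bernoulli_loglik(y, eta0))
  Zs <- lapply(groups, function(g) stats::model.matrix(~ factor(g) - 1))
  Z <- do.call(cbind, Zs)
  qdim <- ncol(Z)
  prec <- unlist(mapply(function(Zi, s2) rep(1 / s2, ncol(Zi)), Zs, sigma2,
                        SIMPLIFY = FALSE))
  b <- rep(0, qdim)
  for (it in 1:200) {
    eta <- eta0 + drop(Z %*% b)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Z, y - mu)) - prec * b
    H <- crossprod(Z, Z * (mu * (1 - mu)))
    diag(H) <- diag(H) + prec
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- eta0 + drop(Z %*% b)
  mu <- stats::plogis(eta)
  H <- crossprod(Z, Z * (mu * (1 - mu)))
  diag(H) <- diag(H) + prec
  bernoulli_loglik(y, eta) - 0.5 * sum(prec * b^2) +
    0.5 * sum(log(prec)) - 0.5 * as.numeric(determinant(H)$modulus)
}

#' Exact marginal log-likelihood by dense Gauss-Hermite quadrature
#'
#' Test oracle for small crossed-random-intercept Bernoulli models. The
#' integral over the factor with fewer levels is evaluated on a dense product
#' grid (one quadrature dimension per level); conditional on those values the
#' observations of different levels of the other factor are independent, so
#' its integral factorises into one-dimensional quadratures. Deterministic
#' given the quadrature orders. Only feasible when the smaller factor has few
#' levels (the product grid grows as `nodes^levels`).
#'
#' @inheritParams laplace_loglik
#' @param nodes Quadrature order for the factorised (inner) dimensions,
#'   default 25.
#' @param outer_nodes Order per dimension of the product grid; by default the
#'   largest order (capped at `nodes`, floor 7) keeping the grid below 2e5
#'   points.
#' @return Scalar log-likelihood.
#' @export
loglik_oracle <- function(y, X, beta, sigma2, groups, nodes = 25, outer_nodes = NULL) {
  X <- as.matrix(X)
  eta0 <- drop(X %*% beta)
  stopifnot(length(sigma2) == length(groups))
  keep <- sigma2 > 0
  groups <- lapply(groups[keep], function(g) droplevels(as.factor(g)))
  sigma2 <- sigma2[keep]
  if (length(groups) == 0) return(bernoulli_loglik(y, eta0))

  gh <- pracma::gaussHermite(nodes)
  if (length(groups) == 1) {
    g <- groups[[1]]
    u <- sqrt(2 * sigma2[1]) * gh$x
    w <- gh$w / sqrt(pi)
    sgn <- ifelse(y == 1, 1, -1)
    acc <- matrix(0, nlevels(g), 1)
    for (q in seq_len(nodes)) {
      lp <- stats::plogis(sgn * (eta0 + u[q]), log.p = TRUE)
      acc <- acc + w[q] * exp(rowsum(lp, g))
    }
    return(sum(log(acc)))
  }

  sizes <- vapply(groups, nlevels, integer(1))
  o <- which.min(sizes)              # outer: dense product grid
  g_out <- groups[[o]]; g_in <- groups[[-o]]
  s2_out <- sigma2[o]; s2_in <- sigma2[-o]
  m_out <- nlevels(g_out)
  if (m_out > 6) stop("dimension too large for dense quadrature (", m_out, " levels)")
  if (is.null(outer_nodes)) {
    outer_nodes <- min(nodes, max(7, floor(2e5^(1 / m_out))))
  }
  gh_o <- pracma::gaussHermite(outer_nodes)
  v_out <- sqrt(2 * s2_out) * gh_o$x
  w_out <- gh_o$w / sqrt(pi)
  u_in <- sqrt(2 * s2_in) * gh$x
  w_in <- gh$w / sqrt(pi)

  idx <- as.matrix(expand.grid(rep(list(seq_len(outer_nodes)), m_out)))
  V <- matrix(v_out[idx], nrow = nrow(idx))          # grid point x level
  logW <- rowSums(matrix(log(w_out[idx]), nrow = nrow(idx)))
  Eta <- eta0 + t(V)[as.integer(g_out), , drop = FALSE]  # obs x grid point
  sgn <- ifelse(y == 1, 1, -1)
  acc <- matrix(0, nlevels(g_in), ncol(Eta))
  for (q in seq_len(nodes)) {
    lp <- stats::plogis(sgn * (Eta + u_in[q]), log.p = TRUE)
    acc <- acc + w_in[q] * exp(rowsum(lp, g_in))
  }
  ll <- colSums(log(acc)) + logW
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}
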