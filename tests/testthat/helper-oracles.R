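# Independent oracles used to cross-check the package implementation.
# Everything here is deliberately written from first principles and shares
# no code with the package internals.

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via the
# Golub-Welsch eigen decomposition of the Jacobi matrix.
gh_rule <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact (to quadrature accuracy) marginal log-likelihood of a binomial logit
# random-intercept model, by adaptive Gauss-Hermite quadrature: the rule is
# recentred/rescaled at the conditional mode of each cluster.
agq_loglik <- function(beta, sigma, y, X, cluster, nodes = 51) {
  rule <- gh_rule(nodes)
  eta_fix <- as.numeric(X %*% beta)
  total <- 0
  for (g in unique(cluster)) {
    idx <- cluster == g
    yg <- y[idx]; eg <- eta_fix[idx]
    h <- function(d) {
      eta <- eg + d
      sum(yg * eta - log1p(exp(eta))) + stats::dnorm(d, 0, sigma, log = TRUE)
    }
    opt <- stats::optimize(function(d) -h(d), interval = c(-10 * sigma - 5, 10 * sigma + 5))
    m <- opt$minimum
    # curvature of -h at the mode
    p <- stats::plogis(eg + m)
    hess <- sum(p * (1 - p)) + 1 / sigma^2
    s <- 1 / sqrt(hess)
    z <- m + sqrt(2) * s * rule$nodes
    lg <- vapply(z, h, numeric(1)) + rule$nodes^2 + log(rule$weights) +
      log(sqrt(2) * s)
    mx <- max(lg)
    total <- total + mx + log(sum(exp(lg - mx)))
  }
  total
}

# Maximized AGQ log-likelihood over (beta, log sigma).
agq_max_loglik <- function(y, X, cluster, nodes = 51,
                           start_beta = NULL, start_logsigma = log(0.5)) {
  if (is.null(start_beta)) {
    start_beta <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
  }
  par0 <- c(start_beta, start_logsigma)
  fn <- function(par) {
    k <- length(par)
    -agq_loglik(par[-k], exp(par[k]), y, X, cluster, nodes = nodes)
  }
  opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(loglik = -opt$value,
       beta = opt$par[-length(opt$par)],
       sigma = exp(opt$par[length(opt$par)]))
}

# Lin's concordance via an algebraically different route: Pearson correlation
# times the bias-correction factor C_b = 2 / (v + 1/v + u^2) with
# v = sd(x)/sd(y), u = (mean(x) - mean(y)) / sqrt(sd(x) sd(y)), population sds.
ccc_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt(stats::var(x) * (n - 1) / n)
  sy <- sqrt(stats::var(y) * (n - 1) / n)
  v <- sx / sy
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  stats::cor(x, y) * 2 / (v + 1 / v + u^2)
}

# Brute-force neighbor means over an adjacency list.
neighbor_mean_oracle <- function(graph, values) {
  out <- numeric(length(graph$areas))
  names(out) <- graph$areas
  for (a in graph$areas) {
    nb <- graph$neighbors[[a]]
    if (length(nb) == 0) { out[a] <- 0; next }
    v <- ifelse(nb %in% names(values), values[nb], 0)
    out[a] <- sum(v) / length(nb)
  }
  out
}
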