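# Gauss-Hermite nodes/weights by Golub-Welsch (weight function exp(-x^2)):
# eigen-decomposition of the Jacobi matrix; weights from the first
# eigenvector components.
gh_nodes <- function(order) {
  if (order == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(order - 1)
  J <- matrix(0, order, order)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Approximate marginal log-likelihood of the random-intercept model
#'
#' Evaluates, at given parameter values, the marginal likelihood
#' `prod_j integral prod_i Bernoulli(y_ij; invlogit(alpha + x_ij'beta + g))
#' N(g; 0, sigma^2) dg` by adaptive Gauss-Hermite quadrature: each
#' cluster's integrand is re-centered at its posterior mode and re-scaled
#' by the local curvature before applying the quadrature rule, so moderate
#' orders are already near-exact.
#'
#' @param alpha fixed intercept (log-odds).
#' @param beta named fixed-effect vector (may be empty for an
#'   intercept-only model).
#' @param sigma random-intercept SD (>= 0; 0 collapses to plain logistic).
#' @param X design matrix (ignored when `beta` is empty).
#' @param y 0/1 outcome vector.
#' @param cluster cluster ids.
#' @param order quadrature order (default 50).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(alpha, beta, sigma, X, y, cluster, order = 50) {
  eta0 <- rep(alpha, length(y)) +
    (if (length(beta)) as.numeric(X %*% beta) else 0)
  if (sigma == 0)
    return(sum(stats::dbinom(y, 1, invlogit(eta0), log = TRUE)))
  gh <- gh_nodes(order)
  idx <- split(seq_along(y), cluster)
  total <- 0
  for (ix in idx) {
    yi <- y[ix]; ei <- eta0[ix]
    h <- function(g)
      sum(stats::dbinom(yi, 1, invlogit(ei + g), log = TRUE)) +
        stats::dnorm(g, 0, sigma, log = TRUE)
    opt <- stats::optimize(h, interval = c(-10 * sigma, 10 * sigma),
                           maximum = TRUE, tol = 1e-10)
    m <- opt$maximum
    p <- invlogit(ei + m)
    curv <- sum(p * (1 - p)) + 1 / sigma^2  # -h''(m)
    s <- 1 / sqrt(curv)
    g_nodes <- m + sqrt(2) * s * gh$x
    hvals <- vapply(g_nodes, h, numeric(1))
    logint <- log(sqrt(2) * s) +
      log(sum(gh$w * exp(gh$x^2 + hvals - opt$objective))) + opt$objective
    total <- total + logint
  }
  total
}
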