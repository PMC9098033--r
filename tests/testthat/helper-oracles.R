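# Independent oracles, kept deliberately naive: explicit covariance
# matrices, solve()/determinant() instead of any closed form used by the
# package, and a generic optimizer for ML fits.

# brute-force multivariate normal log-density with explicit V
mvn_loglik_oracle <- function(y, mu, V) {
  r <- y - mu
  -0.5 * (length(y) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(V, r)))
}

# per-subject log-density under one component, brute force
subject_loglik_oracle <- function(data, i, beta, d, sigma2) {
  rows <- data$id == i
  ni <- sum(rows)
  V <- sigma2 * (d * matrix(1, ni, ni) + diag(ni))
  mvn_loglik_oracle(data$y[rows],
                    drop(data$X[rows, , drop = FALSE] %*% beta), V)
}

# brute-force mixture log-likelihood
mixture_loglik_oracle <- function(data, comps) {
  total <- 0
  for (i in seq_len(data$n)) {
    dens <- sum(vapply(comps, function(cp) {
      cp$pi * exp(subject_loglik_oracle(data, i, cp$beta, cp$d, cp$sigma2))
    }, numeric(1)))
    total <- total + log(dens)
  }
  total
}

# generic-optimizer ML fit of the single-component random-intercept LMM
# (exact marginal likelihood, log-parameterized variances, BFGS)
ml_lmm_oracle <- function(data, reltol = 1e-12) {
  p <- data$p
  rows_of <- split(seq_len(data$N), data$id)
  negll <- function(par) {
    beta <- par[seq_len(p)]
    d <- exp(par[p + 1L])
    s2 <- exp(par[p + 2L])
    -sum(vapply(rows_of, function(rows) {
      ni <- length(rows)
      V <- s2 * (d * matrix(1, ni, ni) + diag(ni))
      mvn_loglik_oracle(data$y[rows],
                        drop(data$X[rows, , drop = FALSE] %*% beta), V)
    }, numeric(1)))
  }
  start <- c(unname(stats::coef(stats::lm(data$y ~ data$X - 1))), log(0.5),
             log(stats::var(data$y)))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = reltol))
  list(beta = opt$par[seq_len(p)], d = exp(opt$par[p + 1L]),
       sigma2 = exp(opt$par[p + 2L]), loglik = -opt$value)
}

# small single-cluster spec used by several oracle comparisons
small_single_spec <- function(n = 100) {
  B <- matrix(c(10, -2, 1.5, 0, -0.8), ncol = 1,
              dimnames = list(c("(Intercept)", "wave", "x1", "x2", "x3"),
                              NULL))
  cohort_spec(B, pi = 1, d = 0.7, sigma2 = 4, n_subjects = n,
              retention = c(1, 0.9, 0.8))
}

# tight control for oracle-equivalence fits
tight_control <- function(...) {
  lmmclust_control(tol = 1e-10, inner_tol = 1e-11, cd_tol = 1e-11,
                   block_max = 100L, n_starts = 1L, ...)
}

# map fitted cluster indices to true ones by maximal overlap
cluster_map <- function(labels, truth, G) {
  vapply(seq_len(G), function(g) {
    tt <- table(factor(truth[labels == g], seq_len(G)))
    as.integer(which.max(tt))
  }, integer(1))
}

# per-cluster support errors (false inclusions + exclusions) of a fitted
# model against a generating spec, over penalized coordinates
support_errors <- function(fit, spec, truth) {
  map <- cluster_map(fit$labels, truth, fit$G)
  pen <- fit$penalized
  B <- coef(fit, scale = "standardized")
  vapply(seq_len(fit$G), function(g) {
    est <- names(which(B[, g] != 0 & pen))
    tru <- intersect(rownames(spec$beta)[spec$beta[, map[g]] != 0],
                     names(which(pen)))
    length(setdiff(est, tru)) + length(setdiff(tru, est))
  }, numeric(1))
}
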