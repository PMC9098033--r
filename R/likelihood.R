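#' Marginal covariance of a subject's outcome vector
#'
#' For the random-effects model `y_i = X_i b + Z_i b_i + e_i` with
#' `b_i ~ N(0, sigma2 * D)` and `e_i ~ N(0, sigma2 * I)`, the marginal
#' covariance of `y_i` is `sigma2 * (Z_i D Z_i' + I)`. `D` is the
#' *relative* random-effect covariance (scaled by the residual variance),
#' following the usual mixed-model parameterization.
#'
#' @param Z random-effects design, an `n_i x q` matrix (a vector is treated
#'   as a single column).
#' @param D `q x q` relative covariance matrix (scalar allowed when q = 1),
#'   symmetric positive semidefinite.
#' @param sigma2 residual variance, positive scalar.
#' @return The `n_i x n_i` marginal covariance matrix.
#' @export
marginal_covariance <- function(Z, D, sigma2) {
  Z <- as.matrix(Z)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("D must be symmetric", call. = FALSE)
  }
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("D must be positive semidefinite", call. = FALSE)
  }
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be positive", call. = FALSE)
  }
  sigma2 * (Z %*% D %*% t(Z) + diag(nrow(Z)))
}

#' Log-density of one subject under one mixture component
#'
#' Evaluates the exact multivariate normal log-density of a subject's
#' outcome vector under a component's linear mixed model:
#' `y_i ~ N(X_i beta, sigma2 (Z_i D Z_i' + I))`.
#'
#' @param y outcome vector of length `n_i`.
#' @param X fixed-effects design, `n_i x p`.
#' @param Z random-effects design, `n_i x q`.
#' @param theta component parameters: a list with `beta` (length p), `d`
#'   (scalar relative random-intercept variance) or `D` (q x q matrix), and
#'   `sigma2`.
#' @return The log-density, a scalar.
#' @export
subject_loglik <- function(y, X, Z, theta) {
  X <- as.matrix(X)
  D <- if (!is.null(theta$D)) theta$D else theta$d
  V <- marginal_covariance(Z, D, theta$sigma2)
  r <- y - drop(X %*% theta$beta)
  ch <- tryCatch(chol(V), error = function(e) {
    stop("singular marginal covariance (sigma2 = ", theta$sigma2,
         ", D = ", paste(D, collapse = ","), ")", call. = FALSE)
  })
  u <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

# n x G matrix of per-subject log-densities under each component, using the
# closed form for the random-intercept model: with J the all-ones matrix,
# (dJ + I)^{-1} = I - d/(1 + n_i d) J and det = 1 + n_i d, so
#   ll_i = -1/2 [ n_i log(2 pi s2) + log(1 + n_i d) + (rss_i - c_i srs_i^2)/s2 ]
# where rss_i = r_i'r_i, srs_i = sum(r_i), c_i = d/(1 + n_i d).
loglik_matrix <- function(data, components) {
  n <- data$n
  G <- length(components)
  out <- matrix(NA_real_, n, G)
  n_i <- data$n_i
  for (g in seq_len(G)) {
    th <- components[[g]]
    r <- data$y - drop(data$X %*% th$beta)
    rss <- rowsum_vec(r * r, data$id, n)
    srs <- rowsum_vec(r, data$id, n)
    cc <- th$d / (1 + n_i * th$d)
    out[, g] <- -0.5 * (n_i * log(2 * pi * th$sigma2) + log1p(n_i * th$d) +
                          (rss - cc * srs^2) / th$sigma2)
  }
  out
}

# fast grouped sum returning a plain vector of length n
rowsum_vec <- function(x, id, n) {
  out <- numeric(n)
  rs <- rowsum(x, id, reorder = FALSE)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Observed-data log-likelihood of a fitted mixture
#'
#' Computes `sum_i log sum_g pi_g phi_g(y_i)` on the log scale via
#' log-sum-exp, so components with very small density never underflow to a
#' domain error.
#'
#' @param data a [long_data] object.
#' @param model a fitted [lmmclust] model (or any list with `components`,
#'   each holding `beta`, `d`, `sigma2`, `pi`).
#' @return The unpenalized mixture log-likelihood, a scalar.
#' @export
mixture_loglik <- function(data, model) {
  ll <- loglik_matrix(data, model$components)
  lpi <- log(vapply(model$components, `[[`, numeric(1), "pi"))
  sum(logsumexp_rows(sweep(ll, 2, lpi, "+")))
}

# row-wise log(sum(exp(x))) tolerating -Inf entries
logsumexp_rows <- function(lw) {
  m <- apply(lw, 1, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(lw - m)))
}

#' E-step: posterior responsibilities and mixing-probability update
#'
#' Computes `w_ig = pi_g phi_g(y_i) / sum_l pi_l phi_l(y_i)` stably in log
#' space, then updates the mixing probabilities as the responsibility column
#' means, `pi_g = sum_i w_ig / n`. A component with `pi_g = 0` receives zero
#' responsibility for every subject.
#'
#' @inheritParams mixture_loglik
#' @return A list with `W` (`n x G` responsibility matrix, rows summing to
#'   1), `pi` (updated mixing probabilities), and `loglik` (the observed-data
#'   log-likelihood at the *input* parameters).
#' @export
e_step <- function(data, model) {
  ll <- loglik_matrix(data, model$components)
  lpi <- log(vapply(model$components, `[[`, numeric(1), "pi"))
  lw <- sweep(ll, 2, lpi, "+")
  norm <- logsumexp_rows(lw)
  W <- exp(lw - norm)
  W[, !is.finite(lpi)] <- 0
  W <- W / rowSums(W)
  list(W = W, pi = colMeans(W), loglik = sum(norm))
}

#' Soft-thresholding operator
#'
#' The scalar LASSO solution operator `S(z, lam) = sign(z) max(|z| - lam, 0)`
#' used by the coordinate-descent M-step.
#'
#' @param z numeric vector.
#' @param lam nonnegative threshold.
#' @return `sign(z) * pmax(|z| - lam, 0)`.
#' @export
soft_threshold <- function(z, lam) {
  stopifnot(lam >= 0)
  sign(z) * pmax(abs(z) - lam, 0)
}
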