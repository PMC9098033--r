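test_that("marginal covariance has the sigma2 (Z D Z' + I) form", {
  V <- marginal_covariance(matrix(1, 3, 1), 1, 1)
  expect_equal(V, matrix(1, 3, 3) + diag(3))

  # zero random-effect variance gives sigma2 * I
  expect_equal(marginal_covariance(matrix(rnorm(6), 3, 2), diag(0, 2), 2.5),
               2.5 * diag(3))

  # scalar case: 2 * (0.5 + 1) = 3
  expect_equal(drop(marginal_covariance(matrix(1, 1, 1), 0.5, 2)), 3)

  expect_error(marginal_covariance(matrix(1, 2, 1), -1, 1), "semidefinite")
  expect_error(marginal_covariance(matrix(1, 2, 1), 1, 0), "positive")
})

test_that("subject log-density matches the brute-force normal density", {
  # perfect fit, d = 0, sigma2 = 1: only the normalizing constant remains
  y <- c(3, 5)
  X <- cbind(1, c(0, 1))
  th <- list(beta = c(3, 2), d = 0, sigma2 = 1)
  expect_equal(subject_loglik(y, X, matrix(1, 2, 1), th), -log(2 * pi))

  # fixed numeric case against explicit inverse and determinant
  set.seed(42)
  y <- c(1.2, -0.7, 2.4)
  X <- cbind(1, 0:2, rnorm(3))
  th <- list(beta = c(0.5, 0.3, -1), d = 0.5, sigma2 = 2)
  V <- 2 * (0.5 * matrix(1, 3, 3) + diag(3))
  expect_equal(subject_loglik(y, X, matrix(1, 3, 1), th),
               mvn_loglik_oracle(y, drop(X %*% th$beta), V),
               tolerance = 1e-12)

  # exchangeable covariance: permuting time points leaves it unchanged
  pp <- c(3, 1, 2)
  expect_equal(subject_loglik(y[pp], X[pp, ], matrix(1, 3, 1), th),
               subject_loglik(y, X, matrix(1, 3, 1), th), tolerance = 1e-12)
})

test_that("the vectorized per-component densities agree with the generic form", {
  co <- simulate_cohort(taag_spec(n_subjects = 20), seed = 9)
  dat <- co$data
  th <- list(beta = rnorm(dat$p, sd = 0.1), d = 0.3, sigma2 = 25, pi = 1)
  ll <- lmmclust:::loglik_matrix(dat, list(th))
  for (i in c(1, 7, 20)) {
    rows <- dat$id == i
    expect_equal(ll[i, 1],
                 subject_loglik(dat$y[rows], dat$X[rows, , drop = FALSE],
                                matrix(1, sum(rows), 1), th),
                 tolerance = 1e-10)
  }
})

test_that("mixture log-likelihood reduces, adds, and matches the oracle", {
  co <- simulate_cohort(taag_spec(n_subjects = 15), seed = 2)
  dat <- co$data
  mk <- function(b0, slope, d, s2, pi) {
    beta <- numeric(dat$p)
    beta[1] <- b0; beta[2] <- slope
    list(beta = beta, d = d, sigma2 = s2, pi = pi)
  }
  comps <- list(mk(15, -1, 0.5, 36, 0.6), mk(2, 29, 0.5, 100, 0.4))
  model <- list(components = comps)

  expect_equal(mixture_loglik(dat, model),
               mixture_loglik_oracle(dat, comps), tolerance = 1e-10)

  # G = 1 reduces to the sum of subject log-densities
  one <- list(components = list(mk(15, -1, 0.5, 36, 1)))
  expect_equal(mixture_loglik(dat, one),
               sum(lmmclust:::loglik_matrix(dat, one$components)),
               tolerance = 1e-12)

  # label permutation leaves the mixture unchanged
  expect_equal(mixture_loglik(dat, list(components = rev(comps))),
               mixture_loglik(dat, model), tolerance = 1e-12)

  # duplicating every subject doubles the value
  df <- data.frame(id = c(dat$id, dat$id + dat$n),
                   wave = c(dat$wave, dat$wave), y = c(dat$y, dat$y),
                   rbind(dat$X[, -(1:2)], dat$X[, -(1:2)]),
                   check.names = FALSE)
  expect_equal(mixture_loglik(long_data(df), model),
               2 * mixture_loglik(dat, model), tolerance = 1e-10)
})

test_that("E-step responsibilities follow Bayes rule and update pi", {
  co <- simulate_cohort(taag_spec(n_subjects = 12), seed = 6)
  dat <- co$data
  beta <- numeric(dat$p); beta[1] <- 15
  th1 <- list(beta = beta, d = 0.5, sigma2 = 36, pi = 0.5)

  # identical components with equal priors: every responsibility is 1/2
  es <- e_step(dat, list(components = list(th1, th1)))
  expect_equal(es$W, matrix(0.5, dat$n, 2), tolerance = 1e-12)
  expect_equal(es$pi, c(0.5, 0.5))

  # degenerate prior: all mass on component 1, no division error
  th2 <- th1; th2$pi <- 0
  th1b <- th1; th1b$pi <- 1
  es <- e_step(dat, list(components = list(th1b, th2)))
  expect_equal(es$W[, 1], rep(1, dat$n))
  expect_equal(es$W[, 2], rep(0, dat$n))

  # direct Bayes-rule arithmetic on a 2-subject toy
  toy <- long_data(data.frame(id = c(1, 1, 2, 2), wave = c(0, 1, 0, 1),
                              y = c(0, 0, 10, 10), x = c(1, -1, 0.5, 2)))
  a <- list(beta = c(0, 0, 0), d = 0, sigma2 = 1, pi = 0.3)
  b <- list(beta = c(10, 0, 0), d = 0, sigma2 = 1, pi = 0.7)
  es <- e_step(toy, list(components = list(a, b)))
  l1 <- exp(sapply(1:2, function(i) subject_loglik_oracle(toy, i, a$beta, 0, 1)))
  l2 <- exp(sapply(1:2, function(i) subject_loglik_oracle(toy, i, b$beta, 0, 1)))
  expect_equal(es$W[, 1], 0.3 * l1 / (0.3 * l1 + 0.7 * l2), tolerance = 1e-12)
  expect_equal(rowSums(es$W), c(1, 1), tolerance = 1e-12)

  # extreme separation must not underflow to NaN
  far <- list(beta = c(1e4, 0, 0), d = 0, sigma2 = 1, pi = 0.5)
  es <- e_step(toy, list(components = list(a, far)))
  expect_true(all(is.finite(es$W)))
})

test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.5, 1), 0)
  z <- seq(-4, 4, by = 0.5)
  expect_equal(soft_threshold(z, 1.2), sign(z) * pmax(abs(z) - 1.2, 0))
  expect_error(soft_threshold(1, -0.1))
})
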