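test_that("BIC follows -2 loglik + df log N with the stated df accounting", {
  # constructed model with known ingredients
  beta1 <- c("(Intercept)" = 1, wave = 2, x = 0)
  beta2 <- c("(Intercept)" = 1, wave = 0, x = 3)
  fake <- structure(list(
    G = 2L,
    components = list(list(beta = beta1, d = 0.1, sigma2 = 1, pi = 0.5),
                      list(beta = beta2, d = 0.1, sigma2 = 1, pi = 0.5)),
    loglik = -100,
    data = list(N = 100L, n = 40L)
  ), class = "lmmclust")
  # df = 4 nonzero coefficients + 2G variance parameters + (G - 1) mixing
  expect_equal(lmmclust:::model_df(fake), 4 + 4 + 1)
  expect_equal(model_bic(fake), 200 + 9 * log(100))
  expect_equal(model_bic(fake, count = "subjects"), 200 + 9 * log(40))

  # one more nonzero coefficient at unchanged loglik adds exactly log(N)
  fake2 <- fake
  fake2$components[[1]]$beta[["x"]] <- 0.5
  expect_equal(model_bic(fake2) - model_bic(fake), log(100))
})

test_that("logLik carries the df and nobs that stats::BIC needs", {
  co <- simulate_cohort(taag_spec(n_subjects = 50), seed = 41)
  dat <- standardize_covariates(co$data)
  fit <- lmmclust(dat, 2, 5, lmmclust_control(n_starts = 1, seed = 41))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), lmmclust:::model_df(fit))
  expect_equal(stats::BIC(fit), model_bic(fit))
  expect_equal(nobs(fit), dat$N)
})

test_that("a degenerate single-point grid returns the plain ML fit", {
  co <- simulate_cohort(small_single_spec(60), seed = 43)
  sr <- lmmclust_search(co$data, G = 1, lambda = 0,
                        control = tight_control(seed = 43))
  expect_equal(sr$best$G, 1L)
  oracle <- ml_lmm_oracle(co$data)
  expect_equal(unname(sr$best$components[[1]]$beta), oracle$beta,
               tolerance = 1e-4)
  expect_equal(nrow(sr$grid), 1L)
})

test_that("the search records every fit, and the winner attains the minimal BIC", {
  co <- simulate_cohort(inflate_separation(taag_spec(n_subjects = 150)),
                        seed = 47)
  dat <- standardize_covariates(co$data)
  sr <- lmmclust_search(dat, G = 2:3, nlambda = 3,
                        control = lmmclust_control(n_starts = 1, seed = 47,
                                                   max_iter = 100L))
  ok <- is.na(sr$grid$error)
  expect_equal(sum(ok), 2 * 4)  # nlambda + the unpenalized endpoint, per G
  expect_equal(model_bic(sr$best, sr$count), min(sr$grid$bic[ok]))
  # the largest path lambda leaves every penalized coefficient at zero
  for (g in 2:3) {
    top <- sr$grid[sr$grid$G == g, ][1, ]
    expect_equal(top$n_nonzero, 0)
  }
  # per-G winners agree with the grid
  for (g in 2:3) {
    expect_equal(model_bic(sr$best_per_G[[paste0("G", g)]], sr$count),
                 min(sr$grid$bic[ok & sr$grid$G == g]))
  }
  expect_error(lmmclust_search(dat, G = integer(0)), "empty")
})

test_that("BIC prefers a sparser model than the unpenalized fit when truth is sparse", {
  co <- simulate_cohort(inflate_separation(taag_spec(n_subjects = 200)),
                        seed = 53)
  dat <- standardize_covariates(co$data)
  sr <- lmmclust_search(dat, G = 3, nlambda = 5,
                        control = lmmclust_control(n_starts = 1, seed = 53))
  g <- sr$grid[is.na(sr$grid$error), ]
  nz_best <- g$n_nonzero[which.min(g$bic)]
  nz_unpen <- g$n_nonzero[g$lambda1 == 0]
  expect_lt(nz_best, nz_unpen)
})

test_that("unpenalized refits on a hard partition reproduce the M-step and the oracle", {
  co <- simulate_cohort(small_single_spec(80), seed = 59)
  dat <- co$data
  labels <- rep(1L, dat$n)

  # all covariates selected: same objective as the single-cluster ML fit
  rf <- refit_clusters(dat, labels, list(c("wave", "x1", "x2", "x3")))
  fit <- lmmclust(dat, 1, 0, tight_control())
  expect_equal(rf$clusters[[1]]$coef$estimate,
               unname(fit$components[[1]]$beta), tolerance = 1e-6)

  # intercept-only refit equals the generic-optimizer oracle on that design
  rf0 <- refit_clusters(dat, labels, list(character(0)))
  sub <- lmmclust:::subset_subjects(dat, seq_len(dat$n), columns = character(0))
  oracle <- ml_lmm_oracle(sub)
  expect_equal(rf0$clusters[[1]]$coef$estimate, oracle$beta, tolerance = 1e-4)

  # Wald table is well-formed
  expect_true(all(rf$clusters[[1]]$coef$se > 0))
  expect_true(all(rf$clusters[[1]]$coef$p >= 0 & rf$clusters[[1]]$coef$p <= 1))

  # a cluster smaller than its selected-variable count + 3 is ill-posed
  expect_error(refit_clusters(dat, c(2L, rep(1L, dat$n - 1L)),
                              list(c("wave", "x1"), c("wave", "x1", "x2", "x3"))),
               "ill-posed")
  expect_error(refit_clusters(dat, labels, list("nope")), "unknown")
})

test_that("a forcibly included null covariate is usually insignificant in the refit", {
  hits <- 0L
  reps <- 20L
  for (s in seq_len(reps)) {
    co <- simulate_cohort(small_single_spec(200), seed = 600 + s)
    rf <- refit_clusters(co$data, rep(1L, co$data$n),
                         list(c("wave", "x1", "x2", "x3")))
    z <- rf$clusters[[1]]$coef["x2", "z"]  # true coefficient is zero
    if (abs(z) < 1.96) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * reps)
})
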