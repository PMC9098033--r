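test_that("cluster summaries report sizes, proportions and wave statistics", {
  co <- simulate_cohort(taag_spec(n_subjects = 40), seed = 61)
  dat <- co$data
  cs <- summarize_clusters(dat, co$truth$cluster)
  sizes <- attr(cs, "sizes")
  expect_equal(sum(sizes), dat$n)
  expect_equal(sum(attr(cs, "proportions")), 1)
  # recompute one cell by hand
  g <- co$truth$cluster[dat$id]
  sel <- g == 1 & dat$wave == 0
  expect_equal(cs$mean[cs$cluster == 1 & cs$wave == 0], mean(dat$y[sel]))
  expect_equal(cs$sd[cs$cluster == 1 & cs$wave == 0], sd(dat$y[sel]))

  # constant outcome: every mean c, every sd 0
  dat2 <- dat; dat2$y <- rep(7, dat$N)
  cs2 <- summarize_clusters(dat2, co$truth$cluster)
  expect_true(all(cs2$mean[cs2$n > 0] == 7))
  expect_true(all(cs2$sd[cs2$n > 1] == 0))

  # single-cluster labels
  cs3 <- summarize_clusters(dat, rep(1L, dat$n))
  expect_equal(attr(cs3, "sizes"), dat$n)
  expect_equal(attr(cs3, "proportions"), 1)
  expect_error(summarize_clusters(dat, 1:3), "one entry per subject")
})

test_that("simulated cluster wave-means track the generative linear predictors", {
  sp <- taag_spec(n_subjects = 2000)
  co <- simulate_cohort(sp, seed = 67)
  cs <- summarize_clusters(co$data, co$truth$cluster)
  for (g in 1:3) {
    for (w in 0:2) {
      row <- cs[cs$cluster == g & cs$wave == w, ]
      pred <- sp$beta["(Intercept)", g] + sp$beta["wave", g] * w
      se <- row$sd / sqrt(row$n)
      expect_lt(abs(row$mean - pred), 2.5 * se + 0.5)
    }
  }
})

test_that("the selection table shows the support and back-transforms coefficients", {
  co <- simulate_cohort(inflate_separation(taag_spec(n_subjects = 150)),
                        seed = 71)
  dat <- standardize_covariates(co$data)
  ctrl <- lmmclust_control(n_starts = 1, seed = 71)
  fit <- lmmclust(dat, 3, 6, ctrl)
  tab <- selection_table(fit)
  expect_true("(Intercept)" %in% rownames(tab))
  expect_equal(ncol(tab), 3)
  # nonzero pattern equals the model's support on the shown rows
  B <- coef(fit, scale = "standardized")
  for (g in 1:3) {
    shown <- rownames(tab)[!is.na(tab[, g])]
    expect_setequal(shown, names(which(B[, g] != 0)))
  }

  # all-penalized-zero fit: only intercept (and unpenalized rows) remain
  lmx <- lambda_max(dat, 2, ctrl)
  fit0 <- lmmclust(dat, 2, lmx, ctrl)
  tab0 <- selection_table(fit0)
  expect_setequal(rownames(tab0), "(Intercept)")

  # single-component model gives a single column
  fit1 <- lmmclust(dat, 1, 0, lmmclust_control(n_starts = 1))
  expect_equal(ncol(selection_table(fit1)), 1)
})

test_that("back-transformed unpenalized coefficients match a fit on raw covariates", {
  co <- simulate_cohort(small_single_spec(80), seed = 73)
  raw <- co$data
  std <- standardize_covariates(raw)
  ctrl <- tight_control()
  fit_std <- lmmclust(std, 1, 0, ctrl)
  fit_raw <- lmmclust(raw, 1, 0, ctrl)
  expect_equal(coef(fit_std, scale = "original"),
               coef(fit_raw, scale = "original"), tolerance = 1e-5)
})

test_that("cross tabulation matches the reference three-cluster comparison", {
  # counts arranged as the published cross-clustering comparison
  M <- matrix(c(176, 94, 4,
                20, 103, 0,
                5, 4, 22), 3, 3, byrow = TRUE)
  a <- rep(1:3, times = rowSums(M))
  b <- unlist(lapply(1:3, function(r) rep(1:3, times = M[r, ])))
  tab <- cross_tabulate(a, b)
  expect_equal(unname(diag(tab[1:3, 1:3])), c(176, 103, 22))
  expect_equal(unname(tab["Total", "Total"]), 428)
  expect_equal(unname(tab[1:3, "Total"]), rowSums(M))
  expect_equal(unname(tab["Total", 1:3]), colSums(M))
  expect_error(cross_tabulate(1:3, 1:4), "equal length")

  # identical labelings give a diagonal table
  tt <- cross_tabulate(b, b)
  off <- tt[1:3, 1:3]; diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("adjusted Rand index has its defining properties", {
  set.seed(79)
  a <- sample(1:3, 300, replace = TRUE)
  expect_equal(adjusted_rand_index(a, a), 1)
  # relabeling invariance
  expect_equal(adjusted_rand_index(a, c(3, 1, 2)[a]), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  # independent labelings concentrate near zero
  m <- mean(replicate(20, {
    adjusted_rand_index(sample(1:3, 1000, TRUE), sample(1:4, 1000, TRUE))
  }))
  expect_lt(abs(m), 0.05)

  # agreement with the established implementation on shuffled partitions
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    set.seed(s)
    x <- sample(1:4, 200, replace = TRUE)
    y <- x; flip <- sample(200, 50); y[flip] <- sample(1:4, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("label alignment finds the permutation maximizing overlap", {
  set.seed(83)
  ref <- sample(1:3, 120, replace = TRUE)
  shuffled <- c(2, 3, 1)[ref]
  expect_equal(align_labels(shuffled, ref), ref)
  noisy <- shuffled
  noisy[1:10] <- sample(1:3, 10, replace = TRUE)
  al <- align_labels(noisy, ref)
  expect_gte(mean(al == ref), 0.9)
  expect_error(align_labels(1:3, 1:4), "equal length")
})

test_that("model methods expose fitted values, residuals, prediction and summaries", {
  co <- simulate_cohort(inflate_separation(taag_spec(n_subjects = 100)),
                        seed = 89)
  dat <- standardize_covariates(co$data)
  fit <- lmmclust(dat, 3, 5, lmmclust_control(n_starts = 1, seed = 89))

  expect_length(fitted(fit), dat$N)
  expect_equal(residuals(fit), dat$y - fitted(fit))
  expect_equal(predict(fit, type = "class"), unname(fit$labels))
  W <- predict(fit, type = "posterior")
  expect_equal(rowSums(W), rep(1, dat$n), tolerance = 1e-12)

  s <- summary(fit)
  expect_s3_class(s, "summary.lmmclust")
  expect_output(print(s), "Cluster")
  expect_output(print(fit), "Mixture of penalized")

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(dat$N, 2))
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(sims, sims2)

  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$G, 3L)
  expect_length(parsed$components, 3)
  unlink(f)

  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
  unlink(pf)
})
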