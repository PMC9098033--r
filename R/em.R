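#' Control parameters for the EM fitter
#'
#' @param max_iter maximum number of EM iterations.
#' @param tol relative improvement in the penalized observed-data objective
#'   below which the alternation stops.
#' @param cd_tol coordinate-descent convergence tolerance (maximum absolute
#'   coefficient change per sweep).
#' @param cd_max_pass maximum coordinate-descent sweeps per inner fit.
#' @param block_max maximum alternations between the coefficient and
#'   variance-parameter blocks within one M-step.
#' @param inner_tol relative tolerance on the within-cluster objective for
#'   the block alternation.
#' @param n_starts number of initializations: one k-means start on
#'   per-subject (mean, slope) features plus `n_starts - 1` random
#'   hard-assignment starts; the best final objective wins.
#' @param max_restarts restarts with fresh random assignments when a
#'   component's effective size falls below `min_size`.
#' @param d_max upper bound for the relative random-intercept variance in
#'   the 1-D variance search.
#' @param sigma2_min floor for the residual variance.
#' @param min_size empty-cluster floor on the effective size
#'   `sum_i w_ig`; default `max(2, 0.005 n)`.
#' @param unpenalized names of design columns exempt from the penalty in
#'   addition to the intercept (which is never penalized).
#' @param lambda2 optional ridge penalty on the relative random-intercept
#'   variance `d_g` (default 0, off).
#' @param scale_by_size if `TRUE`, scale each cluster's penalty by its
#'   effective size (sensitivity analysis; default off, the per-cluster
#'   objective is penalized unscaled).
#' @param seed optional integer; when set, the RNG is seeded on entry so
#'   initializations are reproducible.
#' @param verbose print per-iteration objectives.
#' @return A list of class `lmmclust_control`.
#' @export
lmmclust_control <- function(max_iter = 500L, tol = 1e-6, cd_tol = 1e-8,
                             cd_max_pass = 50L, block_max = 5L,
                             inner_tol = 1e-7, n_starts = 3L,
                             max_restarts = 3L, d_max = 1e3,
                             sigma2_min = 1e-8, min_size = NULL,
                             unpenalized = character(0), lambda2 = 0,
                             scale_by_size = FALSE, seed = NULL,
                             verbose = FALSE) {
  structure(as.list(environment()), class = "lmmclust_control")
}

# per-subject within-subject column sums of X (n x p); reused across M-steps
subject_colsums <- function(data) {
  Tm <- rowsum(data$X, data$id, reorder = TRUE)
  Tm[order(as.integer(rownames(Tm))), , drop = FALSE]
}

# One cluster's penalized M-step: blockwise ascent alternating
#  (a) coordinate descent with soft-thresholding on beta given (d, sigma2),
#  (b) exact profile update of (d, sigma2) given beta (closed-form sigma2
#      profiled out, 1-D bounded search over d, with an ascent guard).
# When freeze is TRUE the penalized coordinates are pinned at zero and the
# largest KKT score |x_j' A r| / sigma2 seen at any sweep is accumulated in
# score_env$max (used to compute the penalty-path endpoint lambda_max).
m_step_cluster <- function(data, w, lambda1, theta, penalized, control, Tm,
                           freeze = FALSE, score_env = NULL) {
  n <- data$n; n_i <- data$n_i
  wr <- w[data$id]
  Nw <- sum(w * n_i)
  beta <- theta$beta; d <- theta$d; sigma2 <- theta$sigma2
  r <- data$y - drop(data$X %*% beta)
  s <- rowsum_vec(r, data$id, n)
  p <- data$p
  Xsq <- data$X * data$X
  Tsq <- Tm * Tm

  cluster_obj <- function(d, sigma2, beta) {
    cc <- d / (1 + n_i * d)
    rss <- rowsum_vec(r * r, data$id, n)
    q <- sum(w * (rss - cc * s^2))
    -0.5 * (Nw * log(2 * pi * sigma2) + sum(w * log1p(n_i * d)) + q / sigma2) -
      lambda1 * sum(abs(beta[penalized])) - control$lambda2 * d
  }

  X <- data$X
  obj_prev <- -Inf
  for (block in seq_len(control$block_max)) {
    ## (a) coordinate descent on beta (active-set sweeps between full sweeps)
    cc <- d / (1 + n_i * d)
    wc <- w * cc
    den <- colSums(Xsq * wr) - colSums(Tsq * wc)
    thr <- lambda1 * sigma2
    cd_pass <- function(idx) {
      delta_max <- 0
      for (j in idx) {
        dj <- den[j]
        if (dj <= .Machine$double.eps) next
        rho <- sum(X[, j] * r * wr) - sum(Tm[, j] * s * wc) + dj * beta[j]
        if (penalized[j]) {
          if (freeze) {
            sc <- abs(rho) / sigma2
            if (!is.null(score_env) && sc > score_env$max) score_env$max <- sc
            next
          }
          a <- abs(rho) - thr
          bnew <- if (a > 0) sign(rho) * a / dj else 0
        } else {
          bnew <- rho / dj
        }
        delta <- bnew - beta[j]
        if (delta != 0) {
          r <<- r - X[, j] * delta
          s <<- s - Tm[, j] * delta
          beta[j] <<- bnew
          if (abs(delta) > delta_max) delta_max <- abs(delta)
        }
      }
      delta_max
    }
    passes <- 0L
    all_idx <- seq_len(p)
    repeat {
      dm_full <- cd_pass(all_idx)
      passes <- passes + 1L
      cd_eps <- control$cd_tol * (1 + max(abs(beta)))
      if (dm_full < cd_eps || passes >= control$cd_max_pass) break
      active <- which(beta != 0 | !penalized)
      repeat {
        dm <- cd_pass(active)
        passes <- passes + 1L
        if (dm < cd_eps || passes >= control$cd_max_pass) break
      }
      if (passes >= control$cd_max_pass) break
    }

    ## (b) variance parameters given beta: profile sigma2, search d
    rss <- rowsum_vec(r * r, data$id, n)
    prof <- function(dd) {
      cc <- dd / (1 + n_i * dd)
      q <- sum(w * (rss - cc * s^2))
      s2 <- max(q / Nw, control$sigma2_min)
      -0.5 * (Nw * log(2 * pi * s2) + sum(w * log1p(n_i * dd)) + q / s2) -
        control$lambda2 * dd
    }
    opt <- stats::optimize(prof, c(0, control$d_max), maximum = TRUE,
                           tol = 1e-9)
    cand_d <- c(opt$maximum, 0, d)
    vals <- vapply(cand_d, prof, numeric(1))
    d <- cand_d[which.max(vals)]
    cc <- d / (1 + n_i * d)
    q <- sum(w * (rss - cc * s^2))
    sigma2 <- max(q / Nw, control$sigma2_min)

    obj <- cluster_obj(d, sigma2, beta)
    if (obj - obj_prev < control$inner_tol * (abs(obj_prev) + 1)) {
      obj_prev <- max(obj, obj_prev)
      break
    }
    obj_prev <- obj
  }
  list(beta = stats::setNames(beta, colnames(data$X)), d = d, sigma2 = sigma2,
       eff_size = sum(w), objective = obj_prev)
}

#' Penalized M-step across all mixture components
#'
#' Given a responsibility matrix, updates each component's fixed-effect
#' coefficients by coordinate descent with soft-thresholding under the
#' responsibility-weighted whitened least-squares objective, and its variance
#' parameters `(d_g, sigma2_g)` by an exact profile update, alternating the
#' two blocks until the within-cluster penalized objective stabilizes. The
#' intercept is never penalized. Mixing probabilities are set to the
#' responsibility column means.
#'
#' @param data a [long_data] object.
#' @param W `n x G` responsibility matrix with rows summing to 1.
#' @param lambda1 nonnegative LASSO penalty on the penalized fixed effects.
#' @param control an [lmmclust_control()] list.
#' @param components optional warm-start component list.
#' @return A list of G components, each with `beta`, `d`, `sigma2`, `pi`,
#'   and the effective cluster size.
#' @export
m_step <- function(data, W, lambda1, control = lmmclust_control(),
                   components = NULL) {
  stopifnot(inherits(data, "long_data"))
  W <- as.matrix(W)
  if (nrow(W) != data$n) stop("W must have one row per subject", call. = FALSE)
  if (max(abs(rowSums(W) - 1)) > 1e-8) {
    stop("responsibility rows must sum to 1", call. = FALSE)
  }
  penalized <- penalized_mask(data, control)
  Tm <- subject_colsums(data)
  G <- ncol(W)
  out <- vector("list", G)
  for (g in seq_len(G)) {
    th <- if (!is.null(components)) components[[g]] else init_theta(data)
    lam_g <- effective_lambda(lambda1, sum(W[, g]), control)
    out[[g]] <- m_step_cluster(data, W[, g], lam_g, th, penalized, control, Tm)
    out[[g]]$pi <- mean(W[, g])
  }
  out
}

penalized_mask <- function(data, control) {
  nm <- colnames(data$X)
  stats::setNames(!(nm %in% c("(Intercept)", control$unpenalized)), nm)
}

effective_lambda <- function(lambda1, eff_size, control) {
  if (isTRUE(control$scale_by_size)) lambda1 * eff_size else lambda1
}

init_theta <- function(data) {
  list(beta = stats::setNames(c(mean(data$y), rep(0, data$p - 1L)),
                              colnames(data$X)),
       d = 0.5, sigma2 = stats::var(data$y))
}

# per-subject (mean outcome, OLS slope over wave) features for k-means init
subject_features <- function(data) {
  ybar <- rowsum_vec(data$y, data$id, data$n) / data$n_i
  wbar <- rowsum_vec(data$wave, data$id, data$n) / data$n_i
  sxy <- rowsum_vec(data$y * data$wave, data$id, data$n) - data$n_i * ybar * wbar
  sxx <- rowsum_vec(data$wave^2, data$id, data$n) - data$n_i * wbar^2
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  cbind(mean = ybar, slope = slope)
}

hard_W <- function(assign, G) {
  W <- matrix(0, length(assign), G)
  W[cbind(seq_along(assign), assign)] <- 1
  W
}

kmeans_start <- function(data, G) {
  f <- scale(subject_features(data))
  f[!is.finite(f)] <- 0
  km <- tryCatch(stats::kmeans(f, centers = G, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km)) return(random_start(data, G))
  hard_W(km$cluster, G)
}

random_start <- function(data, G) {
  for (try in 1:20) {
    a <- sample.int(G, data$n, replace = TRUE)
    if (min(tabulate(a, G)) >= 2L) return(hard_W(a, G))
  }
  hard_W(rep_len(seq_len(G), data$n)[sample.int(data$n)], G)
}

# one EM run from a given responsibility start; returns the best iterate
run_em <- function(data, G, lambda1, control, W0, penalized, Tm,
                   freeze = FALSE, score_env = NULL) {
  floor_size <- if (is.null(control$min_size)) max(2, 0.005 * data$n) else
    control$min_size
  comps <- NULL
  W <- W0
  trace <- numeric(0)
  best <- list(obj = -Inf)
  status <- "max_iter"
  prev <- -Inf
  for (it in seq_len(control$max_iter)) {
    if (it > 1L) {
      es <- e_step(data, list(components = comps))
      W <- es$W
      eff <- colSums(W)
      if (min(eff) < floor_size) { status <- "empty"; break }
    }
    pi <- colMeans(W)
    newcomps <- vector("list", G)
    for (g in seq_len(G)) {
      th <- if (!is.null(comps)) comps[[g]] else init_theta(data)
      lam_g <- effective_lambda(lambda1, sum(W[, g]), control)
      newcomps[[g]] <- m_step_cluster(data, W[, g], lam_g, th, penalized,
                                      control, Tm, freeze = freeze,
                                      score_env = score_env)
      newcomps[[g]]$pi <- pi[g]
    }
    comps <- newcomps
    ll <- mixture_loglik(data, list(components = comps))
    pen <- sum(vapply(seq_len(G), function(g) {
      effective_lambda(lambda1, sum(W[, g]), control) *
        sum(abs(comps[[g]]$beta[penalized]))
    }, numeric(1)))
    obj <- ll - pen - control$lambda2 * sum(vapply(comps, `[[`, numeric(1), "d"))
    trace <- c(trace, obj)
    if (control$verbose) {
      cat(sprintf("  iter %3d  objective %.6f\n", it, obj))
    }
    if (obj > best$obj) {
      best <- list(obj = obj, comps = comps, W = W, loglik = ll, iter = it)
    }
    if (it > 1L) {
      if (obj < prev) { status <- "decrease"; break }
      if (obj - prev < control$tol * (abs(prev) + 1)) {
        status <- "converged"; break
      }
    }
    prev <- obj
  }
  best$trace <- trace
  best$n_iter <- length(trace)
  best$status <- status
  best
}

#' Fit a mixture of penalized linear mixed models by alternating EM
#'
#' Fits a `G`-component finite mixture of random-intercept linear
#' mixed-effects models to a longitudinal dataset, with a LASSO penalty of
#' strength `lambda1` on the penalized fixed-effect coefficients of every
#' component. Each EM iteration recomputes posterior cluster
#' responsibilities and mixing probabilities, then updates each component's
#' coefficients by coordinate descent with soft-thresholding and its
#' variance parameters by an exact profile step. The alternation stops when
#' the penalized observed-data objective stops improving (or decreases), and
#' the best-objective iterate is returned. Several initializations are run
#' (k-means on per-subject trajectory features plus random hard
#' assignments); the best final objective wins.
#'
#' @param data a [long_data] object, typically standardized with
#'   [standardize_covariates()].
#' @param G number of mixture components, `1 <= G <=` number of subjects.
#' @param lambda1 nonnegative LASSO penalty.
#' @param control an [lmmclust_control()] list.
#' @param init optional warm start: a responsibility matrix or a previously
#'   fitted `lmmclust` model; when given, it is the only start.
#' @return An object of class `lmmclust` with components (each holding
#'   `beta`, `d`, `sigma2`, `pi`), the responsibility matrix `W`, hard
#'   `labels`, the unpenalized mixture `loglik`, the penalized `objective`,
#'   the per-iteration `loglik_trace`, and convergence diagnostics. Standard
#'   methods (`print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`,
#'   `predict`, `plot`, `simulate`) apply.
#' @examples
#' spec <- taag_spec(n_subjects = 120)
#' cohort <- simulate_cohort(spec, seed = 7)
#' dat <- standardize_covariates(cohort$data)
#' fit <- lmmclust(dat, G = 3, lambda1 = 5,
#'                 control = lmmclust_control(n_starts = 1, seed = 7))
#' fit
#' @export
lmmclust <- function(data, G, lambda1 = 0, control = lmmclust_control(),
                     init = NULL) {
  stopifnot(inherits(data, "long_data"))
  if (!is.numeric(G) || G < 1 || G != round(G)) {
    stop("G must be a positive integer", call. = FALSE)
  }
  if (G > data$n) stop("G exceeds the number of subjects", call. = FALSE)
  if (lambda1 < 0) stop("lambda1 must be nonnegative", call. = FALSE)
  if (!is.null(control$seed)) set.seed(control$seed)

  penalized <- penalized_mask(data, control)
  Tm <- subject_colsums(data)

  starts <- list()
  if (!is.null(init)) {
    W0 <- if (inherits(init, "lmmclust")) init$W else as.matrix(init)
    if (ncol(W0) != G || nrow(W0) != data$n) {
      stop("init responsibilities do not match (n, G)", call. = FALSE)
    }
    starts <- list(W0)
  } else {
    starts <- c(list(kmeans_start(data, G)),
                if (G > 1L) replicate(max(0L, control$n_starts - 1L),
                                      random_start(data, G),
                                      simplify = FALSE))
  }

  attempts <- list()
  for (W0 in starts) {
    res <- run_em(data, G, lambda1, control, W0, penalized, Tm)
    attempts <- c(attempts, list(res))
    retries <- 0L
    while (res$status == "empty" && retries < control$max_restarts) {
      retries <- retries + 1L
      res <- run_em(data, G, lambda1, control, random_start(data, G),
                    penalized, Tm)
      attempts <- c(attempts, list(res))
    }
  }
  objs <- vapply(attempts, `[[`, numeric(1), "obj")
  clean <- vapply(attempts, function(a) a$status != "empty", logical(1))
  best <- if (any(clean)) {
    attempts[clean][[which.max(objs[clean])]]
  } else {
    warning("a component repeatedly fell below the effective-size floor; ",
            "returning the best model found", call. = FALSE)
    attempts[[which.max(objs)]]
  }
  if (is.null(best$comps)) {
    stop("EM failed to complete a single iteration", call. = FALSE)
  }

  structure(list(
    call = match.call(),
    G = as.integer(G),
    lambda1 = lambda1,
    components = best$comps,
    W = best$W,
    labels = assign_cluster(best$W),
    loglik = best$loglik,
    objective = best$obj,
    loglik_trace = best$trace,
    converged = best$status %in% c("converged", "decrease"),
    stop_reason = best$status,
    n_iter = best$n_iter,
    penalized = penalized,
    data = data,
    control = control
  ), class = "lmmclust")
}

#' Hard cluster assignment from responsibilities
#'
#' @param W `n x G` responsibility matrix.
#' @return Integer labels in `1..G`; ties go to the lowest cluster index.
#' @export
assign_cluster <- function(W) {
  W <- as.matrix(W)
  max.col(W, ties.method = "first")
}

#' Penalty-path endpoint
#'
#' Computes the smallest penalty at which every penalized fixed-effect
#' coefficient is exactly zero in every component along the whole EM path.
#' The EM is run with the penalized coordinates pinned at zero (so the
#' trajectory equals that of any fit whose penalty keeps them at zero) and
#' the largest Karush-Kuhn-Tucker score `|x_j' A_i r| / sigma2` observed at
#' any coordinate sweep is returned. For any `lambda1` at or above this
#' value, [lmmclust()] started identically reproduces that trajectory with
#' all penalized coefficients exactly zero.
#'
#' @inheritParams lmmclust
#' @return The path endpoint `lambda_max`, a positive scalar.
#' @export
lambda_max <- function(data, G, control = lmmclust_control(), init = NULL) {
  stopifnot(inherits(data, "long_data"))
  if (!is.null(control$seed)) set.seed(control$seed)
  penalized <- penalized_mask(data, control)
  Tm <- subject_colsums(data)
  env <- new.env()
  env$max <- 0
  starts <- if (!is.null(init)) {
    list(if (inherits(init, "lmmclust")) init$W else as.matrix(init))
  } else {
    c(list(kmeans_start(data, G)),
      if (G > 1L) replicate(max(0L, control$n_starts - 1L),
                            random_start(data, G), simplify = FALSE))
  }
  for (W0 in starts) {
    run_em(data, G, 0, control, W0, penalized, Tm, freeze = TRUE,
           score_env = env)
  }
  env$max * (1 + 1e-8)
}
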