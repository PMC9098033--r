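# S3 methods for fitted lmmclust models

#' @export
print.lmmclust <- function(x, digits = 3, ...) {
  cat("Mixture of penalized linear mixed models\n")
  cat("  G = ", x$G, ", lambda1 = ", format(x$lambda1, digits = digits),
      ", ", x$data$n, " subjects / ", x$data$N, " records\n", sep = "")
  sizes <- tabulate(x$labels, x$G)
  pis <- vapply(x$components, `[[`, numeric(1), "pi")
  cat("  cluster sizes: ", paste(sizes, collapse = ", "),
      "   mixing: ", paste(format(pis, digits = digits), collapse = ", "),
      "\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 8),
      ", BIC ", format(model_bic(x), digits = 8), "\n", sep = "")
  cat("  ", x$n_iter, " EM iterations (", x$stop_reason, ")\n", sep = "")
  invisible(x)
}

#' Extract mixture component coefficients
#'
#' @param object a fitted [lmmclust] model.
#' @param scale `"original"` back-transforms coefficients to the covariate
#'   scale before standardization (intercept adjusted accordingly);
#'   `"standardized"` returns them as fitted.
#' @param ... ignored.
#' @return A `p x G` matrix of fixed-effect coefficients.
#' @export
coef.lmmclust <- function(object, scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  B <- vapply(object$components, `[[`, numeric(object$data$p), "beta")
  B <- matrix(B, ncol = object$G,
              dimnames = list(colnames(object$data$X),
                              paste0("cluster", seq_len(object$G))))
  if (scale == "original" && !is.null(object$data$std)) {
    B <- backtransform_coef(B, object$data$std)
  }
  B
}

# map coefficients fitted on z-scored covariates back to original units:
# slope_j -> slope_j / sd_j, intercept -> intercept - sum_j slope_j mu_j / sd_j
backtransform_coef <- function(B, std) {
  out <- B
  sc <- which(std$scaled)
  for (g in seq_len(ncol(B))) {
    shift <- sum(B[sc, g] * std$mean[sc] / std$sd[sc])
    out[sc, g] <- B[sc, g] / std$sd[sc]
    out["(Intercept)", g] <- B["(Intercept)", g] - shift
  }
  out
}

#' @export
logLik.lmmclust <- function(object, ...) {
  structure(object$loglik, df = model_df(object), nobs = object$data$N,
            class = "logLik")
}

#' @export
nobs.lmmclust <- function(object, ...) object$data$N

# degrees of freedom: nonzero fixed effects over all clusters, plus one
# (d_g, sigma2_g) pair per cluster, plus G - 1 free mixing probabilities
model_df <- function(model) {
  nnz <- sum(vapply(model$components, function(cp) sum(cp$beta != 0),
                    numeric(1)))
  nnz + 2L * model$G + (model$G - 1L)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = -2 loglik + df log(N)` with the unpenalized observed-data mixture
#' log-likelihood, `df` the number of nonzero fixed-effect coefficients over
#' all clusters plus `2G` variance parameters plus `G - 1` mixing
#' probabilities, and `N` the total number of records (or the number of
#' subjects with `count = "subjects"`, for sensitivity analysis). Identical
#' to `stats::BIC()` on the model when `count = "records"`.
#'
#' @param model a fitted [lmmclust] model.
#' @param count sample-size convention for the `log(N)` term.
#' @return The BIC, a scalar.
#' @export
model_bic <- function(model, count = c("records", "subjects")) {
  count <- match.arg(count)
  N <- if (count == "records") model$data$N else model$data$n
  -2 * model$loglik + model_df(model) * log(N)
}

#' @export
fitted.lmmclust <- function(object, ...) {
  B <- vapply(object$components, `[[`, numeric(object$data$p), "beta")
  B <- matrix(B, ncol = object$G)
  rowSums(object$data$X * t(B[, object$labels[object$data$id], drop = FALSE]))
}

#' @export
residuals.lmmclust <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Predict from a fitted mixture of linear mixed models
#'
#' @param object a fitted [lmmclust] model.
#' @param newdata a [long_data] object on the same covariate scale the model
#'   was fitted on (standardize with the training [std_info()] first);
#'   default: the training data.
#' @param type `"response"` for fitted means under the most probable
#'   cluster, `"class"` for hard cluster labels, `"posterior"` for the
#'   responsibility matrix.
#' @param ... ignored.
#' @return A vector (`response`, `class`) or `n x G` matrix (`posterior`).
#' @export
predict.lmmclust <- function(object, newdata = NULL,
                             type = c("response", "class", "posterior"),
                             ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  stopifnot(inherits(data, "long_data"))
  es <- e_step(data, object)
  if (type == "posterior") return(es$W)
  labels <- assign_cluster(es$W)
  if (type == "class") return(labels)
  B <- vapply(object$components, `[[`, numeric(data$p), "beta")
  B <- matrix(B, ncol = object$G)
  rowSums(data$X * t(B[, labels[data$id], drop = FALSE]))
}

#' @export
summary.lmmclust <- function(object, slope_threshold = 5, ...) {
  cs <- summarize_clusters(object$data, object$labels, object)
  tab <- selection_table(object)
  structure(list(model = object, clusters = cs, selection = tab,
                 slope_threshold = slope_threshold),
            class = "summary.lmmclust")
}

#' @export
print.summary.lmmclust <- function(x, digits = 3, ...) {
  print(x$model, digits = digits)
  cat("\nCluster trajectory summaries (outcome by wave):\n")
  print(x$clusters, digits = digits)
  cat("\nSelected variables (nonzero coefficients, original scale):\n")
  print(x$selection, digits = digits)
  invisible(x)
}

#' Plot mean trajectories of a fitted mixture
#'
#' Draws the model-implied linear mean trajectory of each cluster (intercept
#' plus wave coefficient on the original covariate scale, i.e. the expected
#' outcome at covariate means) and overlays the observed cluster-by-wave
#' outcome means under the hard labels.
#'
#' @param x a fitted [lmmclust] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lmmclust <- function(x, ...) {
  data <- x$data
  waves <- sort(unique(data$wave))
  B <- coef(x, scale = "original")
  mu <- outer(waves, B["wave", ]) +
    matrix(B["(Intercept)", ], length(waves), x$G, byrow = TRUE)
  obs <- matrix(NA_real_, length(waves), x$G)
  for (g in seq_len(x$G)) {
    rows <- x$labels[data$id] == g
    for (k in seq_along(waves)) {
      sel <- rows & data$wave == waves[k]
      if (any(sel)) obs[k, g] <- mean(data$y[sel])
    }
  }
  graphics::matplot(waves, mu, type = "l", lty = 1, lwd = 2,
                    xlab = "wave", ylab = data$outcome_name,
                    main = "Cluster mean trajectories", ...)
  graphics::matpoints(waves, obs, pch = 19)
  graphics::legend("topleft", bty = "n", lty = 1, lwd = 2,
                   col = seq_len(x$G),
                   legend = paste0("cluster ", seq_len(x$G),
                                   " (n=", tabulate(x$labels, x$G), ")"))
  invisible(x)
}

#' Simulate outcomes from a fitted mixture
#'
#' Draws new outcome vectors on the fitted design: each subject's component
#' is drawn from the mixing probabilities, then a random intercept and
#' residual noise are added to the component's linear predictor.
#'
#' @param object a fitted [lmmclust] model.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... ignored.
#' @return A data frame with `nsim` columns of length `N`.
#' @export
simulate.lmmclust <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  data <- object$data
  pis <- vapply(object$components, `[[`, numeric(1), "pi")
  B <- vapply(object$components, `[[`, numeric(data$p), "beta")
  B <- matrix(B, ncol = object$G)
  d <- vapply(object$components, `[[`, numeric(1), "d")
  s2 <- vapply(object$components, `[[`, numeric(1), "sigma2")
  out <- matrix(NA_real_, data$N, nsim)
  for (k in seq_len(nsim)) {
    z <- sample.int(object$G, data$n, replace = TRUE, prob = pis)
    b <- stats::rnorm(data$n, 0, sqrt(s2[z] * d[z]))
    mu <- rowSums(data$X * t(B[, z[data$id], drop = FALSE]))
    out[, k] <- mu + b[data$id] +
      stats::rnorm(data$N, 0, sqrt(s2[z[data$id]]))
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Serialize a fitted model to JSON
#'
#' Writes component parameters, mixing probabilities, responsibilities,
#' labels, the objective trace, and a control echo to a JSON file.
#'
#' @param model a fitted [lmmclust] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    G = model$G, lambda1 = model$lambda1,
    components = lapply(model$components, function(cp) {
      list(beta = as.list(cp$beta), d = cp$d, sigma2 = cp$sigma2, pi = cp$pi)
    }),
    W = unname(apply(model$W, 1, as.list)),
    labels = model$labels,
    loglik = model$loglik, objective = model$objective,
    loglik_trace = model$loglik_trace,
    converged = model$converged, n_iter = model$n_iter,
    control = model$control[c("max_iter", "tol", "n_starts", "seed",
                              "lambda2", "scale_by_size", "unpenalized")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
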