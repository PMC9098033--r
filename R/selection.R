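#' Grid search over cluster number and penalty strength
#'
#' Implements the staged fitting recipe: for each candidate number of
#' clusters, fit the penalized mixture along a descending penalty path (with
#' warm starts from the previous fit), compute the BIC of every fit, and
#' return the model minimizing BIC over the whole `(G, lambda1)` grid. Ties
#' are broken toward smaller `G`, then larger `lambda1`. Individual fit
#' failures are recorded and skipped; the search fails only if every fit
#' fails.
#'
#' @param data a [long_data] object (standardize covariates first).
#' @param G integer vector of candidate cluster numbers.
#' @param lambda optional penalty grid (applied to every G). Default: a
#'   log-spaced path of `nlambda` values from the per-G [lambda_max()] down
#'   to `lambda_min_ratio * lambda_max`, plus 0.
#' @param nlambda number of path points when `lambda` is `NULL`.
#' @param lambda_min_ratio smallest path value as a fraction of
#'   `lambda_max`.
#' @param control an [lmmclust_control()] list; if its `seed` is `NULL` a
#'   fixed seed is used so the path endpoint and the path fits share
#'   initializations.
#' @param count BIC sample-size convention, see [model_bic()].
#' @return An object of class `lmmclust_search`: a list with `grid` (one
#'   row per fit: G, lambda1, n_nonzero, df, loglik, bic, converged,
#'   iterations, error), `best` (the minimum-BIC [lmmclust] model),
#'   `best_per_G` (the minimum-BIC model for each candidate G),
#'   `lambda_max` per G, and the call.
#' @export
lmmclust_search <- function(data, G = 2:4, lambda = NULL, nlambda = 8L,
                            lambda_min_ratio = 0.01,
                            control = lmmclust_control(),
                            count = c("records", "subjects")) {
  stopifnot(inherits(data, "long_data"))
  count <- match.arg(count)
  if (!length(G)) stop("G grid is empty", call. = FALSE)
  if (!is.null(lambda) && !length(lambda)) {
    stop("lambda grid is empty", call. = FALSE)
  }
  if (is.null(control$seed)) control$seed <- 1L

  rows <- list()
  best <- NULL
  best_key <- c(Inf, Inf, -Inf)
  best_per_G <- stats::setNames(vector("list", length(G)), paste0("G", G))
  per_G_key <- rep(list(c(Inf, Inf, -Inf)), length(G))
  lmax_all <- stats::setNames(numeric(length(G)), G)

  for (gi in seq_along(G)) {
    g <- G[gi]
    if (is.null(lambda)) {
      lmax <- lambda_max(data, g, control)
      lmax_all[gi] <- lmax
      lam_grid <- c(exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                            length.out = nlambda)), 0)
    } else {
      lam_grid <- sort(unique(lambda), decreasing = TRUE)
      lmax_all[gi] <- NA_real_
    }
    prev <- NULL
    for (lam in lam_grid) {
      fit <- tryCatch(
        lmmclust(data, g, lam, control = control, init = prev),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows <- c(rows, list(data.frame(
          G = g, lambda1 = lam, n_nonzero = NA, df = NA, loglik = NA,
          bic = NA, converged = NA, iterations = NA,
          error = conditionMessage(fit))))
        next
      }
      prev <- fit
      bic <- model_bic(fit, count)
      nnz <- sum(vapply(fit$components,
                        function(cp) sum(cp$beta[fit$penalized] != 0),
                        numeric(1)))
      rows <- c(rows, list(data.frame(
        G = g, lambda1 = lam, n_nonzero = nnz, df = model_df(fit),
        loglik = fit$loglik, bic = bic, converged = fit$converged,
        iterations = fit$n_iter, error = NA_character_)))
      key <- c(bic, g, -lam)
      if (is.null(best) || compare_keys(key, best_key)) {
        best <- fit
        best_key <- key
      }
      if (compare_keys(key, per_G_key[[gi]])) {
        best_per_G[[gi]] <- fit
        per_G_key[[gi]] <- key
      }
    }
  }
  if (is.null(best)) stop("every fit in the grid failed", call. = FALSE)
  structure(list(grid = do.call(rbind, rows), best = best,
                 best_per_G = best_per_G,
                 lambda_max = lmax_all, count = count,
                 call = match.call()),
            class = "lmmclust_search")
}

# lexicographic "is a strictly better than b": smaller BIC, then smaller G,
# then larger lambda (encoded as -lambda)
compare_keys <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.lmmclust_search <- function(x, digits = 4, ...) {
  ok <- is.na(x$grid$error)
  cat("BIC grid search: ", sum(ok), " fits over G in {",
      paste(unique(x$grid$G), collapse = ", "), "}",
      if (any(!ok)) paste0(" (", sum(!ok), " failed)"), "\n", sep = "")
  b <- x$best
  cat("Selected: G = ", b$G, ", lambda1 = ", format(b$lambda1, digits = digits),
      ", BIC = ", format(model_bic(b, x$count), digits = 8), "\n\n", sep = "")
  print(x$grid[ok, setdiff(names(x$grid), "error")], digits = digits,
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.lmmclust_search <- function(x, ...) {
  g <- x$grid[is.na(x$grid$error), ]
  lam <- ifelse(g$lambda1 > 0, g$lambda1, min(g$lambda1[g$lambda1 > 0]) / 4)
  graphics::plot(lam, g$bic, log = "x", col = as.factor(g$G), pch = 19,
                 xlab = "lambda1 (log scale; 0 drawn leftmost)",
                 ylab = "BIC", main = "BIC over (G, lambda1)", ...)
  for (gg in unique(g$G)) {
    sel <- g$G == gg
    graphics::lines(lam[sel][order(lam[sel])],
                    g$bic[sel][order(lam[sel])],
                    col = which(unique(g$G) == gg))
  }
  graphics::legend("topright", bty = "n", pch = 19,
                   col = seq_along(unique(g$G)),
                   legend = paste0("G = ", unique(g$G)))
  invisible(x)
}

#' Post-selection unpenalized refits with Wald tests
#'
#' Refits, within each cluster of a hard partition, an unpenalized ML
#' random-intercept linear mixed model using only that cluster's selected
#' covariates, and reports Wald z statistics and two-sided normal p-values
#' from the inverse observed information of the fixed effects (treating the
#' variance parameters as fixed at their ML estimates). Intended as a
#' descriptive follow-up to the penalized fit; no multiple-testing
#' correction is applied and no post-selection adjustment is attempted.
#'
#' @param data a [long_data] object on the scale the selection was made.
#' @param labels hard cluster labels, length `n`.
#' @param selected list (one element per cluster) of selected covariate
#'   names; `character(0)` gives an intercept-only refit. A single character
#'   vector is recycled to every cluster.
#' @param control an [lmmclust_control()] list (tightened tolerances are
#'   used for the inner ML fits).
#' @return An object of class `lmmclust_refit`: per-cluster coefficient
#'   tables (`estimate`, `se`, `z`, `p`), variance parameters, and sizes.
#' @export
refit_clusters <- function(data, labels, selected,
                           control = lmmclust_control()) {
  stopifnot(inherits(data, "long_data"))
  if (length(labels) != data$n) {
    stop("labels must have one entry per subject", call. = FALSE)
  }
  clusters <- sort(unique(labels))
  if (!is.list(selected)) selected <- rep(list(selected), length(clusters))
  if (length(selected) != length(clusters)) {
    stop("'selected' must have one element per cluster", call. = FALSE)
  }
  control$tol <- min(control$tol, 1e-9)
  control$inner_tol <- min(control$inner_tol, 1e-10)
  control$cd_tol <- min(control$cd_tol, 1e-10)
  control$block_max <- max(control$block_max, 50L)

  fits <- vector("list", length(clusters))
  names(fits) <- paste0("cluster", clusters)
  for (k in seq_along(clusters)) {
    members <- which(labels == clusters[k])
    sel <- selected[[k]]
    bad <- setdiff(sel, colnames(data$X))
    if (length(bad)) {
      stop("unknown selected covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(members) < length(sel) + 3L) {
      stop("ill-posed refit: cluster ", clusters[k], " has ",
           length(members), " subjects for ", length(sel),
           " selected covariates", call. = FALSE)
    }
    sub <- subset_subjects(data, members, columns = sel)
    fit <- lmmclust(sub, G = 1L, lambda1 = 0, control = control)
    th <- fit$components[[1L]]
    se <- wald_se(sub, th)
    est <- th$beta
    z <- est / se
    fits[[k]] <- list(
      coef = data.frame(estimate = est, se = se, z = z,
                        p = 2 * stats::pnorm(-abs(z)),
                        row.names = names(est)),
      d = th$d, sigma2 = th$sigma2,
      n_subjects = length(members), n_records = sub$N,
      loglik = fit$loglik
    )
  }
  structure(list(clusters = fits, labels = labels), class = "lmmclust_refit")
}

# standard errors from the fixed-effect information sum_i X_i' V_i^{-1} X_i
# with V_i = sigma2 (d J + I); X'V^{-1}X = (X'X - sum_i c_i t_i t_i')/sigma2
wald_se <- function(data, theta) {
  cc <- theta$d / (1 + data$n_i * theta$d)
  Tm <- subject_colsums(data)
  info <- (crossprod(data$X) - crossprod(Tm * sqrt(cc))) / theta$sigma2
  sqrt(diag(solve(info)))
}

#' @export
print.lmmclust_refit <- function(x, digits = 3, ...) {
  for (nm in names(x$clusters)) {
    f <- x$clusters[[nm]]
    cat(nm, ": ", f$n_subjects, " subjects, ", f$n_records,
        " records, d = ", format(f$d, digits = digits),
        ", sigma2 = ", format(f$sigma2, digits = digits), "\n", sep = "")
    stats::printCoefmat(as.matrix(f$coef), digits = digits, P.values = TRUE,
                 has.Pvalue = TRUE)
    cat("\n")
  }
  invisible(x)
}
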