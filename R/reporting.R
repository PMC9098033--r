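#' Per-cluster, per-wave outcome summaries
#'
#' Computes, for each cluster of a hard partition, the sample mean and
#' standard deviation of the outcome at each wave over the available
#' records, together with cluster sizes and proportions. With a fitted
#' model, the cluster intercepts and wave coefficients (original scale) and
#' a trajectory label (maintainer / decreaser / increaser by the sign and
#' size of the wave coefficient) are attached.
#'
#' @param data a [long_data] object.
#' @param labels hard cluster labels, length `n`.
#' @param model optional fitted [lmmclust] model.
#' @param slope_threshold absolute wave-coefficient (outcome units per
#'   wave) below which a cluster is labelled a maintainer.
#' @return A data frame of class `cluster_summary` with one row per cluster
#'   x wave (`cluster`, `wave`, `n`, `mean`, `sd`); attributes `sizes` and
#'   `proportions`; with a model, columns `intercept`, `slope`,
#'   `trajectory`.
#' @export
summarize_clusters <- function(data, labels, model = NULL,
                               slope_threshold = 5) {
  stopifnot(inherits(data, "long_data"))
  if (length(labels) != data$n) {
    stop("labels must have one entry per subject", call. = FALSE)
  }
  G <- max(labels)
  waves <- sort(unique(data$wave))
  row_lab <- labels[data$id]
  out <- expand.grid(wave = waves, cluster = seq_len(G))[, 2:1]
  out$n <- out$mean <- out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    sel <- row_lab == out$cluster[r] & data$wave == out$wave[r]
    out$n[r] <- sum(sel)
    if (any(sel)) {
      out$mean[r] <- mean(data$y[sel])
      out$sd[r] <- stats::sd(data$y[sel])
    }
  }
  sizes <- tabulate(labels, G)
  if (!is.null(model)) {
    B <- coef(model, scale = "original")
    out$intercept <- B["(Intercept)", out$cluster]
    out$slope <- B["wave", out$cluster]
    out$trajectory <- ifelse(abs(out$slope) < slope_threshold, "maintainer",
                             ifelse(out$slope < 0, "decreaser", "increaser"))
  }
  structure(out, sizes = sizes, proportions = sizes / sum(sizes),
            class = c("cluster_summary", "data.frame"))
}

#' @export
print.cluster_summary <- function(x, digits = 3, ...) {
  sizes <- attr(x, "sizes")
  cat("Cluster sizes: ", paste(sizes, collapse = ", "),
      "  (proportions ",
      paste(format(attr(x, "proportions"), digits = digits), collapse = ", "),
      ")\n", sep = "")
  if (any(sizes == 0)) {
    cat("  [cluster(s) ", paste(which(sizes == 0), collapse = ", "),
        " empty: summaries undefined]\n", sep = "")
  }
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Per-cluster variable selection table
#'
#' Tabulates the fixed-effect coefficients that are nonzero in at least one
#' cluster, one column per cluster, with zeros rendered blank. Coefficients
#' are back-transformed to the original covariate scale using the dataset's
#' standardization record, so entries are in outcome units per original
#' covariate unit; the intercept row (always present) is the expected
#' outcome at wave 0 and covariate zero. Unpenalized rows are always shown.
#'
#' @param model a fitted [lmmclust] model.
#' @param std optional standardization record (default: the one stored with
#'   the model's data).
#' @return A data frame of class `selection_table`, zeros as `NA`.
#' @export
selection_table <- function(model, std = NULL) {
  stopifnot(inherits(model, "lmmclust"))
  if (is.null(std)) std <- model$data$std
  B <- vapply(model$components, `[[`, numeric(model$data$p), "beta")
  B <- matrix(B, ncol = model$G,
              dimnames = list(colnames(model$data$X),
                              paste0("cluster", seq_len(model$G))))
  support <- B != 0
  if (!is.null(std)) B <- backtransform_coef(B, std)
  keep <- rowSums(support) > 0 | !model$penalized
  tab <- as.data.frame(B[keep, , drop = FALSE])
  tab[!support[keep, , drop = FALSE]] <- NA_real_
  structure(tab, class = c("selection_table", "data.frame"))
}

#' @export
print.selection_table <- function(x, digits = 3, ...) {
  m <- as.matrix(format(round(as.data.frame(x), digits)))
  m[is.na(as.data.frame(x))] <- ""
  print(m, quote = FALSE, right = TRUE)
  invisible(x)
}

#' Cross-tabulate two partitions
#'
#' Contingency table of two hard clusterings of the same subjects, with row
#' and column totals appended.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param names_a,names_b dimension names for display.
#' @return A table with margins.
#' @export
cross_tabulate <- function(labels_a, labels_b, names_a = "partition A",
                           names_b = "partition B") {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b, dnn = c(names_a, names_b))
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two hard clusterings: 1 if and only
#' if the partitions are identical up to relabelling, about 0 for
#' independent labelings.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(labels_a), 2)
  expected <- b * cc / n2
  maxidx <- (b + cc) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (a - expected) / (maxidx - expected)
}

#' Align cluster labels to a reference partition
#'
#' Relabels `labels` by the permutation of cluster indices maximizing the
#' diagonal overlap with `reference` (exhaustive search over permutations;
#' exact for the small G used here).
#'
#' @param labels label vector to relabel (values in `1..G`).
#' @param reference reference label vector of equal length.
#' @return `labels` with permuted cluster indices.
#' @export
align_labels <- function(labels, reference) {
  if (length(labels) != length(reference)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  G <- max(labels, reference)
  if (G > 8) stop("exhaustive alignment supports at most 8 clusters",
                  call. = FALSE)
  tab <- table(factor(labels, 1:G), factor(reference, 1:G))
  perms <- permutations(G)
  overlap <- apply(perms, 1, function(p) sum(tab[cbind(1:G, p)]))
  best <- perms[which.max(overlap), ]
  unname(best[labels])
}

permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(j, matrix(ifelse(sub >= j, sub + 1L, sub), nrow(sub)))
  }))
}
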