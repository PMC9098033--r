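#' Assemble a long-format longitudinal dataset
#'
#' Builds the internal representation used by all fitting functions from a
#' long-format data frame with one row per subject-wave: the stacked outcome
#' vector, a fixed-effects design matrix whose first column is the intercept
#' and second column the (0-based) wave index, and subject grouping
#' information. The random-effects design is the subject-level random
#' intercept (a column of ones per subject).
#'
#' Rows are grouped by subject and sorted by wave; wave values are recoded to
#' consecutive integers starting at 0 so that the intercept is the first-wave
#' baseline. Categorical covariates are expanded into reference-coded dummy
#' columns (reference = first level, or the level named in `categorical`).
#' Rows with a missing value in any modelled column are dropped with a
#' message.
#'
#' @param df data frame, one row per subject-wave.
#' @param id name of the subject identifier column.
#' @param wave name of the wave/occasion column (numeric or integer).
#' @param outcome name of the continuous outcome column.
#' @param covariates character vector of covariate column names; default all
#'   remaining columns.
#' @param categorical character vector of covariate names to dummy-code, or a
#'   named list/character vector mapping covariate name to reference level.
#' @return An object of class `long_data`: a list with stacked `y`, `X`
#'   (intercept, wave, covariates), row-level `id` and `wave`, per-subject
#'   record counts `n_i`, `subject_ids`, and dimensions `n`, `N`, `p`.
#' @seealso [read_long_csv()], [standardize_covariates()]
#' @export
long_data <- function(df, id = "id", wave = "wave", outcome = "y",
                      covariates = NULL, categorical = NULL) {
  df <- as.data.frame(df)
  for (col in c(id, wave, outcome)) {
    if (!col %in% names(df)) {
      stop("required column '", col, "' not found in input", call. = FALSE)
    }
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c(id, wave, outcome))
  } else {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov)) {
      stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
  }

  cat_ref <- character(0)
  if (!is.null(categorical)) {
    if (is.list(categorical) || !is.null(names(categorical))) {
      cat_ref <- unlist(categorical)
    } else {
      cat_ref <- stats::setNames(rep(NA_character_, length(categorical)), categorical)
    }
    unknown <- setdiff(names(cat_ref), covariates)
    if (length(unknown)) {
      stop("categorical column(s) not among covariates: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  for (col in covariates) {
    if (!is.numeric(df[[col]]) && !col %in% names(cat_ref)) {
      stop("covariate '", col, "' is non-numeric and not declared categorical",
           call. = FALSE)
    }
  }
  if (!is.numeric(df[[wave]])) stop("wave column must be numeric", call. = FALSE)
  if (!is.numeric(df[[outcome]])) stop("outcome column must be numeric", call. = FALSE)

  modelled <- c(id, wave, outcome, covariates)
  complete <- stats::complete.cases(df[modelled])
  if (!all(complete)) {
    message("dropping ", sum(!complete), " row(s) with missing modelled values")
    df <- df[complete, , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete rows remain", call. = FALSE)

  if (anyDuplicated(df[c(id, wave)])) {
    dup <- df[duplicated(df[c(id, wave)]), c(id, wave)]
    stop("duplicate (subject, wave) pair(s), e.g. subject ", dup[1, 1],
         " wave ", dup[1, 2], call. = FALSE)
  }

  # group by subject, sort by wave, recode waves to 0,1,2,...
  wave_levels <- sort(unique(df[[wave]]))
  wave_idx <- match(df[[wave]], wave_levels) - 1L
  subject_ids <- sort(unique(df[[id]]))  # canonical order: row-permutation invariant
  ord <- order(match(df[[id]], subject_ids), wave_idx)
  df <- df[ord, , drop = FALSE]
  wave_idx <- wave_idx[ord]
  row_id <- match(df[[id]], subject_ids)

  # dummy-code categoricals (reference level dropped)
  cols <- list("(Intercept)" = rep(1, nrow(df)), wave = as.numeric(wave_idx))
  for (col in covariates) {
    if (col %in% names(cat_ref)) {
      f <- factor(df[[col]])
      ref <- cat_ref[[col]]
      if (!is.na(ref)) {
        if (!ref %in% levels(f)) {
          stop("reference level '", ref, "' not found in '", col, "'", call. = FALSE)
        }
        f <- stats::relevel(f, ref)
      }
      for (lev in levels(f)[-1]) {
        cols[[paste(col, lev, sep = "_")]] <- as.numeric(f == lev)
      }
    } else {
      cols[[col]] <- as.numeric(df[[col]])
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL

  const <- vapply(seq_len(ncol(X))[-1], function(j) {
    stats::sd(X[, j]) < .Machine$double.eps^0.5
  }, logical(1))
  if (any(const)) {
    stop("constant covariate column(s) after assembly: ",
         paste(colnames(X)[-1][const], collapse = ", "), call. = FALSE)
  }

  out <- structure(list(
    y = as.numeric(df[[outcome]]),
    X = X,
    id = row_id,
    wave = wave_idx,
    wave_levels = wave_levels,
    subject_ids = subject_ids,
    n_i = as.integer(tabulate(row_id)),
    n = length(subject_ids),
    N = nrow(df),
    p = ncol(X),
    covariate_names = colnames(X),
    outcome_name = outcome,
    id_name = id,
    wave_name = wave,
    std = NULL
  ), class = "long_data")
  out
}

#' @export
print.long_data <- function(x, ...) {
  cat("Longitudinal dataset: ", x$n, " subjects, ", x$N, " records, ",
      x$p - 2L, " covariates\n", sep = "")
  cat("  records per subject: ",
      paste(names(table(x$n_i)), table(x$n_i), sep = "x", collapse = ", "),
      "\n", sep = "")
  cat("  waves (0-based): ", paste(sort(unique(x$wave)), collapse = ", "),
      if (!is.null(x$std)) "  [covariates standardized]", "\n", sep = "")
  invisible(x)
}

#' Read a long-format longitudinal CSV
#'
#' Reads a delimited text file with a header row and assembles a
#' [long_data] object according to a schema mapping column roles. The schema
#' is a list with entries `id`, `wave`, `outcome`, and optionally
#' `covariates` (default: all remaining columns) and `categorical`; it may
#' also be the path to a YAML or JSON file holding that list.
#'
#' @param file path to a CSV file.
#' @param schema list of column roles, or path to a YAML/JSON schema file.
#' @param ... passed on to [utils::read.csv()].
#' @return A [long_data] object.
#' @export
read_long_csv <- function(file, schema, ...) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- read_schema(schema)
  }
  if (is.null(schema$id) || is.null(schema$wave) || is.null(schema$outcome)) {
    stop("schema must name 'id', 'wave' and 'outcome' columns", call. = FALSE)
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE, ...)
  long_data(df, id = schema$id, wave = schema$wave, outcome = schema$outcome,
            covariates = schema$covariates, categorical = schema$categorical)
}

read_schema <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML schemas requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a long-format longitudinal dataset to CSV
#'
#' Inverse of [read_long_csv()] for datasets whose covariates are plain
#' numeric columns (dummy columns are written as 0/1). Writes one row per
#' subject-wave with the original id, wave, and outcome column names.
#'
#' @param data a [long_data] object.
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_long_csv <- function(data, file) {
  stopifnot(inherits(data, "long_data"))
  df <- data.frame(data$subject_ids[data$id],
                   data$wave_levels[data$wave + 1L],
                   data$y,
                   data$X[, -(1:2), drop = FALSE],
                   check.names = FALSE)
  names(df)[1:3] <- c(data$id_name, data$wave_name, data$outcome_name)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Standardize covariate columns
#'
#' Z-scores each non-exempt covariate column of the design matrix over all
#' pooled rows (mean 0, standard deviation 1). The intercept is always
#' exempt and the outcome is never touched, so fitted coefficients stay in
#' outcome units per covariate standard deviation; the wave indicator is
#' standardized like any other covariate unless listed in `exempt`.
#' The transform is recorded in the returned object and can be undone with
#' [unstandardize()]; [std_info()] retrieves the per-column means and
#' standard deviations.
#'
#' @param data a [long_data] object.
#' @param exempt character vector of column names to leave unscaled.
#' @return The dataset with transformed covariates and a standardization
#'   record attached.
#' @export
standardize_covariates <- function(data, exempt = character(0)) {
  stopifnot(inherits(data, "long_data"))
  if (!is.null(data$std)) return(data)  # idempotent on the stored transform
  nm <- colnames(data$X)
  scaled <- !(nm %in% c("(Intercept)", exempt))
  mu <- sdv <- rep(NA_real_, data$p)
  for (j in which(scaled)) {
    mu[j] <- mean(data$X[, j])
    sdv[j] <- stats::sd(data$X[, j])
    if (!is.finite(sdv[j]) || sdv[j] < .Machine$double.eps^0.5) {
      stop("degenerate covariate: column '", nm[j],
           "' has zero variance and is not exempt", call. = FALSE)
    }
    data$X[, j] <- (data$X[, j] - mu[j]) / sdv[j]
  }
  data$std <- data.frame(column = nm, mean = mu, sd = sdv, scaled = scaled,
                         stringsAsFactors = FALSE)
  data
}

#' Retrieve the standardization record of a dataset
#'
#' @param data a [long_data] object.
#' @return A data frame with one row per design column (`column`, `mean`,
#'   `sd`, `scaled`), or `NULL` when the data are unstandardized.
#' @export
std_info <- function(data) {
  stopifnot(inherits(data, "long_data"))
  data$std
}

#' Undo covariate standardization
#'
#' @param data a [long_data] object previously passed through
#'   [standardize_covariates()].
#' @return The dataset with covariates back on their original scale.
#' @export
unstandardize <- function(data) {
  stopifnot(inherits(data, "long_data"))
  if (is.null(data$std)) return(data)
  for (j in which(data$std$scaled)) {
    data$X[, j] <- data$X[, j] * data$std$sd[j] + data$std$mean[j]
  }
  data$std <- NULL
  data
}

# Subset a long_data object by subject index (and optionally design columns,
# always retaining the intercept). Internal.
subset_subjects <- function(data, subjects, columns = NULL) {
  keep <- data$id %in% subjects
  new_id <- match(data$id[keep], subjects)
  X <- data$X[keep, , drop = FALSE]
  if (!is.null(columns)) {
    columns <- union("(Intercept)", columns)
    X <- X[, colnames(X) %in% columns, drop = FALSE]
  }
  std <- data$std
  if (!is.null(std) && !is.null(columns)) {
    std <- std[std$column %in% colnames(X), , drop = FALSE]
  }
  structure(list(
    y = data$y[keep], X = X, id = new_id, wave = data$wave[keep],
    wave_levels = data$wave_levels,
    subject_ids = data$subject_ids[subjects],
    n_i = as.integer(tabulate(new_id, nbins = length(subjects))),
    n = length(subjects), N = sum(keep), p = ncol(X),
    covariate_names = colnames(X),
    outcome_name = data$outcome_name, id_name = data$id_name,
    wave_name = data$wave_name, std = std
  ), class = "long_data")
}
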