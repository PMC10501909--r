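# Elastic-net clock training, prediction, age acceleration and group tests.

# Match per-sample trait rows to a sample sheet, keeping table attributes.
.sample_traits <- function(samples, traits) {
  stopifnot(inherits(traits, "trait_table"))
  i <- match(samples$species_id, traits$species_id)
  if (anyNA(i)) {
    stop("unknown species in sample sheet: ",
         paste(unique(samples$species_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  out <- traits[i, , drop = FALSE]
  attr(out, "lifespan_adjusted") <- attr(traits, "lifespan_adjusted")
  class(out) <- c("trait_table", "data.frame")
  out
}

# Validate a sample sheet against a beta matrix and return it column-aligned.
.align_samples <- function(betas, samples) {
  stopifnot(is.matrix(betas), is.data.frame(samples))
  need <- c("sample_id", "species_id", "tissue", "age")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  j <- match(samples$sample_id, colnames(betas))
  if (anyNA(j)) {
    stop("samples absent from beta matrix: ",
         paste(samples$sample_id[is.na(j)], collapse = ", "), call. = FALSE)
  }
  list(betas = betas[, j, drop = FALSE], samples = samples)
}

#' Train a universal epigenetic clock
#'
#' Fits an elastic-net regression of the transformed age on CpG beta values.
#' The outcome is the chosen clock transformation of chronological age
#' ([clock1_forward()], [clock2_forward()] or [clock3_forward()]), evaluated
#' with each sample's species traits. The penalty strength is chosen by
#' internal k-fold cross-validation at the minimum mean cross-validated
#' error; the mixing parameter defaults to 0.5 (the pan-tissue clock
#' convention). Predictors are used on the raw beta scale.
#'
#' CpGs with more than `missing_max` missing values among training samples
#' are dropped; remaining missing entries are mean-imputed per CpG, and the
#' training means of the retained model CpGs are stored in the model for
#' prediction-time imputation.
#'
#' @param betas numeric matrix of beta values in \[0, 1\] (rows CpGs, columns
#'   samples; dimnames required).
#' @param samples data frame with columns `sample_id`, `species_id`,
#'   `tissue`, `age` (years).
#' @param traits a [trait_table()]; must be lifespan-adjusted for `clock2`.
#' @param clock_kind `"clock1"`, `"clock2"` or `"clock3"`.
#' @param alpha elastic-net mixing parameter in (0, 1\]; default 0.5.
#' @param nfolds internal cross-validation fold count; default 10.
#' @param seed integer seed controlling the internal fold split.
#' @param missing_max maximum tolerated per-CpG missing fraction; default 0.2.
#' @param constants a [clock_constants()] list.
#' @return A `clock_model`: list with `clock_kind`, `intercept`,
#'   `coefficients` (named vector of nonzero CpG weights),
#'   `training_means`, `constants` and training metadata.
#' @export
train_clock <- function(betas, samples, traits,
                        clock_kind = c("clock2", "clock1", "clock3"),
                        alpha = 0.5, nfolds = 10, seed = 1,
                        missing_max = 0.2,
                        constants = clock_constants()) {
  clock_kind <- match.arg(clock_kind)
  stopifnot(alpha > 0, alpha <= 1, nfolds >= 2)
  al <- .align_samples(betas, samples)
  betas <- al$betas
  samples <- al$samples
  if (nrow(samples) < nfolds) {
    stop("fewer samples (", nrow(samples), ") than internal folds (",
         nfolds, ")", call. = FALSE)
  }
  st <- .sample_traits(samples, traits)
  y <- .clock_forward(clock_kind, samples$age, st, constants)

  miss_frac <- rowMeans(is.na(betas))
  keep <- miss_frac <= missing_max
  betas <- betas[keep, , drop = FALSE]
  means <- rowMeans(betas, na.rm = TRUE)
  if (anyNA(betas)) {
    na_idx <- which(is.na(betas), arr.ind = TRUE)
    betas[na_idx] <- means[na_idx[, 1L]]
  }
  x <- t(betas)

  if (stats::sd(y) == 0) {
    model <- list(intercept = y[1], coefficients = stats::setNames(
      numeric(0), character(0)), lambda = NA_real_)
  } else {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = nfolds,
                            family = "gaussian")
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
    nz <- which(cf[-1, 1] != 0)
    model <- list(intercept = unname(cf[1, 1]),
                  coefficients = stats::setNames(cf[-1, 1][nz],
                                                 rownames(cf)[-1][nz]),
                  lambda = cv$lambda.min)
  }

  structure(list(
    clock_kind = clock_kind,
    intercept = model$intercept,
    coefficients = model$coefficients,
    training_means = means[names(model$coefficients)],
    constants = constants,
    metadata = list(seed = seed, alpha = alpha, nfolds = nfolds,
                    lambda = model$lambda,
                    n_samples = nrow(samples),
                    n_cpgs = nrow(betas),
                    n_nonzero = length(model$coefficients),
                    lifespan_adjusted = isTRUE(attr(traits,
                                                    "lifespan_adjusted")))),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Universal clock (", x$clock_kind, "): ",
      x$metadata$n_nonzero, " CpGs, intercept ",
      signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' Predict DNAm age with a trained clock
#'
#' Computes the linear prediction on the transformed scale and maps it back
#' to years through the clock-specific inverse transformation, using each
#' sample's species traits. Model CpGs absent from the supplied matrix, and
#' missing values within it, are imputed with the training means stored in
#' the model.
#'
#' @param model a [train_clock()] result.
#' @inheritParams train_clock
#' @return Data frame with `sample_id`, `species_id`, `tissue`, `age`,
#'   `y_hat` (transformed scale) and `dnam_age` (years).
#' @export
predict_age <- function(model, betas, samples, traits) {
  stopifnot(inherits(model, "clock_model"))
  al <- .align_samples(betas, samples)
  betas <- al$betas
  samples <- al$samples
  st <- .sample_traits(samples, traits)

  cpgs <- names(model$coefficients)
  if (length(cpgs) > 0L) {
    sub <- matrix(rep(model$training_means, ncol(betas)),
                  nrow = length(cpgs), dimnames = list(cpgs, colnames(betas)))
    have <- intersect(cpgs, rownames(betas))
    sub[have, ] <- betas[have, , drop = FALSE]
    if (anyNA(sub)) {
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      sub[na_idx] <- model$training_means[na_idx[, 1L]]
    }
    y_hat <- drop(model$intercept + crossprod(sub, model$coefficients))
  } else {
    y_hat <- rep(model$intercept, nrow(samples))
  }

  data.frame(sample_id = samples$sample_id,
             species_id = samples$species_id,
             tissue = samples$tissue,
             age = samples$age,
             y_hat = unname(y_hat),
             dnam_age = unname(.clock_inverse(model$clock_kind, y_hat, st,
                                              model$constants)),
             stringsAsFactors = FALSE)
}

#' Epigenetic age acceleration
#'
#' The raw residual from regressing DNAm age on chronological age by
#' ordinary least squares. By construction the residuals have zero mean and
#' are uncorrelated with chronological age, so AgeAccel compares individuals
#' net of their age.
#'
#' @param predictions a [predict_age()] data frame (columns `sample_id`,
#'   `age`, `dnam_age`).
#' @return Named numeric vector of residuals in years.
#' @export
age_acceleration <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("sample_id", "age", "dnam_age") %in% names(predictions)))
  if (nrow(predictions) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(predictions$age) == 0) {
    stop("zero variance in chronological age", call. = FALSE)
  }
  fit <- stats::lm(dnam_age ~ age, data = predictions)
  stats::setNames(unname(stats::residuals(fit)), predictions$sample_id)
}

#' Group comparison of age acceleration
#'
#' Two-sample t-test of AgeAccel between a control and an experimental
#' group. The reported sign is positive when the control mean exceeds the
#' experimental mean (control animals epigenetically older than treated
#' ones), matching the convention used for anti-aging intervention studies.
#'
#' @param accel numeric vector of age-acceleration residuals.
#' @param groups two-level factor or character vector, parallel to `accel`.
#' @param control label of the control group; defaults to the first level.
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return List with `t`, `p`, `sign`, `mean_control`, `mean_other`.
#' @export
group_ageaccel_test <- function(accel, groups, control = NULL,
                                var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("groups must have exactly 2 levels", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(control)) control <- levels(groups)[1]
  if (!control %in% levels(groups)) {
    stop("control level not found: ", control, call. = FALSE)
  }
  other <- setdiff(levels(groups), control)
  a <- accel[groups == control]
  b <- accel[groups == other]
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       sign = sign(mean(a) - mean(b)),
       mean_control = mean(a), mean_other = mean(b))
}

.clock_format_version <- 1L

#' Save a clock model to a directory
#'
#' Writes `coefficients.csv` (header `cpg_id,coefficient` with a reserved
#' `(Intercept)` row, the de-facto convention for published clocks),
#' `training_means.csv`, and a `metadata.yml` sidecar carrying the clock
#' kind, transformation constants, training metadata and a format version.
#' The round trip through [load_clock()] is lossless.
#'
#' @param model a `clock_model`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  num <- function(v) sprintf("%.17g", v)
  writeLines(c("cpg_id,coefficient",
               paste0("(Intercept),", num(model$intercept)),
               paste0(names(model$coefficients), ",",
                      num(model$coefficients))),
             file.path(path, "coefficients.csv"))
  writeLines(c("cpg_id,training_mean",
               paste0(names(model$training_means), ",",
                      num(model$training_means))),
             file.path(path, "training_means.csv"))
  yaml::write_yaml(list(format_version = .clock_format_version,
                        clock_kind = model$clock_kind,
                        constants = unclass(model$constants),
                        metadata = model$metadata),
                   file.path(path, "metadata.yml"))
  invisible(path)
}

#' Load a clock model saved by [save_clock()]
#'
#' @param path directory written by [save_clock()].
#' @return A `clock_model`.
#' @export
load_clock <- function(path) {
  meta_file <- file.path(path, "metadata.yml")
  coef_file <- file.path(path, "coefficients.csv")
  means_file <- file.path(path, "training_means.csv")
  for (f in c(meta_file, coef_file, means_file)) {
    if (!file.exists(f)) stop("clock file missing: ", f, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_file)
  if (!identical(as.integer(meta$format_version), .clock_format_version)) {
    stop("unsupported clock format version: ", meta$format_version,
         call. = FALSE)
  }
  cf <- utils::read.csv(coef_file, stringsAsFactors = FALSE)
  if (!identical(names(cf), c("cpg_id", "coefficient")) ||
      nrow(cf) < 1L || !identical(cf$cpg_id[1], "(Intercept)") ||
      anyNA(cf$coefficient)) {
    stop("malformed clock coefficient file: ", coef_file, call. = FALSE)
  }
  mn <- utils::read.csv(means_file, stringsAsFactors = FALSE)
  if (!identical(names(mn), c("cpg_id", "training_mean"))) {
    stop("malformed training means file: ", means_file, call. = FALSE)
  }
  constants <- do.call(clock_constants, meta$constants)
  structure(list(
    clock_kind = meta$clock_kind,
    intercept = cf$coefficient[1],
    coefficients = stats::setNames(cf$coefficient[-1], cf$cpg_id[-1]),
    training_means = stats::setNames(mn$training_mean, mn$cpg_id),
    constants = constants,
    metadata = meta$metadata), class = "clock_model")
}
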