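# Stratified cross-validation splits and prediction evaluation statistics.

#' Leave-one-fraction-out fold assignment
#'
#' Partitions the samples into `k` folds so that every (species, tissue)
#' stratum is spread across folds as evenly as its size allows: within each
#' stratum the samples are shuffled with the global seed and dealt
#' round-robin from a random starting fold, so per-stratum fold counts never
#' differ by more than one.
#'
#' @param samples sample sheet (columns `sample_id`, `species_id`, `tissue`).
#' @param k number of folds, default 10.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return A `fold_assignment` data frame (`sample_id`, `fold`) with
#'   attributes `mode = "lofo"`, `k` and `seed`.
#' @export
lofo_folds <- function(samples, k = 10, seed = 1) {
  stopifnot(is.data.frame(samples), k >= 2)
  if (k > nrow(samples)) {
    stop("more folds (", k, ") than samples (", nrow(samples), ")",
         call. = FALSE)
  }
  set.seed(seed)
  stratum <- interaction(samples$species_id, samples$tissue, drop = TRUE)
  fold <- integer(nrow(samples))
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  structure(data.frame(sample_id = samples$sample_id, fold = fold,
                       stringsAsFactors = FALSE),
            mode = "lofo", k = k, seed = seed,
            class = c("fold_assignment", "data.frame"))
}

#' Leave-one-species-out fold assignment
#'
#' One fold per species, containing all of that species' samples.
#'
#' @param samples sample sheet (columns `sample_id`, `species_id`).
#' @return A `fold_assignment` data frame (`sample_id`, `fold` = species id)
#'   with attribute `mode = "loso"`.
#' @export
loso_folds <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (length(unique(samples$species_id)) < 2L) {
    stop("leave-one-species-out requires at least 2 species", call. = FALSE)
  }
  structure(data.frame(sample_id = samples$sample_id,
                       fold = samples$species_id,
                       stringsAsFactors = FALSE),
            mode = "loso",
            class = c("fold_assignment", "data.frame"))
}

#' Out-of-fold clock predictions
#'
#' For each fold, trains a clock on the complement ([train_clock()]) and
#' predicts the held-out fold ([predict_age()]); every sample receives
#' exactly one out-of-fold prediction. Fold-specific training seeds are
#' derived deterministically from `seed`.
#'
#' @inheritParams train_clock
#' @param folds a [lofo_folds()] or [loso_folds()] assignment.
#' @param ... further arguments passed to [train_clock()] (e.g. `alpha`).
#' @return Data frame of out-of-fold predictions (as [predict_age()]) plus a
#'   `fold` column.
#' @export
run_crossval <- function(betas, samples, traits,
                         clock_kind = c("clock2", "clock1", "clock3"),
                         folds, nfolds = 10, seed = 1, ...) {
  clock_kind <- match.arg(clock_kind)
  stopifnot(inherits(folds, "fold_assignment"))
  if (!setequal(folds$sample_id, samples$sample_id)) {
    stop("fold assignment does not cover the sample sheet", call. = FALSE)
  }
  fold_of <- folds$fold[match(samples$sample_id, folds$sample_id)]
  out <- vector("list", length(unique(fold_of)))
  for (i in seq_along(sort(unique(fold_of)))) {
    f <- sort(unique(fold_of))[i]
    held <- fold_of == f
    if (sum(!held) < nfolds) {
      stop("training complement of fold ", f, " has fewer than ", nfolds,
           " samples", call. = FALSE)
    }
    model <- train_clock(betas, samples[!held, , drop = FALSE], traits,
                         clock_kind = clock_kind, nfolds = nfolds,
                         seed = seed + i, ...)
    p <- predict_age(model, betas, samples[held, , drop = FALSE], traits)
    p$fold <- f
    out[[i]] <- p
  }
  res <- do.call(rbind, out)
  res[match(samples$sample_id, res$sample_id), , drop = FALSE]
}

#' Evaluate clock predictions
#'
#' Computes the overall Pearson correlation and MAE between DNAm age and
#' chronological age, the same statistics per species and per
#' species-tissue stratum restricted to strata with at least `min_stratum_n`
#' samples, and the medians of the per-stratum statistics. "MAE" is the
#' median absolute error in years by default (`mae_type = "median"`); the
#' mean variant is available.
#'
#' @param predictions data frame with `species_id`, `tissue`, `age`,
#'   `dnam_age` (e.g. from [run_crossval()]).
#' @param min_stratum_n minimum stratum size entering the medians; default 15.
#' @param mae_type `"median"` (default) or `"mean"` absolute error.
#' @return List of class `clock_eval`: `overall_cor`, `overall_mae`,
#'   per-stratum tables `species` and `species_tissue`, their medians
#'   (`NA` when no stratum qualifies), and the threshold used.
#' @export
evaluate <- function(predictions, min_stratum_n = 15,
                     mae_type = c("median", "mean")) {
  mae_type <- match.arg(mae_type)
  stopifnot(all(c("species_id", "tissue", "age", "dnam_age") %in%
                  names(predictions)))
  mae_fun <- if (mae_type == "median") stats::median else mean
  err <- abs(predictions$dnam_age - predictions$age)

  stat_by <- function(key) {
    parts <- split(seq_len(nrow(predictions)), key, drop = TRUE)
    df <- data.frame(stratum = names(parts),
                     n = lengths(parts),
                     cor = NA_real_, mae = NA_real_,
                     stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_along(parts)) {
      idx <- parts[[i]]
      if (length(idx) >= 2L && stats::sd(predictions$age[idx]) > 0 &&
          stats::sd(predictions$dnam_age[idx]) > 0) {
        df$cor[i] <- stats::cor(predictions$age[idx],
                                predictions$dnam_age[idx])
      }
      df$mae[i] <- mae_fun(err[idx])
    }
    df
  }

  sp <- stat_by(predictions$species_id)
  spt <- stat_by(interaction(predictions$species_id, predictions$tissue,
                             sep = ":", drop = TRUE))
  med <- function(df, col) {
    v <- df[[col]][df$n >= min_stratum_n]
    if (length(v) == 0L) NA_real_ else stats::median(v, na.rm = TRUE)
  }
  structure(list(
    overall_cor = if (stats::sd(predictions$age) > 0 &&
                      stats::sd(predictions$dnam_age) > 0)
      stats::cor(predictions$age, predictions$dnam_age) else NA_real_,
    overall_mae = mae_fun(err),
    species = sp,
    species_tissue = spt,
    median_cor_species = med(sp, "cor"),
    median_mae_species = med(sp, "mae"),
    median_cor_species_tissue = med(spt, "cor"),
    median_mae_species_tissue = med(spt, "mae"),
    min_stratum_n = min_stratum_n,
    mae_type = mae_type), class = "clock_eval")
}

#' @export
print.clock_eval <- function(x, ...) {
  cat(sprintf("overall: r = %.3f, MAE = %.3f years (%s)\n",
              x$overall_cor, x$overall_mae, x$mae_type))
  cat(sprintf("species (n >= %d): med.Cor = %.3f, med.MAE = %.3f\n",
              x$min_stratum_n, x$median_cor_species, x$median_mae_species))
  cat(sprintf("species-tissue:    med.Cor = %.3f, med.MAE = %.3f\n",
              x$median_cor_species_tissue, x$median_mae_species_tissue))
  invisible(x)
}

#' Per-species age estimation bias at half the maximum lifespan
#'
#' For each species, regresses the leave-one-species-out DNAm age estimates
#' on chronological age, evaluates the fitted line at half the species'
#' maximum lifespan, and reports the fitted value minus `0.5 * MaxLifespan`
#' (the default `method = "fit"`). `method = "mean"` instead reports the mean
#' per-sample discrepancy `mean(dnam_age - age)`. A species-blind clock
#' underestimates the age of long-lived species, making this quantity
#' negatively related to lifespan.
#'
#' @param predictions out-of-fold predictions with `species_id`, `age`,
#'   `dnam_age` (typically LOSO).
#' @param traits a [trait_table()] supplying `max_lifespan` per species.
#' @param method `"fit"` (default) or `"mean"`; see above.
#' @param min_n species with fewer samples (default 3) or zero age variance
#'   are excluded with a warning.
#' @return Data frame `species_id`, `n`, `delta_age` (years).
#' @export
delta_age <- function(predictions, traits, method = c("fit", "mean"),
                      min_n = 3) {
  method <- match.arg(method)
  stopifnot(inherits(traits, "trait_table"))
  parts <- split(predictions, predictions$species_id)
  skipped <- character(0)
  rows <- lapply(names(parts), function(sp) {
    d <- parts[[sp]]
    if (nrow(d) < min_n || stats::var(d$age) == 0) {
      skipped <<- c(skipped, sp)
      return(NULL)
    }
    L <- species_traits(traits, sp)$max_lifespan
    value <- if (method == "fit") {
      fit <- stats::lm(dnam_age ~ age, data = d)
      unname(stats::predict(fit, data.frame(age = 0.5 * L))) - 0.5 * L
    } else {
      mean(d$dnam_age - d$age)
    }
    data.frame(species_id = sp, n = nrow(d), delta_age = value,
               stringsAsFactors = FALSE)
  })
  if (length(skipped) > 0L) {
    warning("species excluded from Delta.Age (too few samples or no age ",
            "variance): ", paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species_id = character(0), n = integer(0),
                      delta_age = numeric(0))
  }
  rownames(out) <- NULL
  out
}
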