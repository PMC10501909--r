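# Per-stratum correlation EWAS of age, two-step Stouffer meta-analysis,
# age-group stratification, top-k selection and hypergeometric enrichment.

.z_cap <- 37

#' Convert a Pearson correlation to a signed Z statistic
#'
#' Computes the t statistic `r * sqrt((n - 2) / (1 - r^2))`, its two-sided p
#' value from the t distribution with `n - 2` degrees of freedom, and the
#' signed standard-normal quantile `sign(r) * qnorm(1 - p/2)`. This is the
#' conventional way of feeding correlation tests into Stouffer combination.
#' `|Z|` is capped at 37 (roughly the double-precision limit of the normal
#' quantile) so perfect correlations stay finite. Fisher's
#' `atanh(r) * sqrt(n - 3)` is available as `method = "fisher"`.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @param n sample size(s), at least 4; recycled against `r`.
#' @param method `"t"` (default) or `"fisher"`.
#' @return Signed Z value(s); antisymmetric in `r`.
#' @export
correlation_to_z <- function(r, n, method = c("t", "fisher")) {
  method <- match.arg(method)
  if (any(n < 4, na.rm = TRUE)) stop("n must be at least 4", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  z <- if (method == "fisher") {
    atanh(pmin(pmax(r, -1 + 1e-16), 1 - 1e-16)) * sqrt(n - 3)
  } else {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    # one-tailed log p keeps precision for huge |t|
    logp <- stats::pt(abs(tt), df = n - 2, lower.tail = FALSE,
                      log.p = TRUE)
    sign(r) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  }
  pmin(pmax(z, -.z_cap), .z_cap)
}

#' Unweighted Stouffer combination
#'
#' Combines signed Z statistics as `sum(z) / sqrt(k)`. Combining `k` copies
#' of the same `z` yields `z * sqrt(k)`.
#'
#' @param z_values numeric vector of finite Z statistics (at least one).
#' @return Combined Z.
#' @export
stouffer <- function(z_values) {
  if (length(z_values) == 0L) {
    stop("cannot combine an empty set of Z values", call. = FALSE)
  }
  if (any(!is.finite(z_values))) {
    stop("Z values must be finite", call. = FALSE)
  }
  sum(z_values) / sqrt(length(z_values))
}

#' Per-stratum correlation EWAS of age
#'
#' Splits the samples into (species, tissue) strata, drops strata below the
#' minimum size, and computes for every CpG in every retained stratum the
#' Pearson correlation between beta value and chronological age together
#' with its signed Z ([correlation_to_z()]). CpGs with zero variance within
#' a stratum get `Z = 0` and are flagged, never `NaN`.
#'
#' Small strata of one taxon can be merged before thresholding through a
#' pooling map (e.g. the many 1-3-sample lemur species pooled into one
#' strepsirrhine stratum per tissue, or all monotreme samples pooled across
#' species and tissues); the size threshold applies to the pooled strata.
#'
#' @param betas beta matrix (rows CpGs, columns samples).
#' @param samples sample sheet (`sample_id`, `species_id`, `tissue`, `age`).
#' @param min_n minimum stratum size; 15 for the primary eutherian analysis,
#'   conventionally relaxed to 10 for marsupials and for age-group splits.
#' @param pooling optional named character vector mapping species ids to
#'   pooled labels; unmapped species keep their own id.
#' @param pool_tissues_for labels (after pooling) whose tissues are merged
#'   into a single stratum (tissue set to `"all"`).
#' @return List of `stratum_result` records: each a list with `species`,
#'   `tissue`, `n`, named vectors `r` and `z`, and `constant` (logical flag
#'   of zero-variance CpGs).
#' @export
stratum_correlations <- function(betas, samples, min_n = 15, pooling = NULL,
                                 pool_tissues_for = character(0)) {
  al <- .align_samples(betas, samples)
  betas <- al$betas
  samples <- al$samples
  species <- samples$species_id
  if (!is.null(pooling)) {
    mapped <- !is.na(match(species, names(pooling)))
    species[mapped] <- unname(pooling[species[mapped]])
  }
  tissue <- samples$tissue
  tissue[species %in% pool_tissues_for] <- "all"

  key <- paste(species, tissue, sep = "\r")
  parts <- split(seq_len(nrow(samples)), key)
  out <- list()
  for (p in parts) {
    if (length(p) < min_n) next
    age <- samples$age[p]
    b <- betas[, p, drop = FALSE]
    n_eff <- rowSums(!is.na(b))
    suppressWarnings(r <- as.vector(stats::cor(t(b), age,
                                               use = "pairwise.complete.obs")))
    names(r) <- rownames(b)
    constant <- !is.finite(r)
    z <- numeric(length(r))
    ok <- !constant & n_eff >= 4
    z[ok] <- correlation_to_z(r[ok], n_eff[ok])
    names(z) <- rownames(b)
    out[[length(out) + 1L]] <- structure(
      list(species = species[p[1]], tissue = tissue[p[1]], n = length(p),
           r = r, z = z, constant = constant),
      class = "stratum_result")
  }
  out
}

#' Two-step cross-species meta-analysis of age EWAS
#'
#' Combines per-stratum Z statistics in two unweighted Stouffer steps that
#' correct for the dependency of multiple tissues sampled from the same
#' species: first the tissue strata of each species are combined into one
#' species-level Z per CpG, then the species-level Zs are combined across
#' species into the final Z. Species contributing a single stratum pass
#' through step one unchanged. A CpG missing from a stratum is simply
#' omitted from that stratum's combination.
#'
#' @param strata list of `stratum_result` records from
#'   [stratum_correlations()].
#' @return Data frame of class `ewas_result` with `cpg_id`, `n_strata`,
#'   `n_species`, `Z`, `p` (two-sided normal), `q` (Benjamini-Hochberg);
#'   the per-species Z matrix is attached as attribute `species_z`.
#' @export
two_step_meta <- function(strata) {
  stopifnot(length(strata) > 0L)
  cpgs <- sort(unique(unlist(lapply(strata, function(s) names(s$z)))))
  species <- unique(vapply(strata, `[[`, character(1), "species"))
  species_z <- matrix(NA_real_, nrow = length(cpgs), ncol = length(species),
                      dimnames = list(cpgs, species))
  n_strata <- stats::setNames(integer(length(cpgs)), cpgs)
  for (sp in species) {
    zs <- lapply(strata[vapply(strata, `[[`, character(1),
                               "species") == sp],
                 function(s) s$z)
    zmat <- matrix(NA_real_, nrow = length(cpgs), ncol = length(zs),
                   dimnames = list(cpgs, NULL))
    for (j in seq_along(zs)) zmat[names(zs[[j]]), j] <- zs[[j]]
    k <- rowSums(!is.na(zmat))
    n_strata <- n_strata + k
    has <- k > 0
    species_z[has, sp] <- rowSums(zmat[has, , drop = FALSE],
                                  na.rm = TRUE) / sqrt(k[has])
  }
  k_sp <- rowSums(!is.na(species_z))
  Z <- rowSums(species_z, na.rm = TRUE) / sqrt(pmax(k_sp, 1L))
  Z[k_sp == 0] <- NA_real_
  p <- 2 * stats::pnorm(-abs(Z))
  out <- data.frame(cpg_id = cpgs, n_strata = unname(n_strata),
                    n_species = k_sp, Z = unname(Z), p = unname(p),
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, species_z = species_z,
            class = c("ewas_result", "data.frame"))
}

#' One-step meta-analysis for a single tissue
#'
#' When every species contributes at most one stratum of the same tissue,
#' the dependency correction is unnecessary and the tissue-specific EWAS
#' results are simply combined across species in a single unweighted
#' Stouffer step. Equivalent to [two_step_meta()] in that case.
#'
#' @param strata list of `stratum_result` records sharing one tissue.
#' @return An `ewas_result` data frame (see [two_step_meta()]).
#' @export
single_tissue_meta <- function(strata) {
  stopifnot(length(strata) > 0L)
  tissues <- unique(vapply(strata, `[[`, character(1), "tissue"))
  if (length(tissues) != 1L) {
    stop("single_tissue_meta requires strata from one tissue, got: ",
         paste(tissues, collapse = ", "), call. = FALSE)
  }
  two_step_meta(strata)
}

#' Split a sample sheet into young / middle / old age groups
#'
#' Age groups are defined per species in multiples of the age at sexual
#' maturity: young is `age < 1.5 * ASM`, middle is
#' `1.5 * ASM <= age < 3.5 * ASM`, old is `age >= 3.5 * ASM`. The three
#' sheets partition the input.
#'
#' @param samples sample sheet with `species_id` and `age`.
#' @param traits a [trait_table()] resolving every sample's species.
#' @return Named list of sample sheets: `young`, `middle`, `old`.
#' @export
age_group_split <- function(samples, traits) {
  st <- .sample_traits(samples, traits)
  ratio <- samples$age / st$asm
  list(young = samples[ratio < 1.5, , drop = FALSE],
       middle = samples[ratio >= 1.5 & ratio < 3.5, , drop = FALSE],
       old = samples[ratio >= 3.5, , drop = FALSE])
}

#' Top age-related CpGs by meta-analysis Z
#'
#' Returns the `k` CpGs whose final Z has the requested sign, ordered by
#' `|Z|` descending with ties broken by lexicographic CpG id (deterministic
#' output). If fewer than `k` qualify, all are returned with a warning.
#'
#' @param result an `ewas_result` from [two_step_meta()].
#' @param k number of CpGs, default 1000.
#' @param direction `"positive"` (methylation gain with age) or
#'   `"negative"`.
#' @return Character vector of CpG ids.
#' @export
top_k_cpgs <- function(result, k = 1000,
                       direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  keep <- if (direction == "positive") result$Z > 0 else result$Z < 0
  keep[is.na(keep)] <- FALSE
  d <- result[keep, , drop = FALSE]
  d <- d[order(-abs(d$Z), d$cpg_id), , drop = FALSE]
  if (nrow(d) < k) {
    warning("only ", nrow(d), " CpGs with ", direction,
            " Z available (requested ", k, ")")
    k <- nrow(d)
  }
  d$cpg_id[seq_len(k)]
}

#' One-sided hypergeometric annotation enrichment
#'
#' Overlaps a foreground CpG set (e.g. the top 1,000 age-related CpGs) with
#' an annotation set against a background universe (e.g. all array CpGs),
#' building the 2x2 table `a = |fg & ann|`, `b = |fg \ ann|`,
#' `c = |ann \ fg|`, `d` the rest. Reports the odds ratio (with the Haldane
#' 0.5 correction only when a cell is zero) and one-sided hypergeometric
#' p values for enrichment (`P(X >= a)`) and depletion (`P(X <= a)`);
#' p values always come from the exact uncorrected table.
#'
#' @param foreground character vector of CpG ids, a subset of `background`.
#' @param annotation character vector of CpG ids (intersected with the
#'   background before testing).
#' @param background character vector: the CpG universe.
#' @return List of class `enrichment_result` with `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_enrichment`, `p_depletion` and the set sizes.
#' @export
hypergeometric_enrichment <- function(foreground, annotation, background) {
  background <- unique(background)
  foreground <- unique(foreground)
  annotation <- intersect(unique(annotation), background)
  outside <- setdiff(foreground, background)
  if (length(outside) > 0L) {
    stop("foreground CpGs outside the background universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ...", call. = FALSE)
  }
  N <- length(background)
  K <- length(annotation)
  n <- length(foreground)
  a <- length(intersect(foreground, annotation))
  b <- n - a
  cc <- K - a
  d <- N - K - b
  or <- if (a == 0 || b == 0 || cc == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  structure(list(
    a = a, b = b, c = cc, d = d,
    odds_ratio = or,
    p_enrichment = stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE),
    p_depletion = stats::phyper(a, K, N - K, n, lower.tail = TRUE),
    n_foreground = n, n_annotation = K, n_background = N),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("overlap %d/%d (annotation %d of %d): OR = %.3g, ",
              x$a, x$n_foreground, x$n_annotation, x$n_background,
              x$odds_ratio))
  cat(sprintf("p_enrich = %.3g, p_deplete = %.3g\n",
              x$p_enrichment, x$p_depletion))
  invisible(x)
}
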