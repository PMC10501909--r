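# Seeded generator of multi-species, multi-tissue methylomes with planted
# transformed-age signal; the validation surface for every other module.

#' Simulation design for synthetic methylomes
#'
#' Describes a multi-species, multi-tissue methylation study: how many
#' species and tissues, how many samples per species-tissue stratum, how
#' many CpGs, and how many of them carry a planted age signal. The defaults
#' describe the standard validation dataset: 20 species with allometrically
#' related life-history traits, 3 tissues each, 20 samples per stratum
#' (1,200 samples), 2,000 CpGs of which 100 gain and 100 lose methylation
#' with transformed age.
#'
#' The planted signal lives on the double-log relative-age scale (the
#' clock-2 outcome), so a relative-age clock is well specified while the
#' basic log-age clock is informatively misspecified across species - which
#' is what makes the lifespan-dependent bias of species-blind clocks
#' reproducible in simulation. Betas are generated on the logit scale
#' (baseline + slope * loglogAge + tissue effect + noise) and mapped through
#' the inverse logit, so they stay strictly inside (0, 1).
#'
#' @param n_species number of species (default 20).
#' @param tissues_per_species tissues per species (default 3).
#' @param samples_per_stratum samples per species-tissue stratum (default 20).
#' @param n_cpgs total CpGs (default 2000).
#' @param n_planted_pos CpGs gaining methylation with age (default 100).
#' @param n_planted_neg CpGs losing methylation with age (default 100).
#' @param signal_slope_range range of |slope| on the logit scale per unit of
#'   transformed age, default c(0.5, 1.5).
#' @param baseline_logit_mean,baseline_logit_sd per-CpG baseline logit
#'   distribution, default 0 and 1.5 (betas mostly within 0.05-0.95).
#' @param noise_sd residual logit-scale noise per observation, default 0.5.
#' @param tissue_effect_sd sd of per-CpG-per-tissue offsets, default 0.25.
#' @param trait_noise_sd sd of the log-scale noise on the allometric
#'   lifespan relation, default 0.5 (chosen so the two log trait variables
#'   correlate moderately, near 0.5, as across real mammals).
#' @param seed mandatory integer seed.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(n_species = 20, tissues_per_species = 3,
                       samples_per_stratum = 20, n_cpgs = 2000,
                       n_planted_pos = 100, n_planted_neg = 100,
                       signal_slope_range = c(0.5, 1.5),
                       baseline_logit_mean = 0, baseline_logit_sd = 1.5,
                       noise_sd = 0.5, tissue_effect_sd = 0.25,
                       trait_noise_sd = 0.5, seed = 1) {
  stopifnot(n_species >= 2, tissues_per_species >= 1,
            samples_per_stratum >= 1, n_cpgs >= 1,
            n_planted_pos >= 0, n_planted_neg >= 0,
            n_planted_pos + n_planted_neg <= n_cpgs,
            length(signal_slope_range) == 2L,
            signal_slope_range[1] > 0,
            diff(signal_slope_range) >= 0,
            noise_sd >= 0, tissue_effect_sd >= 0, trait_noise_sd >= 0,
            baseline_logit_sd >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(as.list(environment()), class = "sim_design")
}

# Deterministic sub-seeds so that, e.g., enlarging the CpG panel never
# perturbs the trait draws. Kept below 2^31.
.sub_seed <- function(seed, purpose) {
  (as.integer(seed) %% 1000000L) * 1000L +
    match(purpose, c("traits", "ages", "betas"))
}

#' Simulate an allometrically consistent species trait table
#'
#' Draws ASM log-uniformly between 0.1 and 10 years, gestation time as a
#' uniform 2-30% fraction of ASM, and maximum lifespan from the allometric
#' relation `log((L+G)/(ASM+G)) = 2.92 + 0.38 * log(G/ASM) + noise`
#' (log-normal noise of sd `trait_noise_sd`). With zero trait noise,
#' [fit_allometric_surrogate()] recovers intercept 2.92 and slope 0.38
#' exactly. Draws violating `MaxLifespan > ASM` are resampled (bounded
#' retries).
#'
#' @param design a [sim_design()] (only the trait-related fields are used).
#' @return An unadjusted [trait_table()] with empty exempt set.
#' @export
simulate_traits <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(.sub_seed(design$seed, "traits"))
  n <- design$n_species
  ids <- sprintf("sp%03d", seq_len(n))
  asm <- exp(stats::runif(n, log(0.1), log(10)))
  gest <- asm * stats::runif(n, 0.02, 0.3)
  lifespan <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (attempt in 1:100) {
    if (length(todo) == 0L) break
    eps <- stats::rnorm(length(todo), 0, design$trait_noise_sd)
    ratio <- exp(2.92 + 0.38 * log(gest[todo] / asm[todo]) + eps)
    L <- ratio * (asm[todo] + gest[todo]) - gest[todo]
    ok <- L > asm[todo]
    lifespan[todo[ok]] <- L[ok]
    todo <- todo[!ok]
  }
  if (length(todo) > 0L) {
    stop("failed to generate valid lifespans after 100 retries",
         call. = FALSE)
  }
  trait_table(data.frame(species_id = ids, max_lifespan = lifespan,
                         gestation_time = gest, asm = asm,
                         stringsAsFactors = FALSE),
              exempt = character(0))
}

#' Simulate a multi-species methylome with planted age signal
#'
#' Ages are drawn uniformly between 0 and 90% of each species' reported
#' maximum lifespan, covering early development to near end of life. Each
#' planted CpG `c` has `logit(beta) = b0_c + s_c * loglogAge + t_ct + noise`
#' with `loglogAge` the double-log relative age of the sample (computed with
#' adjusted lifespans), `s_c` drawn from the design's slope range (positive
#' set, mirrored negative for the loss set) and `t_ct` a per-CpG per-tissue
#' offset; null CpGs omit the slope term. Betas are the inverse logit, hence
#' strictly in (0, 1).
#'
#' @param traits a trait table from [simulate_traits()].
#' @param design the matching [sim_design()].
#' @return List with `betas` (CpG x sample matrix), `samples` (sample
#'   sheet), `truth` (data frame of planted `cpg_id`, `planted_sign`,
#'   `slope`) and `design`.
#' @export
simulate_methylomes <- function(traits, design) {
  stopifnot(inherits(design, "sim_design"), inherits(traits, "trait_table"),
            nrow(traits) == design$n_species)
  n_sp <- design$n_species
  n_ti <- design$tissues_per_species
  n_per <- design$samples_per_stratum
  n_samples <- n_sp * n_ti * n_per
  n_cpgs <- design$n_cpgs

  sp <- rep(traits$species_id, each = n_ti * n_per)
  ti <- rep(rep(sprintf("tissue%02d", seq_len(n_ti)), each = n_per),
            times = n_sp)
  set.seed(.sub_seed(design$seed, "ages"))
  L_rep <- traits$max_lifespan[match(sp, traits$species_id)]
  age <- stats::runif(n_samples, 0, 0.9 * L_rep)
  samples <- data.frame(sample_id = sprintf("s%05d", seq_len(n_samples)),
                        species_id = sp, tissue = ti, age = age,
                        stringsAsFactors = FALSE)

  adj <- adjust_max_lifespan(traits)
  loglog <- clock2_forward(age, .sample_traits(samples, adj))

  set.seed(.sub_seed(design$seed, "betas"))
  cpg_ids <- sprintf("cpg%05d", seq_len(n_cpgs))
  n_pos <- design$n_planted_pos
  n_neg <- design$n_planted_neg
  slope <- numeric(n_cpgs)
  if (n_pos > 0) {
    slope[seq_len(n_pos)] <- stats::runif(n_pos, design$signal_slope_range[1],
                                          design$signal_slope_range[2])
  }
  if (n_neg > 0) {
    slope[n_pos + seq_len(n_neg)] <-
      -stats::runif(n_neg, design$signal_slope_range[1],
                    design$signal_slope_range[2])
  }
  b0 <- stats::rnorm(n_cpgs, design$baseline_logit_mean,
                     design$baseline_logit_sd)
  tissues <- unique(ti)
  t_eff <- matrix(stats::rnorm(n_cpgs * length(tissues), 0,
                               design$tissue_effect_sd),
                  nrow = n_cpgs,
                  dimnames = list(cpg_ids, tissues))

  logit <- b0 + outer(slope, loglog) + t_eff[, match(ti, tissues)] +
    matrix(stats::rnorm(n_cpgs * n_samples, 0, design$noise_sd),
           nrow = n_cpgs)
  betas <- stats::plogis(logit)
  dimnames(betas) <- list(cpg_ids, samples$sample_id)

  planted <- slope != 0
  truth <- data.frame(cpg_id = cpg_ids[planted],
                      planted_sign = sign(slope[planted]),
                      slope = slope[planted],
                      stringsAsFactors = FALSE)
  list(betas = betas, samples = samples, truth = truth, design = design)
}

.fixture_designs <- function(seed = 1) {
  list(
    tiny = sim_design(n_species = 3, tissues_per_species = 2,
                      samples_per_stratum = 16, n_cpgs = 200,
                      n_planted_pos = 10, n_planted_neg = 10, seed = seed),
    default = sim_design(seed = seed),
    null = sim_design(n_species = 10, tissues_per_species = 2,
                      samples_per_stratum = 20, n_cpgs = 2000,
                      n_planted_pos = 0, n_planted_neg = 0, seed = seed)
  )
}

#' Generate a named fixture bundle on disk
#'
#' Writes the deterministic CSV bundle (`betas.csv`, `samples.csv`,
#' `traits.csv`, `truth.csv`) for one of three canonical designs: `tiny`
#' (3 species x 2 tissues x 16 samples, 200 CpGs, 10+10 planted; generates
#' in well under a second), `default` (the full validation design, see
#' [sim_design()]) and `null` (2,000 CpGs, no planted signal, for type-I
#' calibration). Identical name + seed gives identical bytes.
#'
#' @param name `"tiny"`, `"default"` or `"null"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed, default 1.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture <- function(name = c("tiny", "default", "null"),
                         dir = tempfile("fixture"), seed = 1) {
  name <- match.arg(name)
  design <- .fixture_designs(seed)[[name]]
  traits <- simulate_traits(design)
  sim <- simulate_methylomes(traits, design)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(betas = file.path(dir, "betas.csv"),
             samples = file.path(dir, "samples.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "truth.csv"))
  write_beta_matrix(sim$betas, paths[["betas"]])
  write_sample_sheet(sim$samples, paths[["samples"]])
  write_trait_table(traits, paths[["traits"]])
  .write_csv(sim$truth, paths[["truth"]])
  invisible(paths)
}
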