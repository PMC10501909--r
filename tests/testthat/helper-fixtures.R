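# Shared fixtures, built in code. Heavyweight simulations are memoized per
# test run.

toy_traits <- function(adjusted = FALSE, exempt = character(0)) {
  tt <- trait_table(data.frame(
    species_id = c("spA", "spB", "spC"),
    max_lifespan = c(20, 60, 5),
    gestation_time = c(0.25, 0.9, 0.07),
    asm = c(1, 8, 0.3),
    stringsAsFactors = FALSE), exempt = exempt)
  if (adjusted) tt <- adjust_max_lifespan(tt)
  tt
}

humanlike_traits <- function(adjusted = TRUE) {
  tt <- trait_table(data.frame(species_id = "humanlike",
                               max_lifespan = 122.5,
                               gestation_time = 0.75, asm = 13.5),
                    exempt = "humanlike")
  if (adjusted) tt <- adjust_max_lifespan(tt)  # exempt: values unchanged
  tt
}

example_anage <- function() {
  load_trait_table(system.file("extdata", "anage_example.csv",
                               package = "uniclock"))
}

# Small but informative simulated study: 6 species x 2 tissues x 15 samples,
# 300 CpGs with 30 + 30 planted.
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    design <- sim_design(n_species = 6, tissues_per_species = 2,
                         samples_per_stratum = 15, n_cpgs = 300,
                         n_planted_pos = 30, n_planted_neg = 30, seed = 42)
    traits <- simulate_traits(design)
    sim <- simulate_methylomes(traits, design)
    sim$traits <- traits
    sim$traits_adj <- adjust_max_lifespan(traits)
    .small_sim_cache$sim <- sim
  }
  .small_sim_cache$sim
}

random_trait_table <- function(n, seed) {
  design <- sim_design(n_species = max(n, 2), n_cpgs = 1,
                       n_planted_pos = 0, n_planted_neg = 0, seed = seed)
  simulate_traits(design)
}

# Rank (Mann-Whitney) AUC of scores for recovering a positive set.
rank_auc <- function(score, is_positive) {
  r <- rank(score)
  np <- sum(is_positive)
  nn <- sum(!is_positive)
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}
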