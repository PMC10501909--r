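# The full default-design validation study, shared by the heavier tests.
.heavy_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.heavy_cache$sim)) {
    design <- sim_design(seed = 1)
    traits <- simulate_traits(design)
    sim <- simulate_methylomes(traits, design)
    sim$traits <- traits
    sim$traits_adj <- adjust_max_lifespan(traits)
    .heavy_cache$sim <- sim
  }
  .heavy_cache$sim
}
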