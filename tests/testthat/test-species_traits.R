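test_that("a well-formed table loads as-is and invalid rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,max_lifespan,gestation_time,asm",
               "spA,20,0.25,1", "spB,60,0.9,8", "spC,5,0.07,0.3"), path)
  tt <- load_trait_table(path)
  expect_s3_class(tt, "trait_table")
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$max_lifespan, c(20, 60, 5))
  expect_false(attr(tt, "lifespan_adjusted"))

  writeLines(c("species_id,max_lifespan,gestation_time,asm",
               "spA,20,0.25,1", "spBad,3,0.1,7"), path)
  expect_error(load_trait_table(path), "spBad")

  writeLines(c("species_id,max_lifespan,gestation_time,asm",
               "spA,20,0.25,1", "spA,30,0.3,2"), path)
  expect_error(load_trait_table(path), "duplicate.*spA")

  writeLines(c("species_id,max_lifespan,asm", "spA,20,1"), path)
  expect_error(load_trait_table(path), "gestation_time")
})

test_that("lifespan adjustment multiplies non-exempt species exactly once", {
  tt <- trait_table(data.frame(species_id = c("human", "house mouse", "spX"),
                               max_lifespan = c(122.5, 4, 24),
                               gestation_time = c(0.75, 0.052, 0.5),
                               asm = c(13.5, 0.13, 2)))
  adj <- adjust_max_lifespan(tt)
  expect_identical(adj$max_lifespan[1:2], c(122.5, 4))
  expect_equal(adj$max_lifespan[3], 31.2)
  expect_true(attr(adj, "lifespan_adjusted"))
  expect_error(adjust_max_lifespan(adj), "already")

  # order-insensitive and exactly multiplicative
  perm <- tt[c(3, 1, 2), ]
  attr(perm, "exempt") <- attr(tt, "exempt")
  attr(perm, "lifespan_adjusted") <- FALSE
  class(perm) <- class(tt)
  adj2 <- adjust_max_lifespan(perm)
  for (sp in tt$species_id) {
    expect_equal(adj2$max_lifespan[adj2$species_id == sp],
                 adj$max_lifespan[adj$species_id == sp], tolerance = 1e-12)
  }
  expect_equal(adj$max_lifespan[3] / tt$max_lifespan[3], 1.3,
               tolerance = 1e-12)
})

test_that("log-lifespan ratios anchor at the reference and are base-invariant", {
  tt <- example_anage()
  ratios <- log_lifespan_ratio(tt, "bowhead whale")
  expect_identical(unname(ratios["bowhead whale"]), 1)
  expect_equal(round(unname(ratios["human"]), 2), 0.90)

  synth <- trait_table(data.frame(species_id = c("ref", "half"),
                                  max_lifespan = c(exp(4), exp(2)),
                                  gestation_time = c(0.5, 0.5),
                                  asm = c(2, 1)))
  expect_equal(unname(log_lifespan_ratio(synth, "ref")["half"]), 0.5)
  # monotone in lifespan
  expect_true(all(diff(ratios[order(tt$max_lifespan)]) > 0))
  # base invariance
  expect_equal(unname(ratios), log10(tt$max_lifespan) / log10(211))

  shortref <- trait_table(data.frame(species_id = "tiny", max_lifespan = 0.9,
                                     gestation_time = 0.05, asm = 0.2))
  expect_error(log_lifespan_ratio(shortref, "tiny"), "exceed 1 year")
})

test_that("allometric surrogate fit matches the normal-equations oracle", {
  # exact generative recovery with zero noise
  d0 <- sim_design(n_species = 40, n_cpgs = 1, n_planted_pos = 0,
                   n_planted_neg = 0, trait_noise_sd = 0, seed = 7)
  tt0 <- simulate_traits(d0)
  fit0 <- fit_allometric_surrogate(tt0)
  expect_equal(fit0$intercept, 2.92, tolerance = 1e-10)
  expect_equal(fit0$slope, 0.38, tolerance = 1e-10)

  # brute-force normal equations on a small noisy table
  tt <- random_trait_table(8, seed = 5)
  fit <- fit_allometric_surrogate(tt)
  x <- log(tt$gestation_time / tt$asm)
  y <- log((tt$max_lifespan + tt$gestation_time) /
             (tt$asm + tt$gestation_time))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, as.numeric(beta[1, 1]), tolerance = 1e-10)
  expect_equal(fit$slope, as.numeric(beta[2, 1]), tolerance = 1e-10)
  expect_equal(fit$correlation, cor(x, y), tolerance = 1e-12)

  # two species: exact interpolation, |r| = 1
  fit2 <- fit_allometric_surrogate(tt[1:2, ])
  expect_equal(abs(fit2$correlation), 1, tolerance = 1e-12)
  expect_equal(fit2$intercept + fit2$slope * x[1], y[1], tolerance = 1e-10)

  degen <- trait_table(data.frame(species_id = c("a", "b", "c"),
                                  max_lifespan = c(10, 20, 30),
                                  gestation_time = c(0.2, 0.2, 0.2),
                                  asm = c(1, 1, 1)))
  expect_error(fit_allometric_surrogate(degen), "zero variance")
})

test_that("Monte-Carlo slope recovery stays near 0.38 at moderate noise", {
  d <- sim_design(n_species = 500, n_cpgs = 1, n_planted_pos = 0,
                  n_planted_neg = 0, trait_noise_sd = 0.2, seed = 11)
  fit <- fit_allometric_surrogate(simulate_traits(d))
  expect_lt(abs(fit$slope - 0.38), 0.03)
})

test_that("change-point surrogate m_hat behaves as the allometric power law", {
  eq <- trait_table(data.frame(species_id = "eq", max_lifespan = 30,
                               gestation_time = 0.5, asm = 0.5))
  expect_equal(unname(estimate_m_hat(eq)), 5.0)
  frac <- trait_table(data.frame(species_id = "f", max_lifespan = 30,
                                 gestation_time = 0.1, asm = 1.0))
  expect_equal(unname(estimate_m_hat(frac)), 5 * 0.1^0.38, tolerance = 1e-12)
  expect_equal(round(unname(estimate_m_hat(frac)), 4), 2.0843)
  expect_equal(unname(estimate_m_hat(frac, c2 = 1, exponent = 0)), 1.0)

  # strictly increasing in gestation, decreasing in asm
  g <- seq(0.05, 1, length.out = 20)
  mk <- function(gest, asm) trait_table(data.frame(
    species_id = sprintf("s%02d", seq_along(gest)), max_lifespan = 100,
    gestation_time = gest, asm = asm))
  expect_true(all(diff(estimate_m_hat(mk(g, 1))) > 0))
  expect_true(all(diff(estimate_m_hat(mk(rep(0.2, 20),
                                         seq(0.5, 5, length.out = 20)))) < 0))
})
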