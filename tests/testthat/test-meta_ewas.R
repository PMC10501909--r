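test_that("correlation-to-Z conversion matches the t/normal oracle", {
  expect_equal(correlation_to_z(0, 10), 0)
  # independent oracle: explicit t statistic and CDF composition
  r <- 0.5; n <- 15
  t_oracle <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t_oracle, 2.0817, tolerance = 1e-4)
  z_oracle <- qnorm(1 - 2 * pt(-abs(t_oracle), df = n - 2) / 2)
  expect_equal(correlation_to_z(r, n), z_oracle, tolerance = 1e-10)
  expect_lt(abs(correlation_to_z(r, n) - 1.90), 0.01)

  # antisymmetry, exact
  for (rr in c(0.1, 0.5, 0.99)) {
    expect_identical(correlation_to_z(-rr, 20), -correlation_to_z(rr, 20))
  }
  # perfect correlation capped, not infinite
  expect_equal(correlation_to_z(1, 10), 37)
  expect_equal(correlation_to_z(-1, 10), -37)
  expect_error(correlation_to_z(0.5, 3), "at least 4")
  expect_error(correlation_to_z(1.5, 10), "\\[-1, 1\\]")

  # Fisher alternative
  expect_equal(correlation_to_z(0.5, 12, method = "fisher"),
               atanh(0.5) * 3, tolerance = 1e-12)
})

test_that("Stouffer combination obeys its closed forms", {
  expect_equal(stouffer(1.7), 1.7)
  expect_equal(stouffer(c(1.96, 1.96)), 3.92 / sqrt(2))
  expect_equal(round(stouffer(c(1.96, 1.96)), 4), 2.7719)
  expect_equal(stouffer(c(1.5, -1.5)), 0)
  for (k in c(2, 5, 9)) {
    expect_equal(stouffer(rep(0.8, k)), 0.8 * sqrt(k), tolerance = 1e-12)
  }
  expect_error(stouffer(numeric(0)), "empty")
  expect_error(stouffer(c(1, Inf)), "finite")
})

make_stratum <- function(species, tissue, z, n = 20) {
  structure(list(species = species, tissue = tissue, n = n, r = z * 0,
                 z = z, constant = rep(FALSE, length(z))),
            class = "stratum_result")
}

test_that("two-step meta-analysis corrects tissue dependency within species", {
  z1 <- c(cpgA = 2); z2 <- c(cpgA = 2); z3 <- c(cpgA = 0)
  strata <- list(make_stratum("A", "blood", z1),
                 make_stratum("A", "liver", z2),
                 make_stratum("B", "blood", z3))
  res <- two_step_meta(strata)
  expect_equal(res$Z, (2 * sqrt(2) + 0) / sqrt(2))
  expect_equal(res$Z, 2.0)
  expect_equal(res$n_species, 2L)
  expect_equal(res$n_strata, 3L)
  sz <- attr(res, "species_z")
  expect_equal(unname(sz["cpgA", "A"]), 2 * sqrt(2))

  # one-step pooling of the same strata is a different (wrong) answer
  expect_equal(stouffer(c(2, 2, 0)), 4 / sqrt(3))
  expect_false(isTRUE(all.equal(res$Z, 4 / sqrt(3))))

  # single species, single stratum: pass-through
  solo <- two_step_meta(list(make_stratum("A", "blood", c(cpgA = 1.3))))
  expect_equal(solo$Z, 1.3)
  expect_equal(solo$p, 2 * pnorm(-1.3))

  # invariant to stratum ordering
  res2 <- two_step_meta(strata[c(3, 1, 2)])
  expect_equal(res2$Z, res$Z)

  # CpG absent from one stratum is omitted from that combination only
  z4 <- c(cpgA = 1, cpgB = 2)
  res3 <- two_step_meta(list(make_stratum("A", "blood", z4),
                             make_stratum("A", "liver", c(cpgA = 1))))
  expect_equal(res3$Z[res3$cpg_id == "cpgA"], 2 / sqrt(2))
  expect_equal(res3$Z[res3$cpg_id == "cpgB"], 2)
})

test_that("single-tissue meta is one-step Stouffer across species", {
  strata <- list(make_stratum("A", "cortex", c(x = 1)),
                 make_stratum("B", "cortex", c(x = 1)),
                 make_stratum("C", "cortex", c(x = 1)))
  res <- single_tissue_meta(strata)
  expect_equal(res$Z, sqrt(3), tolerance = 1e-12)
  # reduces to two_step_meta when each species has one stratum
  expect_equal(res$Z, two_step_meta(strata)$Z)
  expect_error(single_tissue_meta(list(make_stratum("A", "cortex", c(x = 1)),
                                       make_stratum("A", "liver", c(x = 1)))),
               "one tissue")
})

test_that("stratum correlations respect thresholds, pooling and constant CpGs", {
  set.seed(12)
  n <- 16
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:(n + 14)),
    species_id = c(rep("big", n), rep("small", 14)),
    tissue = "blood",
    age = c(seq(1, 16, length.out = n), runif(14, 1, 10)))
  betas <- rbind(
    linear = (samples$age - min(samples$age)) /
      diff(range(samples$age)),
    constant = rep(0.4, nrow(samples)),
    noise = runif(nrow(samples)))
  colnames(betas) <- samples$sample_id

  strata <- stratum_correlations(betas, samples, min_n = 15)
  expect_length(strata, 1L)  # the 14-sample stratum is dropped
  s <- strata[[1]]
  expect_equal(s$species, "big")
  expect_equal(s$n, n)
  expect_equal(unname(s$r["linear"]), 1, tolerance = 1e-12)
  expect_equal(unname(s$z["linear"]), 37)
  expect_true(s$constant[["constant"]])
  expect_equal(unname(s$z["constant"]), 0)

  # pooling two 8-sample strata of one taxon lets it pass the threshold
  samples2 <- data.frame(
    sample_id = sprintf("t%02d", 1:16),
    species_id = rep(c("lemur1", "lemur2"), each = 8),
    tissue = "blood", age = rep(seq(1, 8), 2))
  betas2 <- matrix(runif(32), nrow = 2,
                   dimnames = list(c("c1", "c2"), samples2$sample_id))
  expect_length(stratum_correlations(betas2, samples2, min_n = 15), 0L)
  pooled <- stratum_correlations(
    betas2, samples2, min_n = 15,
    pooling = c(lemur1 = "strepsirrhine", lemur2 = "strepsirrhine"))
  expect_length(pooled, 1L)
  expect_equal(pooled[[1]]$species, "strepsirrhine")
  expect_equal(pooled[[1]]$n, 16)

  # monotreme-style pooling across species AND tissues
  samples3 <- samples2
  samples3$tissue <- rep(c("blood", "liver"), 8)
  mono <- stratum_correlations(
    betas2, samples3, min_n = 15,
    pooling = c(lemur1 = "monotremes", lemur2 = "monotremes"),
    pool_tissues_for = "monotremes")
  expect_length(mono, 1L)
  expect_equal(mono[[1]]$tissue, "all")
  expect_equal(mono[[1]]$n, 16)
})

test_that("age-group split partitions at 1.5 and 3.5 ASM", {
  traits <- trait_table(data.frame(species_id = "x", max_lifespan = 30,
                                   gestation_time = 0.25, asm = 1))
  samples <- data.frame(sample_id = sprintf("s%d", 1:5), species_id = "x",
                        tissue = "blood", age = c(1.0, 1.5, 2.0, 3.5, 4.0))
  g <- age_group_split(samples, traits)
  expect_equal(g$young$sample_id, "s1")
  expect_equal(g$middle$sample_id, c("s2", "s3"))  # 1.5*ASM is middle
  expect_equal(g$old$sample_id, c("s4", "s5"))     # 3.5*ASM is old
  expect_setequal(c(g$young$sample_id, g$middle$sample_id,
                    g$old$sample_id), samples$sample_id)
})

test_that("top-k selection is sign-filtered, |Z|-ordered and deterministic", {
  res <- data.frame(cpg_id = c("cg_b", "cg_a", "cg_c", "cg_d"),
                    Z = c(3, -5, 2, 3))
  expect_equal(top_k_cpgs(res, k = 1, direction = "positive"), "cg_b")
  expect_equal(top_k_cpgs(res, k = 3, direction = "positive"),
               c("cg_b", "cg_d", "cg_c"))  # tie 3 vs 3: lexicographic
  expect_equal(top_k_cpgs(res, k = 1, direction = "negative"), "cg_a")
  expect_warning(all_pos <- top_k_cpgs(res, k = 10), "only 3")
  expect_length(all_pos, 3L)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  bg <- sprintf("cg%03d", 1:100)
  ann <- bg[1:20]
  fg <- c(bg[1:8], bg[90:91])  # a = 8 of n = 10
  e <- hypergeometric_enrichment(fg, ann, bg)
  expect_equal(c(e$a, e$b, e$c, e$d), c(8, 2, 12, 78))
  expect_equal(e$odds_ratio, (8 * 78) / (2 * 12))
  expect_equal(e$odds_ratio, 26.0)
  # brute-force enumeration oracle
  p_brute <- sum(vapply(8:10, function(i) {
    choose(20, i) * choose(80, 10 - i) / choose(100, 10)
  }, numeric(1)))
  expect_equal(e$p_enrichment, p_brute, tolerance = 1e-12)
  p_dep_brute <- sum(vapply(0:8, function(i) {
    choose(20, i) * choose(80, 10 - i) / choose(100, 10)
  }, numeric(1)))
  expect_equal(e$p_depletion, p_dep_brute, tolerance = 1e-12)

  # Haldane correction only on zero cells
  e0 <- hypergeometric_enrichment(bg[21:30], ann, bg)
  expect_equal(e0$a, 0)
  expect_equal(e0$odds_ratio, (0.5 * 70.5) / (10.5 * 20.5))

  expect_error(hypergeometric_enrichment(c(bg[1], "outsider"), ann, bg),
               "outside")
})

test_that("enrichment p values are calibrated under a null foreground", {
  set.seed(33)
  bg <- sprintf("cg%04d", 1:1000)
  ann <- bg[1:200]
  reps <- replicate(200, {
    fg <- sample(bg, 100)
    e <- hypergeometric_enrichment(fg, ann, bg)
    c(p = e$p_enrichment, a = e$a)
  })
  # the exact test is discrete, hence super-uniform: never anti-conservative
  for (t in c(0.01, 0.05, 0.2, 0.5)) {
    expect_lt(mean(reps["p", ] < t), t + 2 * sqrt(t * (1 - t) / 200))
  }
  # the mid-p correction removes the lattice atoms and is near-uniform
  mid <- reps["p", ] - 0.5 * dhyper(reps["a", ], 200, 800, 100)
  expect_gt(suppressWarnings(ks.test(mid, "punif")$p.value), 0.01)
})
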