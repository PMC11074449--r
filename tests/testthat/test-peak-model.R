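test_that("degradation factor follows the 90 bp anchored power law", {
  expect_equal(degradation_factor(90, 0.3), 1)
  expect_equal(degradation_factor(190, 0.5), 0.5)
  expect_equal(degradation_factor(290, 0.8), 0.64)
  expect_error(degradation_factor(100, 0), "\\(0, 1\\]")
  expect_error(degradation_factor(-5, 0.5), "positive")
})

test_that("noiseless log-linear profiles recover the degradation slope exactly", {
  kit <- tiny_kit()
  # homozygous loci: one peak each, so log(mean height) is exactly linear in size
  ref <- toy_reference(list(L1 = "10", L2 = "8", L3 = "11"))
  ev <- noiseless_evidence(ref, mu = 2000, slope = 0.996, kit = kit)
  fit <- fit_degradation(ev, kit)
  expect_equal(fit$per_base_slope, 0.996, tolerance = 1e-6)
  expect_true(fit$include_degradation)
  expect_equal(fit$epsilon, 0.996^100, tolerance = 1e-4)
  # constant heights: slope 1, degradation excluded
  flat <- noiseless_evidence(ref, mu = 2000, slope = 1, kit = kit)
  fit0 <- fit_degradation(flat, kit)
  expect_equal(fit0$per_base_slope, 1)
  expect_equal(fit0$p_deg, 0)
  expect_false(fit0$include_degradation)
  expect_error(fit_degradation(ev[ev$locus == "L1", ], kit), "3 loci")
})

test_that("simulated ski-slope profiles recover the per-base slope", {
  # heterozygous references so locus dosage is uniform; omega = 0.2 noise
  kit <- default_kit()
  slopes <- purrr::map_dbl(1:4, function(i) {
    freqs <- simulate_frequency_table(sim_config(seed = 500 + i))
    ref <- purrr::map_dfr(unique(freqs$locus), function(l) {
      top <- dplyr::slice_max(freqs[freqs$locus == l, ], frequency, n = 2,
                              with_ties = FALSE)
      tibble::tibble(sample_id = "H", locus = l, allele = top$allele)
    }) |> as_str_profile(kind = "reference")
    cfg <- sim_config(seed = 600 + i, mxn = 1, phi = 0, per_base_slope = 0.996,
                      omega = 0.2)
    ev <- simulate_tumor_profile(ref, freqs, cfg)
    fit_degradation(ev, kit)$p_deg
  })
  # each single-profile estimate is noisy (21 loci); the estimator is
  # unbiased enough that the replicate mean lands within 20%
  expect_lt(abs(mean(slopes) - 0.004) / 0.004, 0.2)
  expect_true(all(abs(slopes - 0.004) / 0.004 < 0.5))
})

test_that("allele shapes add dosage, weights and degradation into the gamma shape", {
  kit <- tiny_kit()
  p <- gamma_params(mu = 1000, omega = 0.2, epsilon = 1, mxn = 1, K = 2)
  het <- list(normal = genotype("10", "12"), subclones = list(genotype("10", "12")))
  sh <- allele_shapes(het, gamma_params(1000, 0.2, 1, mxn = 0.5, K = 2), kit, "L1")
  expect_equal(unname(sh), rep(1 / 0.04, 2))              # weights sum over shared alleles
  hom <- list(normal = genotype("10"), subclones = list(genotype("10")))
  sh2 <- allele_shapes(hom, p, kit, "L1")
  expect_equal(unname(sh2["10"]), 2 / 0.04)               # two copies in the normal pop
  # two populations sharing one allele copy each at weights .6/.4
  sh3 <- allele_shapes(list(normal = genotype("10", "12"),
                            subclones = list(genotype("10", "13"))),
                       gamma_params(1000, 0.2, 1, mxn = 0.6, K = 2), kit, "L1")
  expect_equal(unname(sh3["10"]), (0.6 + 0.4) / 0.04)
  expect_equal(unname(sh3["13"]), 0.4 / 0.04)
  # epsilon = 1 makes shapes independent of fragment size
  far <- allele_shapes(het, gamma_params(1000, 0.2, 1, 0.5, K = 2), kit, "L3")
  expect_equal(unname(far), unname(sh))
  # LOSS contributes nothing; with the normal population at weight 0 and a
  # total-loss subclone, no allele has a positive expected contribution
  none <- allele_shapes(list(normal = genotype("10", "12"),
                             subclones = list(genotype("LOSS", "LOSS"))),
                        gamma_params(1000, 0.2, 1, 0, K = 2), kit, "L1")
  expect_length(none, 2)
  expect_true(all(none == 0))
})

test_that("locus likelihood multiplies gamma densities and dropout factors", {
  kit <- tiny_kit()
  p <- gamma_params(mu = 1000, omega = 0.25, epsilon = 1, mxn = 1, K = 2)
  combo <- list(normal = genotype("10", "12"), subclones = list(genotype("10", "12")))
  obs <- tibble::tibble(allele = c("10", "12"), height = c(950, 1100),
                        size = unname(allele_size(kit, "L1", c("10", "12"))))
  val <- locus_likelihood(obs, combo, p, at = 175, kit = kit, locus = "L1")
  scale <- 1000 * 0.25^2
  expect_equal(val, dgamma(950, 1 / 0.25^2, scale = scale) *
                 dgamma(1100, 1 / 0.25^2, scale = scale), tolerance = 1e-12)
  # observed allele the combination cannot produce: exactly zero (no drop-in)
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(allele = "13", height = 800,
                                               size = unname(allele_size(kit, "L1", "13"))))
  expect_identical(locus_likelihood(obs2, combo, p, 175, kit, "L1"), 0)
  # no expected alleles and no observed peaks: empty product = 1
  total_loss <- list(normal = genotype("10", "12"),
                     subclones = list(genotype("LOSS", "LOSS")))
  p0 <- gamma_params(1000, 0.25, 1, mxn = 0, K = 2)
  expect_equal(locus_likelihood(obs[0, ], total_loss, p0, 175, kit, "L1"), 1)
  # dropout factor for an unobserved expected allele
  one <- obs[1, ]
  v <- locus_likelihood(one, combo, p, 175, kit, "L1")
  expect_equal(v, dgamma(950, 1 / 0.25^2, scale = scale) *
                 pgamma(175, 1 / 0.25^2, scale = scale), tolerance = 1e-12)
  # peak ordering does not matter
  expect_equal(locus_likelihood(obs[2:1, ], combo, p, 175, kit, "L1"), val)
})

test_that("dropout factors are monotone in the analytical threshold", {
  kit <- tiny_kit()
  p <- gamma_params(1000, 0.25, 1, mxn = 1, K = 2)
  combo <- list(normal = genotype("10", "12"), subclones = list(genotype("10", "12")))
  obs <- tibble::tibble(allele = "10", height = 950,
                        size = unname(allele_size(kit, "L1", "10")))
  ats <- c(100, 175, 300, 600)
  vals <- purrr::map_dbl(ats, ~ locus_likelihood(obs, combo, p, .x, kit, "L1"))
  expect_true(all(diff(vals) >= 0))  # CDF factor grows with AT
})

test_that("profile log-likelihood equals the hand-computed two-combination toy", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  ev <- toy_evidence(tibble::tibble(locus = "L2", allele = c("8", "9.3"),
                                    height = c(1200, 900)))
  poi <- toy_reference(list(L2 = c("8", "9.3")))
  vi <- variant_incidence(0.1, loss_fraction = 0.5)
  hyp <- hypothesis("HP", K = 2, poi = poi, mxn = 0.5, phi = vi)
  p <- gamma_params(mu = 1100, omega = 0.3, epsilon = 1, mxn = 0.5, K = 2)
  enum <- enumerate_combinations(c("8", "9.3"), "L2", hyp, freqs)
  manual <- sum(purrr::map_dbl(seq_len(nrow(enum)), function(i) {
    combo <- list(normal = enum$normal[[i]], subclones = enum$subclones[[i]])
    enum$prior[i] * locus_likelihood(ev[, c("allele", "height", "size")], combo,
                                     p, 175, kit, "L2")
  }))
  expect_equal(profile_log_likelihood(ev, hyp, p, freqs, kit),
               log(manual), tolerance = 1e-9)
})

test_that("loci are independent: the log-likelihood adds across loci", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  vi <- variant_incidence(0.15)
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = c("8", "8")))
  p <- gamma_params(1000, 0.25, 1, mxn = 0.4, K = 2)
  e1 <- toy_evidence(tibble::tibble(locus = "L1", allele = c("10", "12"),
                                    height = c(900, 1000)))
  e2 <- toy_evidence(tibble::tibble(locus = "L2", allele = "8", height = 2100))
  e12 <- toy_evidence(tibble::tibble(locus = c("L1", "L1", "L2"),
                                     allele = c("10", "12", "8"),
                                     height = c(900, 1000, 2100)))
  ll <- function(e) {
    hyp <- hypothesis("HP", K = 2, poi = poi, mxn = 0.4, phi = vi)
    profile_log_likelihood(e, hyp, p, freqs, kit)
  }
  expect_equal(ll(e12), ll(e1) + ll(e2), tolerance = 1e-10)
})

test_that("merging identical populations preserves the likelihood (gamma additivity)", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  poi <- toy_reference(list(L1 = c("10", "12")))
  ev <- toy_evidence(tibble::tibble(locus = "L1", allele = c("10", "12"),
                                    height = c(900, 1000)))
  vi <- variant_incidence(0)   # subclones forced identical to the normal
  p3 <- gamma_params(1000, 0.25, 1, mxn = 0.4, subclone_weights = c(0.35, 0.25))
  p2 <- gamma_params(1000, 0.25, 1, mxn = 0.4, subclone_weights = 0.6)
  h3 <- hypothesis("HP", K = 3, poi = poi, mxn = 0.4, phi = vi)
  h2 <- hypothesis("HP", K = 2, poi = poi, mxn = 0.4, phi = vi)
  expect_equal(profile_log_likelihood(ev, h3, p3, freqs, kit),
               profile_log_likelihood(ev, h2, p2, freqs, kit), tolerance = 1e-12)
})

test_that("the vectorized likelihood context agrees with the reference path", {
  # same model through two implementations: flattened context vs the
  # readable per-locus loop
  freqs <- tiny_freqs()
  kit <- tiny_kit()
  vi <- variant_incidence(0.2, loss_fraction = 0.3)
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = c("8", "9.3"), L3 = "13"))
  ev <- toy_evidence(tibble::tibble(
    locus = c("L1", "L1", "L1", "L2", "L3"),
    allele = c("10", "12", "13", "8", "13"),
    height = c(900, 1000, 400, 1800, 2000)))
  p <- gamma_params(950, 0.3, 0.85, mxn = 0.45, K = 2)
  for (kind in c("HP", "HD_UNRELATED", "HD_PO", "HD_FS")) {
    hyp <- hypothesis(kind, K = 2, poi = poi, mxn = 0.45, phi = vi)
    fast <- profile_log_likelihood(ev, hyp, p, freqs, kit, by_locus = TRUE)
    slow <- purrr::map_dbl(c("L1", "L2", "L3"), function(l) {
      obs <- tibble::as_tibble(ev)[ev$locus == l, c("allele", "height", "size")]
      enum <- enumerate_combinations(obs$allele, l, hyp, freqs)
      log(sum(purrr::map_dbl(seq_len(nrow(enum)), function(i)
        enum$prior[i] * locus_likelihood(obs, list(normal = enum$normal[[i]],
                                                   subclones = enum$subclones[[i]]),
                                         p, 175, kit, l))))
    })
    expect_equal(unname(fast[c("L1", "L2", "L3")]), slow, tolerance = 1e-9,
                 label = kind)
  }
})
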