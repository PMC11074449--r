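make_small_case <- function(seed, mxn = 0.4, n_loci = 8, ...) {
  cfg <- sim_config(seed = seed, mxn = mxn, n_loci = n_loci, ...)
  freqs <- simulate_frequency_table(cfg)
  ref <- sample_reference_profile(freqs, seed = derive2(seed), "POI")
  ev <- simulate_tumor_profile(ref, freqs, cfg)
  list(cfg = cfg, freqs = freqs, ref = ref, ev = ev)
}
derive2 <- function(seed) seed * 131 + 7

test_that("likelihood maximization is deterministic in the seed", {
  cs <- make_small_case(7)
  hyp <- hypothesis("HP", K = 2, poi = cs$ref, mxn = 0.4, phi = cs$cfg$phi)
  f1 <- maximize_likelihood(cs$ev, hyp, cs$freqs, seed = 11)
  f2 <- maximize_likelihood(cs$ev, hyp, cs$freqs, seed = 11)
  expect_identical(f1$logL, f2$logL)
  expect_identical(f1$params$mu, f2$params$mu)
})

test_that("nuisance parameters are recovered from single-source simulations", {
  cfg <- sim_config(seed = 41, n_loci = 21, mu = 1000, omega = 0.15,
                    per_base_slope = 1, mxn = 1, phi = 0)
  freqs <- simulate_frequency_table(cfg)
  ref <- sample_reference_profile(freqs, seed = 42, "P")
  ev <- simulate_tumor_profile(ref, freqs, cfg)
  hyp <- hypothesis("HP", K = 2, poi = ref, mxn = 1, phi = cfg$phi)
  fit <- maximize_likelihood(ev, hyp, freqs, seed = 5)
  expect_lt(abs(fit$params$mu - 1000) / 1000, 0.05)
  expect_lt(abs(fit$params$omega - 0.15) / 0.15, 0.20)
})

test_that("phi = 0 with identical populations collapses to the single-source model", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = "8", L3 = c("11", "14")))
  ev <- toy_evidence(tibble::tibble(
    locus = c("L1", "L1", "L2", "L3", "L3"),
    allele = c("10", "12", "8", "11", "14"),
    height = c(900, 1050, 2200, 980, 1010)))
  hyp <- hypothesis("HP", K = 2, poi = poi, mxn = 0.35, phi = variant_incidence(0))
  p <- gamma_params(1000, 0.22, 0.9, mxn = 0.35, K = 2)
  expect_equal(profile_log_likelihood(ev, hyp, p, freqs, kit),
               oracle_single_source_loglik(ev, poi, 1000, 0.22, 0.9, 175, kit),
               tolerance = 1e-10)
})

test_that("full-profile likelihood equals the brute-force oracle on 2-locus toys", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = c("8", "9.3")))
  ev <- toy_evidence(tibble::tibble(
    locus = c("L1", "L1", "L1", "L2"),
    allele = c("10", "12", "13", "8"),
    height = c(900, 1050, 300, 2200)))
  for (kind in c("HP", "HD_UNRELATED")) {
    for (mxn in c(0.3, 0.7)) {
      hyp <- hypothesis(kind, K = 2, poi = poi, mxn = mxn,
                        phi = variant_incidence(0.18, loss_fraction = 0.45))
      p <- gamma_params(1050, 0.28, 0.88, mxn = mxn, K = 2)
      got <- profile_log_likelihood(ev, hyp, p, freqs, kit)
      want <- oracle_profile_loglik(ev, poi, kind, mxn, 0.18, 0.45, freqs, kit,
                                    175, 1050, 0.28, 0.88)
      expect_equal(got, want, tolerance = 1e-6 * abs(want),
                   label = paste(kind, mxn))
    }
  }
})

test_that("optimized log-likelihoods agree with an independently optimized oracle", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = c("8", "9.3")))
  ev <- toy_evidence(tibble::tibble(
    locus = c("L1", "L1", "L2"), allele = c("10", "12", "8"),
    height = c(950, 1020, 2050)))
  vi <- variant_incidence(0.2, loss_fraction = 0.5)
  for (kind in c("HP", "HD_UNRELATED")) {
    hyp <- hypothesis(kind, K = 2, poi = poi, mxn = 0.4, phi = vi)
    fit <- maximize_likelihood(ev, hyp, freqs, kit = kit, seed = 3,
                               degfit = structure(list(include_degradation = FALSE,
                                                       epsilon = 1),
                                                  class = "tlr_degfit"))
    # oracle maximizes the brute-force likelihood over (mu, omega) itself
    oracle_best <- optim(c(log(1000), 0.3), function(p) {
      -oracle_profile_loglik(ev, poi, kind, 0.4, 0.2, 0.5, freqs, kit, 175,
                             exp(p[1]), p[2], 1)
    }, method = "L-BFGS-B",
    lower = c(log(17.5), 0.05), upper = c(log(1e5), 1.5))
    expect_lt(abs(fit$logL - (-oracle_best$value)), 1e-3, label = kind)
  }
})

test_that("noiseless single-source evidence reaches the random-match-probability limit", {
  kit <- tiny_kit()
  freqs <- tiny_freqs()
  poi <- toy_reference(list(L1 = c("10", "12"), L2 = c("8", "9.3"), L3 = "13"))
  ev <- noiseless_evidence(poi, mu = 1500, slope = 1, kit = kit)
  lr <- compute_lr(ev, poi, freqs, mxn = 1, phi = 0, kit = kit, K = 2)
  rmp <- sum(purrr::map_dbl(c("L1", "L2", "L3"), function(l) {
    g <- reference_genotype(poi, l)
    f <- allele_frequency(freqs, l, unique(g))
    -log10(if (g[1] == g[2]) f[[1]]^2 else 2 * f[[1]] * f[[2]])
  }))
  expect_equal(lr$log10_lr, rmp, tolerance = 0.02)
  # per-locus decomposition sums to the total
  expect_equal(sum(tidy(lr)$log10_lr), lr$log10_lr, tolerance = 1e-6)
})

test_that("a person of interest sharing no alleles is strongly excluded", {
  cs <- make_small_case(31)
  stranger_rows <- purrr::map_dfr(unique(cs$freqs$locus), function(l)
    tibble::tibble(sample_id = "S", locus = l, allele = "99"))
  stranger <- as_str_profile(stranger_rows, kind = "reference")
  lr <- compute_lr(cs$ev, stranger, cs$freqs, mxn = 0.4, phi = cs$cfg$phi)
  expect_lt(lr$log10_lr, 0)
})

test_that("interval LR is linear in the normal-cell fraction for a true contributor", {
  cs <- make_small_case(43, mxn = 0.5)
  iv <- interval_lr(cs$ev, cs$ref, cs$freqs, mxn_center = 0.5, n = 7,
                    phi_table = default_phi())
  expect_equal(nrow(iv$values), 7)
  expect_true(all(iv$values$log10_lr > 0))
  expect_equal(iv$mean, mean(iv$values$log10_lr))
  g <- glance(iv)
  expect_gte(g$pearson_r^2, 0.9)
  expect_gt(g$slope_mxn, 0)
})

test_that("the non-contributor test is deterministic and caches nothing incorrectly", {
  cs <- make_small_case(57, n_loci = 6)
  nc1 <- non_contributor_test(cs$ev, cs$freqs, mxn_center = 0.4,
                              phi = cs$cfg$phi, per_group = 3, seed = 9)
  nc2 <- non_contributor_test(cs$ev, cs$freqs, mxn_center = 0.4,
                              phi = cs$cfg$phi, per_group = 3, seed = 9)
  expect_identical(nc1$values$log10_lr, nc2$values$log10_lr)
  expect_equal(nrow(nc1$values), 15)
  expect_equal(length(unique(nc1$values$mxn)), 5)
  # the true contributor outranks every non-contributor
  lr_true <- compute_lr(cs$ev, cs$ref, cs$freqs, mxn = 0.4, phi = cs$cfg$phi)
  expect_gt(lr_true$log10_lr, max(nc1$values$log10_lr))
})

test_that("gamma MLE diagnostic recovers simulated locus totals", {
  totals <- withr::with_seed(77, rgamma(200, shape = 4, scale = 500))
  ev <- as_str_profile(tibble::tibble(
    sample_id = "D", locus = sprintf("L%03d", 1:200), allele = "10",
    height = totals), kind = "evidence")
  qq <- gamma_qq_diagnostic(ev)
  expect_lt(abs(qq$shape - 4) / 4, 0.15)
  expect_equal(nrow(qq$qq), 200)
  # scale equivariance: scaling heights scales the gamma scale, not the shape
  ev2 <- dplyr::mutate(ev, height = height * 3)
  qq2 <- gamma_qq_diagnostic(as_str_profile(ev2, kind = "evidence"))
  expect_equal(qq2$shape, qq$shape, tolerance = 1e-6)
  expect_equal(qq2$scale, qq$scale * 3, tolerance = 1e-6)
  expect_error(gamma_qq_diagnostic(ev[1:5, ]), "10 loci")
  flat <- as_str_profile(tibble::tibble(sample_id = "D",
                                        locus = sprintf("L%03d", 1:12),
                                        allele = "10", height = 100),
                         kind = "evidence")
  expect_error(gamma_qq_diagnostic(flat), "degenerate")
})

test_that("grid experiment returns consistent shapes and axis fits", {
  cs <- make_small_case(63, n_loci = 5)
  g <- grid_experiment(cs$ev, cs$ref, cs$freqs, mxn_center = 0.4, n = 3,
                       phi_range = c(0.1, 0.3))
  expect_equal(dim(g$log10_lr), c(3, 3))
  expect_true(all(is.finite(g$log10_lr)))
  expect_equal(nrow(g$fits), 6)
  td <- tidy(g)
  expect_equal(nrow(td), 9)
  expect_equal(td$log10_lr[td$mxn == g$mxn_grid[2] & td$phi == g$phi_grid[3]],
               g$log10_lr[2, 3])
})
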