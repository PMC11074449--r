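#' Maximize the profile likelihood over nuisance parameters
#'
#' The a priori parameters (`mxn`, `phi`) stay fixed; `mu`, `omega`, the
#' degradation factor `epsilon` (when the log-linear pre-fit indicates
#' degradation) and, for `K > 2`, the subclone weight split are maximized by
#' bounded optimization (`log(mu)` in `[log(at / 10), log(1e5)]`, `omega` in
#' `[0.05, 1.5]`, `epsilon` in `[0.1, 1]`). Five seeded starts are scored and
#' the best two polished with L-BFGS-B; results are deterministic in `seed`.
#'
#' @param E Evidence profile tibble.
#' @param hyp A `tlr_hypothesis`.
#' @param freqs Frequency table.
#' @param kit Kit map.
#' @param at Analytical threshold (RFU).
#' @param seed Integer seed for the start sequence.
#' @param n_starts Number of seeded starts (default 5).
#' @param n_polish How many of the best starts to polish (default 2).
#' @param degfit Optional precomputed [fit_degradation()] result.
#' @return List with `params` (a `tlr_params`), `logL`, `convergence` and
#'   `include_degradation`.
#' @export
maximize_likelihood <- function(E, hyp, freqs, kit = default_kit(), at = 175,
                                seed = 1, n_starts = 5, n_polish = 2,
                                degfit = NULL) {
  ctx <- build_likelihood_context(E, hyp, freqs, kit, at)
  degfit <- degfit %||% fit_degradation(E, kit)
  optimize_context(ctx, E, hyp, degfit, seed = seed, n_starts = n_starts,
                   n_polish = n_polish)
}

# Parameter vector layout: (log mu, omega, [epsilon], [K-2 logit sticks]).
optimize_context <- function(ctx, E, hyp, degfit, seed = 1, n_starts = 5,
                             n_polish = 2) {
  K <- hyp$K
  mxn <- hyp$mxn
  include_deg <- degfit$include_degradation
  n_sticks <- max(0, K - 2)
  lower <- c(log(ctx$at / 10), 0.05, if (include_deg) 0.1, rep(-8, n_sticks))
  upper <- c(log(1e5), 1.5, if (include_deg) 1, rep(8, n_sticks))

  unpack <- function(p) {
    mu <- exp(p[1]); omega <- p[2]
    epsilon <- if (include_deg) p[3] else 1
    sticks <- if (n_sticks > 0) p[(length(p) - n_sticks + 1):length(p)] else numeric(0)
    w <- stick_weights(sticks, 1 - mxn, K - 1)
    list(mu = mu, omega = omega, epsilon = epsilon, weights = c(mxn, w))
  }
  objective <- function(p) {
    q <- unpack(p)
    ll <- eval_context(ctx, q$mu, q$omega, q$epsilon, q$weights)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  # informed start: mu from the median locus total height at dosage ~2
  tot <- if (nrow(E) > 0) {
    stats::aggregate(E$height, list(E$locus), sum)$x
  } else ctx$at * 10
  mu0 <- min(max(median(tot) / 2, exp(lower[1]) * 1.01), exp(upper[1]) * 0.99)
  start0 <- c(log(mu0), 0.3, if (include_deg) degfit$epsilon, rep(0, n_sticks))
  start0 <- pmin(pmax(start0, lower), upper)
  starts <- list(start0)
  if (n_starts > 1) {
    rand <- withr::with_seed(seed, matrix(runif((n_starts - 1) * length(lower)),
                                          ncol = length(lower)))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- lower + rand[i, ] * (upper - lower)
    }
  }
  scores <- vapply(starts, objective, numeric(1))
  ord <- order(scores)
  best <- NULL
  for (i in head(ord, max(1, n_polish))) {
    fit <- tryCatch(
      optim(starts[[i]], objective, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 300, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    j <- ord[1]
    best <- list(par = starts[[j]], value = scores[j], convergence = 52L)
    if (!is.finite(-best$value) || best$value >= 1e12) {
      # likelihood is identically zero (e.g. unexplainable observed alleles)
      q <- unpack(starts[[j]])
      return(list(params = do.call(make_params, q), logL = -Inf,
                  convergence = 52L, include_degradation = include_deg))
    }
  }
  q <- unpack(best$par)
  logL <- -best$value
  if (best$value >= 1e12) logL <- -Inf
  list(params = make_params(q$mu, q$omega, q$epsilon, q$weights),
       logL = logL, convergence = best$convergence %||% 0L,
       include_degradation = include_deg)
}

make_params <- function(mu, omega, epsilon, weights) {
  gamma_params(mu, omega, epsilon, mxn = weights[1],
               subclone_weights = weights[-1])
}

# Map K-2 unbounded sticks to K-1 weights summing to `total`.
stick_weights <- function(sticks, total, n) {
  if (n == 1) return(total)
  w <- numeric(n); rem <- 1
  for (j in seq_len(n - 1)) {
    frac <- stats::plogis(sticks[j])
    w[j] <- rem * frac
    rem <- rem - w[j]
  }
  w[n] <- rem
  w * total
}

#' Likelihood ratio for a tumor profile against a person of interest
#'
#' Maximizes the likelihood independently under `Hp` (tumor from the person
#' of interest) and the chosen `Hd` (unrelated individual, parent/offspring,
#' or full sibling) and returns `log10 LR` with a per-locus decomposition at
#' the fitted parameters.
#'
#' @param E Evidence profile tibble.
#' @param poi Reference profile tibble of the person of interest.
#' @param freqs Frequency table.
#' @param mxn Normal-cell fraction in `[0,1]`.
#' @param phi Variant incidence ([variant_incidence()] input).
#' @param hd `"unrelated"`, `"po"` or `"fs"`.
#' @param kit Kit map.
#' @param K Number of cell populations; default [estimate_min_contributors()].
#' @param at Analytical threshold (RFU).
#' @param loss_fraction Loss/replacement split of a variant event.
#' @param seed Optimizer seed.
#' @param n_starts,n_polish Optimizer start policy.
#' @return An object of class `tlr_lr`: `log10_lr`, `per_locus` tibble,
#'   `hp_fit`, `hd_fit`, `noc`, `hypotheses`.
#' @export
compute_lr <- function(E, poi, freqs, mxn, phi, hd = c("unrelated", "po", "fs"),
                       kit = default_kit(), K = NULL, at = 175,
                       loss_fraction = 0.5, seed = 1, n_starts = 5, n_polish = 2) {
  hd <- match.arg(hd)
  E <- apply_analytical_threshold(E, at)
  K <- K %||% estimate_min_contributors(E)
  vi <- if (inherits(phi, "tlr_phi")) phi else variant_incidence(phi, loss_fraction)
  hyp_p <- hypothesis("HP", K = K, poi = poi, mxn = mxn, phi = vi)
  hd_kind <- switch(hd, unrelated = "HD_UNRELATED", po = "HD_PO", fs = "HD_FS")
  hyp_d <- hypothesis(hd_kind, K = K, poi = poi, mxn = mxn, phi = vi)
  degfit <- fit_degradation(E, kit)

  fit_p <- maximize_likelihood(E, hyp_p, freqs, kit, at, seed = seed,
                               n_starts = n_starts, n_polish = n_polish, degfit = degfit)
  fit_d <- maximize_likelihood(E, hyp_d, freqs, kit, at, seed = seed,
                               n_starts = n_starts, n_polish = n_polish, degfit = degfit)
  finish_lr(E, hyp_p, hyp_d, fit_p, fit_d, freqs, kit, at, hd)
}

finish_lr <- function(E, hyp_p, hyp_d, fit_p, fit_d, freqs, kit, at, hd) {
  pl_p <- suppressWarnings(profile_log_likelihood(E, hyp_p, fit_p$params, freqs, kit, at,
                                                  by_locus = TRUE))
  pl_d <- suppressWarnings(profile_log_likelihood(E, hyp_d, fit_d$params, freqs, kit, at,
                                                  by_locus = TRUE))
  loci <- names(pl_p)
  per_locus <- tibble(locus = loci,
                      log10_lr = (pl_p - pl_d[loci]) * log10e)
  structure(list(
    log10_lr = (fit_p$logL - fit_d$logL) * log10e,
    per_locus = per_locus,
    hp_fit = fit_p, hd_fit = fit_d,
    noc = hyp_p$K, mxn = hyp_p$mxn,
    hypotheses = c(hp = "HP", hd = switch(hd, unrelated = "HD_UNRELATED",
                                          po = "HD_PO", fs = "HD_FS"))
  ), class = "tlr_lr")
}

#' @export
print.tlr_lr <- function(x, ...) {
  cat("Tumor-source likelihood ratio (", x$hypotheses["hp"], " vs ",
      x$hypotheses["hd"], ")\n", sep = "")
  cat("  log10(LR) =", format(x$log10_lr, digits = 6),
      " [K =", x$noc, ", Mxn =", x$mxn, "]\n")
  cat("  Hp logL =", format(x$hp_fit$logL, digits = 8),
      "; Hd logL =", format(x$hd_fit$logL, digits = 8), "\n")
  invisible(x)
}

#' Sensitivity grid of log10(LR) over the a priori parameters
#'
#' Recomputes the LR on an `n x n` grid: the normal-cell fraction over the
#' confidence interval `mxn_center +/- 0.10` (clipped to `[0.01, 0.99]`) and
#' a single phi applied to all loci over `phi_range`. Least-squares lines of
#' `log10 LR` on each axis (the other fixed) summarize the dependence.
#'
#' @inheritParams compute_lr
#' @param mxn_center Center of the normal-cell-fraction interval.
#' @param phi_range Range of variant incidence (default the colorectal range
#'   `[0.0775, 0.4341]`).
#' @param n Grid points per axis (default 21).
#' @return An object of class `tlr_grid`: `mxn_grid`, `phi_grid`, `log10_lr`
#'   matrix (`mxn` by `phi`), and `fits` (per-line slope, intercept, Pearson r).
#' @export
grid_experiment <- function(E, poi, freqs, mxn_center,
                            phi_range = c(0.0775, 0.4341), n = 21,
                            hd = "unrelated", kit = default_kit(), K = NULL,
                            at = 175, loss_fraction = 0.5, seed = 1,
                            n_starts = 5, n_polish = 2) {
  mxn_grid <- mxn_interval(mxn_center, n)
  phi_grid <- seq(phi_range[1], phi_range[2], length.out = n)
  m <- matrix(NA_real_, nrow = n, ncol = n,
              dimnames = list(signif(mxn_grid, 6), signif(phi_grid, 6)))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      lr <- tryCatch(
        compute_lr(E, poi, freqs, mxn = mxn_grid[i], phi = phi_grid[j], hd = hd,
                   kit = kit, K = K, at = at, loss_fraction = loss_fraction,
                   seed = seed, n_starts = n_starts, n_polish = n_polish),
        error = function(e) NULL)
      if (!is.null(lr)) m[i, j] <- lr$log10_lr
    }
  }
  fits <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n), function(j) line_fit(mxn_grid, m[, j], "mxn", phi_grid[j])),
    purrr::map_dfr(seq_len(n), function(i) line_fit(phi_grid, m[i, ], "phi", mxn_grid[i]))
  )
  structure(list(mxn_grid = mxn_grid, phi_grid = phi_grid, log10_lr = m,
                 fits = fits),
            class = "tlr_grid")
}

mxn_interval <- function(center, n = 21) {
  lo <- max(0.01, center - 0.10)
  hi <- min(0.99, center + 0.10)
  seq(lo, hi, length.out = n)
}

line_fit <- function(x, y, axis, fixed_at) {
  ok <- is.finite(y)
  if (sum(ok) < 3) {
    return(tibble(axis = axis, fixed_at = fixed_at, slope = NA_real_,
                  intercept = NA_real_, pearson_r = NA_real_))
  }
  fit <- lm(y[ok] ~ x[ok])
  tibble(axis = axis, fixed_at = fixed_at,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         pearson_r = suppressWarnings(cor(x[ok], y[ok])))
}

#' Interval LR: log10(LR) across the Mxn confidence interval
#'
#' Recomputes the LR at `n` equally spaced normal-cell fractions in
#' `mxn_center +/- 0.10` while phi takes the per-locus incidences from
#' `phi_table` (loci absent from the table get the mean incidence). The
#' min/mean/max across the interval is the conservative "LR interval value".
#'
#' @inheritParams compute_lr
#' @param mxn_center Center of the normal-cell-fraction interval.
#' @param phi_table Per-locus incidence table (`locus`, `phi`), named vector,
#'   or `tlr_phi`; default [default_phi()].
#' @param n Number of interval points (default 21).
#' @return An object of class `tlr_interval`: `values` tibble (`mxn`,
#'   `log10_lr`) plus `min`, `mean`, `max`.
#' @export
interval_lr <- function(E, poi, freqs, mxn_center, phi_table = default_phi(),
                        n = 21, hd = "unrelated", kit = default_kit(), K = NULL,
                        at = 175, loss_fraction = 0.5, seed = 1, n_starts = 5,
                        n_polish = 2) {
  vi <- if (inherits(phi_table, "tlr_phi")) phi_table else
    variant_incidence(phi_table, loss_fraction)
  mxn_grid <- mxn_interval(mxn_center, n)
  vals <- purrr::map_dbl(mxn_grid, function(mx) {
    compute_lr(E, poi, freqs, mxn = mx, phi = vi, hd = hd, kit = kit, K = K,
               at = at, seed = seed, n_starts = n_starts,
               n_polish = n_polish)$log10_lr
  })
  structure(list(values = tibble(mxn = mxn_grid, log10_lr = vals),
                 min = min(vals), mean = mean(vals), max = max(vals)),
            class = "tlr_interval")
}

#' Non-contributor (Hd-true) test
#'
#' Scores randomly generated unrelated individuals as the person of interest
#' to verify LR specificity. The normal-cell-fraction interval
#' `mxn_center +/- 0.10` is split into five groups (its minimum, quartiles
#' and maximum); each group scores `per_group` random profiles drawn from
#' the frequency table. The Hd denominator depends only on the evidence and
#' the parameter setting, so it is fitted once per group and reused.
#'
#' @inheritParams compute_lr
#' @param mxn_center Center of the normal-cell-fraction interval.
#' @param per_group Non-contributors per Mxn group (default 200; the study
#'   design is 5 x 200 = 1000 individuals).
#' @param seed Seed for the individual panel and the optimizer.
#' @return An object of class `tlr_noncontrib`: `values` tibble (`group`,
#'   `mxn`, `poi_id`, `log10_lr`), `fraction_negative`, and per-group boxplot
#'   statistics.
#' @export
non_contributor_test <- function(E, freqs, mxn_center, phi,
                                 per_group = 200, kit = default_kit(), K = NULL,
                                 at = 175, loss_fraction = 0.5, seed = 1,
                                 n_starts = 5, n_polish = 1) {
  E <- apply_analytical_threshold(E, at)
  K <- K %||% estimate_min_contributors(E)
  vi <- if (inherits(phi, "tlr_phi")) phi else variant_incidence(phi, loss_fraction)
  iv <- mxn_interval(mxn_center, 21)
  group_mxn <- unname(quantile(iv, c(0, 0.25, 0.5, 0.75, 1)))
  degfit <- fit_degradation(E, kit)

  rows <- purrr::map_dfr(seq_along(group_mxn), function(g) {
    mx <- group_mxn[g]
    hyp_d <- hypothesis("HD_UNRELATED", K = K, mxn = mx, phi = vi)
    ctx_d <- build_likelihood_context(E, hyp_d, freqs, kit, at)
    fit_d <- optimize_context(ctx_d, E, hyp_d, degfit, seed = seed,
                              n_starts = n_starts, n_polish = max(2, n_polish))
    purrr::map_dfr(seq_len(per_group), function(i) {
      id <- (g - 1) * per_group + i
      poi <- sample_reference_profile(freqs, seed = derive_seed(seed, id),
                                      sample_id = paste0("NC", id))
      hyp_p <- hypothesis("HP", K = K, poi = poi, mxn = mx, phi = vi)
      ctx_p <- build_likelihood_context(E, hyp_p, freqs, kit, at)
      fit_p <- optimize_context(ctx_p, E, hyp_p, degfit,
                                seed = derive_seed(seed, id),
                                n_starts = n_starts, n_polish = n_polish)
      tibble(group = g, mxn = mx, poi_id = paste0("NC", id),
             log10_lr = (fit_p$logL - fit_d$logL) * log10e)
    })
  })
  box <- rows |>
    dplyr::group_by(.data$group, .data$mxn) |>
    dplyr::summarise(
      min = min(.data$log10_lr), q1 = quantile(.data$log10_lr, 0.25),
      median = median(.data$log10_lr), q3 = quantile(.data$log10_lr, 0.75),
      max = max(.data$log10_lr),
      fraction_negative = mean(.data$log10_lr < 0), .groups = "drop")
  structure(list(values = rows,
                 fraction_negative = mean(rows$log10_lr < 0),
                 by_group = box, group_mxn = group_mxn),
            class = "tlr_noncontrib")
}

#' Gamma goodness-of-fit diagnostic for locus total peak heights
#'
#' Fits a gamma distribution to the per-locus total peak heights by maximum
#' likelihood and returns theoretical-vs-empirical quantile pairs for a Q-Q
#' plot (points along `y = x` support the gamma peak-height assumption).
#'
#' @param E Evidence profile tibble with at least 10 loci carrying peaks.
#' @return An object of class `tlr_qq`: `shape`, `rate`, `scale`, and a
#'   `qq` tibble (`theoretical`, `empirical`, one row per locus).
#' @export
gamma_qq_diagnostic <- function(E) {
  totals <- E |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(total = sum(.data$height)) |>
    dplyr::pull(.data$total)
  if (length(totals) < 10) abort("gamma Q-Q diagnostic needs at least 10 loci with peaks")
  if (sd(totals) == 0) abort("degenerate peak heights: all locus totals equal")
  # fit on mean-normalized totals for numerical stability; the gamma shape is
  # scale-invariant and the rate rescales exactly
  m <- mean(totals)
  # fitdistr's BFGS may probe negative parameters and emit NaN warnings
  fit <- suppressWarnings(MASS::fitdistr(totals / m, "gamma"))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"]) / m
  emp <- sort(totals)
  theo <- qgamma(ppoints(length(emp)), shape = shape, rate = rate)
  structure(list(shape = shape, rate = rate, scale = 1 / rate,
                 qq = tibble(theoretical = theo, empirical = emp)),
            class = "tlr_qq")
}
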