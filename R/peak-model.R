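#' Gamma peak-height model parameters
#'
#' The peak height contributed by one allele copy at mixture weight 1 in an
#' undegraded template follows `gamma(1 / omega^2, scale = mu * omega^2)`:
#' `mu` is the expected height (RFU) and `omega` its coefficient of
#' variation. Contributions of cell populations add in the gamma shape
#' (shared scale), weighted by the mixture weights: the normal-cell fraction
#' `mxn` plus `K - 1` subclone weights summing to `1 - mxn`. `epsilon` is the
#' degradation factor per 100 bp.
#'
#' @param mu Expected height of one allele copy at weight 1 (RFU), `> 0`.
#' @param omega Coefficient of variation, `> 0`.
#' @param epsilon Degradation factor per 100 bp in `(0, 1]`; 1 disables
#'   degradation.
#' @param mxn Normal-cell fraction in `[0, 1]`.
#' @param subclone_weights Numeric vector of `K - 1` subclone weights summing
#'   to `1 - mxn`; default: equal split.
#' @param K Number of cell populations (used only when `subclone_weights` is
#'   `NULL`).
#' @return An object of class `tlr_params`.
#' @export
gamma_params <- function(mu, omega, epsilon = 1, mxn, subclone_weights = NULL, K = 2) {
  if (mu <= 0) abort("`mu` must be positive")
  if (omega <= 0) abort("`omega` must be positive")
  if (epsilon <= 0 || epsilon > 1) abort("`epsilon` must lie in (0, 1]")
  if (mxn < 0 || mxn > 1) abort("`mxn` must lie in [0,1]")
  if (is.null(subclone_weights)) subclone_weights <- rep((1 - mxn) / (K - 1), K - 1)
  if (any(subclone_weights < 0)) abort("subclone weights must be non-negative")
  if (abs(sum(subclone_weights) - (1 - mxn)) > 1e-9) {
    abort("subclone weights must sum to 1 - mxn")
  }
  structure(list(mu = mu, omega = omega, epsilon = epsilon,
                 weights = c(mxn, subclone_weights)),
            class = "tlr_params")
}

#' Degradation scaling factor
#'
#' `epsilon^((size - 90) / 100)`: the expected-height multiplier for a
#' fragment of the given size, relative to a 90 bp fragment.
#'
#' @param size Fragment size in bp, `> 0`.
#' @param epsilon Degradation factor per 100 bp in `(0, 1]`.
#' @return Factor in `(0, 1]` for sizes `>= 90`.
#' @export
degradation_factor <- function(size, epsilon) {
  if (any(epsilon <= 0) || any(epsilon > 1)) abort("`epsilon` must lie in (0, 1]")
  if (any(size <= 0)) abort("`size` must be positive")
  epsilon^((size - 90) / 100)
}

#' Fit the log-linear degradation model
#'
#' Ordinary least squares of `log(mean locus peak height)` on mean locus
#' fragment size, the "ski-slope" diagnostic for FFPE degradation. The
#' per-base slope is `exp(fitted slope)` (capped at 1), interpretable as the
#' probability of no strand breakage between two adjacent bases;
#' `p_deg = 1 - per_base_slope`. Degradation is included in the likelihood
#' when `p_deg > 1e-4`, with the gamma-model factor initialized as
#' `epsilon = per_base_slope^100`.
#'
#' @param profile Evidence profile tibble.
#' @param kit Kit map (used when peak sizes are missing).
#' @return An object of class `tlr_degfit` with fields `per_base_slope`,
#'   `p_deg`, `intercept`, `include_degradation`, `epsilon` and the per-locus
#'   fit data.
#' @export
fit_degradation <- function(profile, kit = default_kit()) {
  dat <- profile |>
    dplyr::mutate(size = ifelse(is.finite(.data$size), .data$size,
                                purrr::map2_dbl(.data$locus, .data$allele,
                                                ~ allele_size(kit, .x, .y)))) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(mean_height = mean(.data$height),
                     mean_size = mean(.data$size), .groups = "drop")
  if (nrow(dat) < 3) abort("degradation fit needs at least 3 loci with observed peaks")
  fit <- lm(log(mean_height) ~ mean_size, data = dat)
  slope <- unname(coef(fit)[2])
  per_base_slope <- min(1, exp(slope))
  p_deg <- 1 - per_base_slope
  structure(list(per_base_slope = per_base_slope,
                 p_deg = p_deg,
                 intercept = unname(coef(fit)[1]),
                 include_degradation = p_deg > 1e-4,
                 epsilon = max(0.1, per_base_slope^100),
                 data = dat),
            class = "tlr_degfit")
}

#' Expected-contribution gamma shapes per allele
#'
#' `shape(a) = (1 / omega^2) * sum_pop w_pop * n_{a,pop} *
#' degradation_factor(size(a), epsilon)` with `n_{a,pop}` the copy count of
#' allele `a` in population `pop` (the normal population first, then the
#' subclones). `LOSS` contributes nothing. All alleles share the scale
#' `mu * omega^2`, so population contributions add in the shape.
#'
#' @param combo List with `normal` (length-2 genotype) and `subclones` (list
#'   of length-2 genotypes).
#' @param params A `tlr_params`.
#' @param kit Kit map for fragment sizes.
#' @param locus Locus name.
#' @param sizes Optional named vector of fragment sizes overriding the kit
#'   (used for observed peak sizes and for `Q`).
#' @param q_size Size assigned to `Q` (default: mean of `sizes`, else the
#'   mean kit size of the kit's 10-20 repeat range).
#' @return Named numeric vector of shapes over the combination's alleles.
#' @export
allele_shapes <- function(combo, params, kit, locus, sizes = NULL, q_size = NULL) {
  pops <- c(list(combo$normal), combo$subclones)
  stopifnot(length(pops) == length(params$weights))
  alleles <- setdiff(unique(unlist(pops)), ALLELE_LOSS)
  if (length(alleles) == 0) return(setNames(numeric(0), character(0)))
  sz <- purrr::map_dbl(alleles, function(a) {
    if (!is.null(sizes) && a %in% names(sizes) && is.finite(sizes[[a]])) return(sizes[[a]])
    if (a == ALLELE_Q) {
      if (!is.null(q_size)) return(q_size)
      if (!is.null(sizes) && length(sizes) > 0) return(mean(sizes, na.rm = TRUE))
      return(unname(allele_size(kit, locus, "15")))
    }
    unname(allele_size(kit, locus, a))
  })
  deg <- degradation_factor(sz, params$epsilon)
  copies <- vapply(seq_along(pops), function(p)
    vapply(alleles, function(a) sum(pops[[p]] == a), numeric(1)), numeric(length(alleles)))
  copies <- matrix(copies, nrow = length(alleles))
  dosage <- drop(copies %*% params$weights)
  setNames(dosage * deg / params$omega^2, alleles)
}

#' Likelihood of one locus' peak data under one genotype combination
#'
#' Product over observed alleles of the gamma density of their heights, times
#' the dropout factor `pgamma(at, shape, scale)` for every allele the
#' combination expects but the profile does not show. An observed allele the
#' combination cannot produce (shape 0) gives density exactly 0 (drop-in is
#' not modeled).
#'
#' @param obs Tibble with columns `allele`, `height`, `size` (peaks at the
#'   locus; zero rows for total dropout).
#' @param combo List with `normal` and `subclones` genotypes.
#' @param params A `tlr_params`.
#' @param at Analytical threshold (RFU).
#' @param kit Kit map.
#' @param locus Locus name.
#' @return Non-negative density.
#' @export
locus_likelihood <- function(obs, combo, params, at = 175, kit = default_kit(),
                             locus) {
  sizes <- setNames(obs$size, obs$allele)
  q_size <- if (nrow(obs) > 0) mean(obs$size, na.rm = TRUE) else NULL
  shapes <- allele_shapes(combo, params, kit, locus, sizes = sizes, q_size = q_size)
  scale <- params$mu * params$omega^2
  dens <- 1
  for (i in seq_len(nrow(obs))) {
    a <- obs$allele[i]
    sh <- if (a %in% names(shapes)) shapes[[a]] else 0
    if (sh <= 0) return(0)
    dens <- dens * dgamma(obs$height[i], shape = sh, scale = scale)
  }
  unobserved <- setdiff(names(shapes)[shapes > 0], obs$allele)
  for (a in unobserved) {
    dens <- dens * pgamma(at, shape = shapes[[a]], scale = scale)
  }
  dens
}

# ---------------------------------------------------------------------------
# Fast likelihood context: flattens the per-locus enumeration into vectors so
# one likelihood evaluation is a handful of vectorized calls. Used by the LR
# engine's optimizer; locus_likelihood() above is the readable reference path.

build_likelihood_context <- function(E, hyp, freqs, kit, at = 175) {
  loci <- intersect(profile_loci(E), unique(freqs$locus))
  if (length(loci) == 0) abort("no locus shared between evidence and frequency table")
  floor <- attr(freqs, "floor") %||% 0.005
  ev_locus <- split(seq_len(nrow(E)), factor(E$locus, levels = loci))
  fq_locus <- split(seq_len(nrow(freqs)), freqs$locus)
  kit_idx <- match(loci, kit$locus)
  if (anyNA(kit_idx)) abort(paste0("locus absent from kit map: ", loci[is.na(kit_idx)][1]))

  parts <- vector("list", length(loci))
  n_combo <- 0L
  for (li in seq_along(loci)) {
    locus <- loci[li]
    ei <- ev_locus[[li]]
    obs_alleles <- E$allele[ei]
    sub <- freqs[fq_locus[[locus]], ]
    core <- enumerate_core(obs_alleles, locus, hyp, sub, floor)

    u <- core$universe                      # known alleles + Q
    nu <- length(u)
    # fragment sizes: observed peak size when present, else the kit map;
    # Q gets the mean observed size (its dropout factor only)
    des <- parse_designation(setdiff(u, ALLELE_Q))
    kit_sz <- kit$offset_bp[kit_idx[li]] + kit$motif_bp[kit_idx[li]] * des$rep + des$extra
    q_size <- if (length(ei) > 0) mean(E$size[ei], na.rm = TRUE) else mean(kit_sz)
    if (!is.finite(q_size)) {
      dtab <- parse_designation(sub$allele)
      q_size <- mean(kit$offset_bp[kit_idx[li]] + kit$motif_bp[kit_idx[li]] * dtab$rep + dtab$extra)
    }
    sz <- c(kit_sz, q_size)[match(u, c(setdiff(u, ALLELE_Q), ALLELE_Q))]
    oi <- match(u, obs_alleles)
    obs_sz <- E$size[ei][oi]
    sz <- ifelse(!is.na(oi) & is.finite(obs_sz), obs_sz, sz)

    # per-population copy counts over the universe
    cnt_of <- function(gmat) {
      m1 <- outer(match(gmat[, 1], u), seq_len(nu), `==`)
      m2 <- outer(match(gmat[, 2], u), seq_len(nu), `==`)
      m1[is.na(m1)] <- FALSE
      m2[is.na(m2)] <- FALSE
      m1 + m2
    }
    gn_cnt <- cnt_of(core$gn)
    gt_cnt <- cnt_of(core$gt)

    # drop combinations that cannot produce an observed allele in any
    # population (their density is identically zero)
    tot <- gn_cnt[core$gn_idx, , drop = FALSE]
    for (k in seq_len(ncol(core$tup))) tot <- tot + gt_cnt[core$tup[, k], , drop = FALSE]
    is_obs <- !is.na(oi)
    ok <- if (any(is_obs)) rowSums(tot[, is_obs, drop = FALSE] == 0) == 0 else
      rep(TRUE, length(core$prior))

    nc <- sum(ok)
    if (nc == 0) {
      # every combination is impossible (no drop-in): sentinel so the locus
      # is flagged -Inf rather than silently dropped
      n_combo <- n_combo + 1L
      parts[[li]] <- list(log_prior = -Inf, locus = li,
                          C = NULL, obs = logical(0), h = numeric(0), e = numeric(0),
                          combo = integer(0))
      next
    }
    gn_idx <- core$gn_idx[ok]; tup <- core$tup[ok, , drop = FALSE]
    C <- matrix(0, nrow = nc * nu, ncol = hyp$K)
    C[, 1] <- as.vector(t(gn_cnt[gn_idx, , drop = FALSE]))
    for (k in seq_len(ncol(tup))) {
      C[, k + 1] <- as.vector(t(gt_cnt[tup[, k], , drop = FALSE]))
    }
    combo_ids <- n_combo + seq_len(nc)
    n_combo <- n_combo + nc
    parts[[li]] <- list(
      log_prior = log(core$prior[ok]), locus = rep(li, nc), C = C,
      obs = rep(is_obs, nc), h = rep(E$height[ei][oi], nc),
      e = rep((sz - 90) / 100, nc),
      combo = rep(combo_ids, each = nu))
  }
  combo_locus <- unlist(lapply(parts, "[[", "locus"))
  list(loci = loci, K = hyp$K, at = at, mxn = hyp$mxn,
       combo_locus = combo_locus,
       log_prior = unlist(lapply(parts, "[[", "log_prior")),
       row_combo = unlist(lapply(parts, "[[", "combo")),
       row_obs = unlist(lapply(parts, "[[", "obs")),
       row_h = unlist(lapply(parts, "[[", "h")),
       row_e = unlist(lapply(parts, "[[", "e")),
       C = do.call(rbind, lapply(parts, "[[", "C")),
       locus_combos = split(seq_len(n_combo), combo_locus))
}

eval_context <- function(ctx, mu, omega, epsilon, weights, by_locus = FALSE) {
  n_combo <- length(ctx$log_prior)
  combo_ll <- ctx$log_prior
  if (length(ctx$row_combo) > 0) {
    D <- drop(ctx$C %*% weights)
    shape <- D * epsilon^ctx$row_e / omega^2
    scale <- mu * omega^2
    ll <- numeric(length(shape))
    pos <- shape > 0
    io <- ctx$row_obs & pos
    ll[io] <- dgamma(ctx$row_h[io], shape = shape[io], scale = scale, log = TRUE)
    ll[ctx$row_obs & !pos] <- -Inf
    iu <- !ctx$row_obs & pos
    ll[iu] <- pgamma(ctx$at, shape = shape[iu], scale = scale, log.p = TRUE)
    s <- rowsum(ll, ctx$row_combo)
    combo_ll[as.integer(rownames(s))] <- combo_ll[as.integer(rownames(s))] + drop(s)
  }
  per_locus <- vapply(ctx$locus_combos, function(idx) logsumexp(combo_ll[idx]), numeric(1))
  if (by_locus) {
    setNames(per_locus, ctx$loci[as.integer(names(ctx$locus_combos))])
  } else {
    sum(per_locus)
  }
}

#' Log-likelihood of a full profile under a hypothesis
#'
#' `sum_m log sum_{g_m} P(g_m | H, phi_m) * p(y_m | g_m, mu, omega,
#' epsilon, weights)`. Loci where every genotype combination is impossible
#' contribute `-Inf` and are named in a warning.
#'
#' @param E Evidence profile tibble (already thresholded).
#' @param hyp A `tlr_hypothesis`.
#' @param params A `tlr_params`.
#' @param freqs Frequency table.
#' @param kit Kit map.
#' @param at Analytical threshold (RFU).
#' @param by_locus Return the per-locus log-likelihood vector instead of the
#'   total.
#' @return Log-likelihood (scalar, or named vector when `by_locus = TRUE`).
#' @export
profile_log_likelihood <- function(E, hyp, params, freqs, kit = default_kit(),
                                   at = 175, by_locus = FALSE) {
  ctx <- build_likelihood_context(E, hyp, freqs, kit, at)
  per_locus <- eval_context(ctx, params$mu, params$omega, params$epsilon,
                            params$weights, by_locus = TRUE)
  bad <- names(per_locus)[!is.finite(per_locus)]
  if (length(bad) > 0) {
    warn(paste0("log-likelihood is -Inf at loc", if (length(bad) > 1) "i " else "us ",
                paste(bad, collapse = ", ")))
  }
  if (by_locus) per_locus else sum(per_locus)
}
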