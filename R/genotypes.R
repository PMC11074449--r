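#' Genotypes and hypothesis specifications
#'
#' Genotypes are unordered pairs of allele labels, represented as sorted
#' character vectors of length 2. Tumor genotypes may contain the reserved
#' symbol `LOSS` (a lost allele copy; `c(LOSS, LOSS)` is total locus loss).
#' Unknown normal genotypes may contain `Q`, the aggregate of all alleles
#' outside the locus candidate set.
#'
#' @param a,b Allele labels.
#' @return Character vector of length 2 (sorted).
#' @export
genotype <- function(a, b = a) sort(c(as.character(a), as.character(b)))

# All unordered genotypes (with repetition) over an allele set: n(n+1)/2 rows.
all_genotypes <- function(alleles) {
  n <- length(alleles)
  if (n == 0) abort("empty candidate allele set")
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  cbind(alleles[idx[, 1]], alleles[idx[, 2]])
}

genotype_key <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "/")
}

#' Per-locus STR variant incidence
#'
#' Wraps the a priori incidence of STR variants `phi`: either one scalar for
#' all loci, or a per-locus table. Loci absent from the table receive the
#' arithmetic mean of the provided values. `loss_fraction` splits a variant
#' event between allele loss (weight `loss_fraction`) and replacement by a
#' population allele (weight `1 - loss_fraction`, spread over alleles by
#' population frequency).
#'
#' @param phi Scalar in `[0,1]`, named numeric vector, or data frame with
#'   columns `locus`, `phi`.
#' @param loss_fraction Loss/replacement split in `[0,1]` (default 0.5).
#' @return An object of class `tlr_phi`.
#' @export
variant_incidence <- function(phi, loss_fraction = 0.5) {
  if (loss_fraction < 0 || loss_fraction > 1) abort("`loss_fraction` must lie in [0,1]")
  if (is.data.frame(phi)) {
    tab <- setNames(as.numeric(phi$phi), phi$locus)
  } else if (!is.null(names(phi))) {
    tab <- phi
  } else {
    if (length(phi) != 1) abort("unnamed `phi` must be a single scalar")
    tab <- setNames(as.numeric(phi), NA_character_)[0]
    attr(tab, "scalar") <- as.numeric(phi)
  }
  vals <- if (length(tab) > 0) as.numeric(tab) else attr(tab, "scalar")
  if (any(vals < 0 | vals > 1)) abort("phi values must lie in [0,1]")
  structure(list(table = tab,
                 default = if (length(tab) > 0) mean(as.numeric(tab)) else attr(tab, "scalar"),
                 loss_fraction = loss_fraction),
            class = "tlr_phi")
}

#' @rdname variant_incidence
#' @param vi A `tlr_phi` object.
#' @param locus Locus name.
#' @export
phi_at <- function(vi, locus) {
  if (!inherits(vi, "tlr_phi")) vi <- variant_incidence(vi)
  v <- unname(vi$table[locus])
  if (is.null(v) || length(v) == 0 || is.na(v)) vi$default else v
}

#' Hypothesis specification
#'
#' `HP`: the tumor tissue is normal cells plus `K - 1` tumor subclones from
#' the person of interest (normal genotype fixed to the reference).
#' `HD_UNRELATED` / `HD_PO` / `HD_FS`: same structure from an unrelated
#' individual, a parent/offspring, or a full sibling of the person of
#' interest (normal genotype enumerated, with Hardy-Weinberg or
#' kinship-conditioned priors).
#'
#' @param kind One of `"HP"`, `"HD_UNRELATED"`, `"HD_PO"`, `"HD_FS"`.
#' @param K Total number of cell populations (normal + subclones), `>= 2`.
#' @param poi Reference profile tibble of the person of interest.
#' @param mxn Normal-cell fraction in `[0,1]` (pathologist's estimate).
#' @param phi A `tlr_phi`, or anything [variant_incidence()] accepts.
#' @param loss_fraction Used when `phi` is not already a `tlr_phi`.
#' @return An object of class `tlr_hypothesis`.
#' @export
hypothesis <- function(kind = c("HP", "HD_UNRELATED", "HD_PO", "HD_FS"),
                       K = 2, poi = NULL, mxn, phi, loss_fraction = 0.5) {
  kind <- match.arg(kind)
  if (K < 2 || K != round(K)) abort("`K` must be an integer >= 2")
  if (mxn < 0 || mxn > 1) abort("`mxn` must lie in [0,1]")
  if (!inherits(phi, "tlr_phi")) phi <- variant_incidence(phi, loss_fraction)
  if (kind %in% c("HP", "HD_PO", "HD_FS") && is.null(poi)) {
    abort(paste0(kind, " requires a person-of-interest reference profile"))
  }
  structure(list(kind = kind, K = as.integer(K), poi = poi, mxn = mxn, phi = phi),
            class = "tlr_hypothesis")
}

#' Minimum number of cell populations by maximum allele count
#'
#' `k_min = 2` when the maximum per-locus allele count `Lmax < 3`, otherwise
#' `ceiling(Lmax / 2)`.
#'
#' @param profile Evidence profile tibble.
#' @return Integer `>= 2`.
#' @export
estimate_min_contributors <- function(profile) {
  if (nrow(profile) == 0) abort("no observed alleles anywhere; evidence is uninterpretable")
  lmax <- profile |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$allele)) |>
    dplyr::pull(.data$n) |> max()
  if (lmax < 3) 2L else as.integer(ceiling(lmax / 2))
}

#' Hardy-Weinberg genotype prior
#'
#' @param g Genotype (length-2 character vector; no `LOSS`).
#' @param f Named frequency vector over the locus allele universe (may
#'   include `Q` with its residual frequency).
#' @return Probability.
#' @export
hw_prior <- function(g, f) {
  if (any(g == ALLELE_LOSS)) abort("normal genotypes cannot contain LOSS")
  fa <- f[g[1]]; fb <- f[g[2]]
  if (anyNA(c(fa, fb))) abort("allele without frequency (flooring disabled here)")
  unname(if (g[1] == g[2]) fa^2 else 2 * fa * fb)
}

# Descent density matrix: D[o, s] = P(tumor slot shows outcome o | source
# allele s). Outcomes are the universe alleles plus LOSS; sources are
# universe alleles. Retain with 1 - phi; loss with phi * lambda; replacement
# by allele a with phi * (1 - lambda) * f(a) (may regenerate the source).
descent_matrix <- function(f, phi, lambda) {
  sources <- names(f)
  outcomes <- c(sources, ALLELE_LOSS)
  D <- matrix(0, nrow = length(outcomes), ncol = length(sources),
              dimnames = list(outcomes, sources))
  D[seq_along(sources), ] <- phi * (1 - lambda) * f  # replacement, any source
  D[ALLELE_LOSS, ] <- phi * lambda
  for (s in seq_along(sources)) D[s, s] <- D[s, s] + (1 - phi)
  D
}

#' Tumor genotype prior under the descent model
#'
#' Each tumor allele slot descends from one normal allele slot: it is
#' retained with probability `1 - phi`, lost with probability `phi *
#' loss_fraction`, or replaced by population allele `a` with probability
#' `phi * (1 - loss_fraction) * f(a)` (replacement may regenerate the
#' source). The probability of an unordered tumor genotype sums the ordered
#' slot-to-source assignments, so `P(g_t | g_n)` is a proper distribution
#' over unordered tumor states.
#'
#' @param g_t Tumor genotype (may contain `LOSS`).
#' @param g_n Normal genotype (no `LOSS`).
#' @param phi Variant incidence at this locus, in `[0,1]`.
#' @param loss_fraction Loss/replacement split in `[0,1]`.
#' @param f Named frequency vector over the locus allele universe.
#' @return Probability.
#' @export
tumor_genotype_prior <- function(g_t, g_n, phi, loss_fraction, f) {
  if (phi < 0 || phi > 1) abort("`phi` must lie in [0,1]")
  if (any(g_n == ALLELE_LOSS)) abort("normal genotypes cannot contain LOSS")
  D <- descent_matrix(f, phi, loss_fraction)
  p <- D[g_t[1], g_n[1]] * D[g_t[2], g_n[2]]
  if (g_t[1] != g_t[2]) p <- p + D[g_t[2], g_n[1]] * D[g_t[1], g_n[2]]
  unname(p)
}

# Vectorized: prior of every tumor genotype (rows of `gt_mat`) given one
# normal genotype, using a prebuilt descent matrix.
tumor_prior_vec <- function(gt_mat, g_n, D) {
  p <- D[gt_mat[, 1], g_n[1]] * D[gt_mat[, 2], g_n[2]]
  het <- gt_mat[, 1] != gt_mat[, 2]
  if (any(het)) {
    p[het] <- p[het] + D[gt_mat[het, 2], g_n[1]] * D[gt_mat[het, 1], g_n[2]]
  }
  unname(p)
}

#' Kinship-conditioned genotype prior
#'
#' Conditional probability of an unknown individual's genotype given the
#' person of interest's genotype, through IBD coefficients: parent-offspring
#' `(k0,k1,k2) = (0,1,0)`; full siblings `(1/4,1/2,1/4)`.
#'
#' @param g_u Unknown's genotype (no `LOSS`).
#' @param g_poi Person of interest's genotype (no `LOSS`).
#' @param relationship `"PO"` or `"FS"`.
#' @param f Named frequency vector over the locus allele universe.
#' @return Probability.
#' @export
kinship_prior <- function(g_u, g_poi, relationship = c("PO", "FS"), f) {
  relationship <- match.arg(relationship)
  if (any(c(g_u, g_poi) == ALLELE_LOSS)) abort("kinship priors apply to normal genotypes only")
  k <- switch(relationship, PO = c(0, 1, 0), FS = c(0.25, 0.5, 0.25))
  # one-IBD term: transmitted allele uniform over the POI's two slots, the
  # other drawn from the population
  p1 <- 0
  for (x in g_poi) {
    if (g_u[1] == g_u[2]) {
      if (x == g_u[1]) p1 <- p1 + 0.5 * f[g_u[1]]
    } else {
      if (x == g_u[1]) p1 <- p1 + 0.5 * f[g_u[2]]
      if (x == g_u[2]) p1 <- p1 + 0.5 * f[g_u[1]]
    }
  }
  unname(k[1] * hw_prior(g_u, f) + k[2] * p1 +
           k[3] * (genotype_key(g_u[1], g_u[2]) == genotype_key(g_poi[1], g_poi[2])))
}

# Collapsed frequency vector from a per-locus slice of the table: candidate
# alleles (floored) plus Q carrying the residual mass.
collapse_f <- function(sub, floor, candidates) {
  f <- sub$frequency[match(candidates, sub$allele)]
  f[is.na(f)] <- floor
  names(f) <- candidates
  c(f, setNames(max(0, 1 - sum(f)), ALLELE_Q))
}

# Vectorized enumeration engine. Returns index form: `gn` (normal genotype
# matrix), `gt` (tumor genotype matrix), `gn_idx` (combo -> normal row),
# `tup` (combo x (K-1) matrix of tumor rows), `prior`, and the collapsed
# frequency vector `f`.
enumerate_core <- function(obs_alleles, locus, hyp, sub, floor) {
  phi_m <- phi_at(hyp$phi, locus)
  lambda <- hyp$phi$loss_fraction
  poi_g <- if (!is.null(hyp$poi)) reference_genotype(hyp$poi, locus) else NULL
  known <- switch(hyp$kind,
    HP = union(obs_alleles, poi_g),
    HD_UNRELATED = obs_alleles,
    HD_PO = ,
    HD_FS = union(obs_alleles, poi_g))
  f <- collapse_f(sub, floor, known)
  universe <- names(f)

  if (hyp$kind == "HP") {
    gn <- matrix(poi_g, nrow = 1)
    gn_prior <- 1
  } else {
    cand_n <- switch(hyp$kind, HD_UNRELATED = c(obs_alleles, ALLELE_Q), universe)
    gn <- all_genotypes(cand_n)
    gn_prior <- switch(hyp$kind,
      HD_UNRELATED = apply(gn, 1, hw_prior, f = f),
      HD_PO = apply(gn, 1, kinship_prior, g_poi = poi_g, relationship = "PO", f = f),
      HD_FS = apply(gn, 1, kinship_prior, g_poi = poi_g, relationship = "FS", f = f))
  }

  gt <- all_genotypes(c(universe, ALLELE_LOSS))
  D <- descent_matrix(f, phi_m, lambda)
  m <- nrow(gn); nt <- nrow(gt)
  PT <- vapply(seq_len(m), function(i) tumor_prior_vec(gt, gn[i, ], D), numeric(nt))
  PT <- matrix(PT, nrow = nt)

  n_sub <- hyp$K - 1L
  if (n_sub == 1) {
    tuples <- matrix(seq_len(nt), ncol = 1)
  } else {
    tuples <- as.matrix(expand.grid(rep(list(seq_len(nt)), n_sub)))
    dimnames(tuples) <- NULL
  }
  T2 <- nrow(tuples)
  gn_idx <- rep(seq_len(m), each = T2)
  tup <- tuples[rep(seq_len(T2), m), , drop = FALSE]
  prior <- gn_prior[gn_idx]
  for (k in seq_len(n_sub)) prior <- prior * PT[cbind(tup[, k], gn_idx)]
  keep <- prior > 0
  if (!any(keep)) abort(paste0("no genotype combination has positive prior at ", locus))
  list(f = f, universe = universe, gn = gn, gt = gt,
       gn_idx = gn_idx[keep], tup = tup[keep, , drop = FALSE], prior = prior[keep])
}

#' Enumerate genotype combinations and their priors at one locus
#'
#' Builds the candidate allele universe, enumerates the normal genotype (or
#' fixes it to the person of interest under `HP`) and all `K - 1` subclone
#' tumor genotypes, and attaches the prior
#' `P(g_n | H) * prod_k P(g_{t,k} | g_n, phi)`. Candidate normal alleles are
#' the observed alleles plus the POI's alleles (`HP`, `HD_PO`, `HD_FS`) or
#' plus `Q` (all `HD` kinds); candidate tumor alleles additionally include
#' `LOSS` and `Q`. Zero-prior combinations are pruned.
#'
#' @param obs_alleles Character vector of observed alleles at the locus (may
#'   be empty for total dropout).
#' @param locus Locus name.
#' @param hyp A `tlr_hypothesis`.
#' @param freqs Frequency table.
#' @return Tibble with list-columns `normal` (length-2 character vectors) and
#'   `subclones` (lists of length-2 character vectors), and column `prior`.
#'   The collapsed frequency vector is attached as attribute `"f"`.
#' @export
enumerate_combinations <- function(obs_alleles, locus, hyp, freqs) {
  sub <- freqs[freqs$locus == locus, ]
  if (nrow(sub) == 0) abort(paste0("locus absent from frequency table: ", locus))
  core <- enumerate_core(obs_alleles, locus, hyp, sub,
                         floor = attr(freqs, "floor") %||% 0.005)
  n <- length(core$prior)
  out <- tibble(
    normal = lapply(seq_len(n), function(i) core$gn[core$gn_idx[i], ]),
    subclones = lapply(seq_len(n), function(i)
      lapply(seq_len(ncol(core$tup)), function(k) core$gt[core$tup[i, k], ])),
    prior = core$prior
  )
  attr(out, "f") <- core$f
  attr(out, "locus") <- locus
  out
}
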