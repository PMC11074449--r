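# Independent brute-force oracles: plain nested loops, no package internals.
# Used to pin down the descent-model priors, kinship priors and the full
# locus/profile likelihood on tiny configurations.

# All descent events of one tumor slot from source allele `s`:
# retain, loss, replacement by each universe allele (weighted by frequency).
oracle_slot_events <- function(s, phi, lambda, f) {
  out <- list(list(a = s, p = 1 - phi), list(a = "LOSS", p = phi * lambda))
  for (a in names(f)) {
    out[[length(out) + 1]] <- list(a = a, p = phi * (1 - lambda) * unname(f[[a]]))
  }
  out
}

oracle_tumor_prior <- function(g_t, g_n, phi, lambda, f) {
  key <- paste(sort(g_t), collapse = "/")
  total <- 0
  for (e1 in oracle_slot_events(g_n[1], phi, lambda, f)) {
    for (e2 in oracle_slot_events(g_n[2], phi, lambda, f)) {
      if (paste(sort(c(e1$a, e2$a)), collapse = "/") == key) {
        total <- total + e1$p * e2$p
      }
    }
  }
  total
}

# All unordered genotypes over an allele set, as a list of chr(2).
oracle_genotypes <- function(alleles) {
  out <- list()
  n <- length(alleles)
  for (i in seq_len(n)) for (j in i:n) {
    out[[length(out) + 1]] <- sort(c(alleles[i], alleles[j]))
  }
  out
}

oracle_hw <- function(g, f) {
  if (g[1] == g[2]) unname(f[[g[1]]]^2) else 2 * unname(f[[g[1]]] * f[[g[2]]])
}

# Full-sibling genotype prior by enumerating both parents from HW and all
# Mendelian transmissions, conditioning on the POI's genotype.
oracle_fs_prior <- function(g_u, g_poi, f) {
  alleles <- names(f)
  key_u <- paste(sort(g_u), collapse = "/")
  key_p <- paste(sort(g_poi), collapse = "/")
  num <- 0; den <- 0
  for (x1 in alleles) for (x2 in alleles) for (y1 in alleles) for (y2 in alleles) {
    p_par <- unname(f[[x1]] * f[[x2]] * f[[y1]] * f[[y2]])
    if (p_par == 0) next
    kids <- list(c(x1, y1), c(x1, y2), c(x2, y1), c(x2, y2))
    kk <- vapply(kids, function(g) paste(sort(g), collapse = "/"), character(1))
    p_poi <- mean(kk == key_p)
    if (p_poi == 0) next
    p_u <- mean(kk == key_u)
    num <- num + p_par * p_poi * p_u
    den <- den + p_par * p_poi
  }
  num / den
}

oracle_po_prior <- function(g_u, g_poi, f) {
  key_u <- paste(sort(g_u), collapse = "/")
  total <- 0
  for (x in g_poi) {
    for (a in names(f)) {
      if (paste(sort(c(x, a)), collapse = "/") == key_u) {
        total <- total + 0.5 * unname(f[[a]])
      }
    }
  }
  total
}

# Collapsed frequency vector, mirroring the package's candidate rule.
oracle_collapse_f <- function(freqs, locus, candidates, floor = attr(freqs, "floor")) {
  f <- list()
  sub <- freqs[freqs$locus == locus, ]
  for (a in candidates) {
    v <- sub$frequency[sub$allele == a]
    f[[a]] <- if (length(v) == 0) floor else v
  }
  f[["Q"]] <- max(0, 1 - sum(unlist(f)))
  f
}

# Density of one locus' peaks under one (normal, tumor) pair, K = 2.
oracle_locus_density <- function(obs, g_n, g_t, mxn, mu, omega, eps, at, kit, locus) {
  alleles <- setdiff(unique(c(g_n, g_t, obs$allele)), "LOSS")
  scale <- mu * omega^2
  dens <- 1
  for (a in alleles) {
    copies_n <- sum(g_n == a); copies_t <- sum(g_t == a)
    if (a %in% obs$allele) {
      sz <- obs$size[obs$allele == a]
    } else if (a == "Q") {
      sz <- if (nrow(obs) > 0) mean(obs$size) else mean(tumorlr::allele_size(kit, locus, "12"))
    } else {
      sz <- unname(tumorlr::allele_size(kit, locus, a))
    }
    shape <- (mxn * copies_n + (1 - mxn) * copies_t) * eps^((sz - 90) / 100) / omega^2
    if (a %in% obs$allele) {
      h <- obs$height[obs$allele == a]
      if (shape <= 0) return(0)
      dens <- dens * stats::dgamma(h, shape = shape, scale = scale)
    } else if (shape > 0) {
      dens <- dens * stats::pgamma(at, shape = shape, scale = scale)
    }
  }
  dens
}

# Full-profile log-likelihood by brute force, K = 2, HP or HD_UNRELATED.
oracle_profile_loglik <- function(E, poi, kind, mxn, phi, lambda, freqs, kit, at,
                                  mu, omega, eps) {
  loci <- unique(E$locus)
  total <- 0
  for (locus in loci) {
    obs <- E[E$locus == locus, ]
    poi_g <- if (!is.null(poi)) tumorlr::reference_genotype(poi, locus) else NULL
    known <- if (kind == "HP") unique(c(obs$allele, poi_g)) else unique(obs$allele)
    f <- oracle_collapse_f(freqs, locus, known)
    fv <- unlist(f)
    if (kind == "HP") {
      gns <- list(poi_g); gn_priors <- 1
    } else {
      gns <- oracle_genotypes(c(unique(obs$allele), "Q"))
      gn_priors <- vapply(gns, oracle_hw, numeric(1), f = f)
    }
    gts <- oracle_genotypes(c(names(fv), "LOSS"))
    lik <- 0
    for (i in seq_along(gns)) {
      for (gt in gts) {
        pr <- gn_priors[i] * oracle_tumor_prior(gt, gns[[i]], phi, lambda, fv)
        if (pr > 0) {
          lik <- lik + pr * oracle_locus_density(obs, gns[[i]], gt, mxn, mu, omega,
                                                 eps, at, kit, locus)
        }
      }
    }
    total <- total + log(lik)
  }
  total
}

# Single-source (one contributor, two allele copies) gamma log-likelihood.
oracle_single_source_loglik <- function(E, poi, mu, omega, eps, at, kit) {
  total <- 0
  scale <- mu * omega^2
  for (locus in unique(E$locus)) {
    obs <- E[E$locus == locus, ]
    g <- tumorlr::reference_genotype(poi, locus)
    for (a in unique(g)) {
      sz <- if (a %in% obs$allele) obs$size[obs$allele == a] else
        unname(tumorlr::allele_size(kit, locus, a))
      shape <- sum(g == a) * eps^((sz - 90) / 100) / omega^2
      if (a %in% obs$allele) {
        total <- total + stats::dgamma(obs$height[obs$allele == a], shape = shape,
                                       scale = scale, log = TRUE)
      } else {
        total <- total + stats::pgamma(at, shape = shape, scale = scale, log.p = TRUE)
      }
    }
    if (any(!obs$allele %in% g)) return(-Inf)
  }
  total
}
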