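#' Simulation configuration
#'
#' Defaults emulate the study conditions: 21 autosomal GlobalFiler loci,
#' gamma peak heights with `mu = 1500` RFU and `omega = 0.2` (dropout rare at
#' the 175 RFU analytical threshold for normal-cell fractions `>= 0.1`),
#' FFPE "ski-slope" degradation with per-base slope 0.996 (the middle of the
#' observed 0.9943-0.9985 range), `K = 2` cell populations, and per-locus
#' variant incidences from the bundled colorectal table.
#'
#' @param n_loci Number of loci (up to the kit's 21).
#' @param alleles_per_locus Integer range of allele counts per locus.
#' @param mu,omega Gamma peak-height expectation (RFU) and coefficient of
#'   variation per allele copy at weight 1.
#' @param per_base_slope Probability of no strand breakage per base.
#' @param mxn Normal-cell fraction.
#' @param K Number of cell populations.
#' @param phi Variant incidence ([variant_incidence()] input).
#' @param loss_fraction Loss/replacement split of a variant event.
#' @param at Analytical threshold (RFU).
#' @param seed Mandatory integer seed.
#' @param kit Kit map.
#' @return A list of class `tlr_sim_config`.
#' @export
sim_config <- function(n_loci = 21, alleles_per_locus = c(5, 10), mu = 1500,
                       omega = 0.2, per_base_slope = 0.996, mxn = 0.4, K = 2,
                       phi = default_phi(), loss_fraction = 0.5, at = 175,
                       seed = 1, kit = default_kit()) {
  if (is.null(seed)) abort("`seed` is mandatory for reproducible simulation")
  vi <- if (inherits(phi, "tlr_phi")) phi else variant_incidence(phi, loss_fraction)
  stopifnot(mxn >= 0, mxn <= 1, per_base_slope > 0, per_base_slope <= 1,
            mu > 0, omega > 0, K >= 2)
  structure(list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 mu = mu, omega = omega, per_base_slope = per_base_slope,
                 mxn = mxn, K = as.integer(K), phi = vi, at = at,
                 seed = as.integer(seed), kit = kit),
            class = "tlr_sim_config")
}

#' Simulate a population allele-frequency table
#'
#' Per locus: an allele count drawn from `alleles_per_locus`, consecutive
#' integer designations (occasionally one `.3` microvariant), and
#' frequencies from a symmetric Dirichlet with concentration 1.5.
#'
#' @param cfg A `tlr_sim_config` (or arguments via `...` of [sim_config()]).
#' @param microvariant_prob Probability a locus carries one `.3` designation.
#' @return A frequency-table tibble.
#' @export
simulate_frequency_table <- function(cfg = sim_config(), microvariant_prob = 0.15) {
  loci <- head(cfg$kit$locus, cfg$n_loci)
  if (length(loci) < cfg$n_loci) abort("kit map has fewer loci than `n_loci`")
  withr::with_seed(cfg$seed, {
    tab <- purrr::map_dfr(loci, function(l) {
      n <- sample(seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2]), 1)
      start <- sample(6:12, 1)
      des <- as.character(seq(start, start + n - 1))
      if (runif(1) < microvariant_prob) {
        k <- sample(seq_len(n), 1)
        des[k] <- paste0(des[k], ".3")
      }
      f <- rgamma(n, shape = 1.5)
      f <- f / sum(f)
      # respect the unseen-allele floor so the table round-trips through disk
      low <- f < 0.005
      if (any(low) && !all(low)) {
        f[low] <- 0.005
        f[!low] <- f[!low] * (1 - sum(f[low])) / sum(f[!low])
      }
      tibble(locus = l, allele = des, frequency = f)
    })
  })
  frequency_table(tab)
}

# Draw one allele per slot by population frequency.
draw_alleles <- function(freqs, locus, n) {
  sub <- freqs[freqs$locus == locus, ]
  sub$allele[sample.int(nrow(sub), n, replace = TRUE, prob = sub$frequency)]
}

#' Simulate a reference (person) profile under Hardy-Weinberg
#'
#' Two alleles per locus drawn independently by population frequency.
#' Homozygous loci are stored as a single row (standard reference-profile
#' convention).
#'
#' @param freqs Frequency table.
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return A reference profile tibble.
#' @export
sample_reference_profile <- function(freqs, seed, sample_id = "REF") {
  loci <- unique(freqs$locus)
  idx <- split(seq_len(nrow(freqs)), factor(freqs$locus, levels = loci))
  al <- freqs$allele; fr <- freqs$frequency
  out_locus <- character(); out_allele <- character()
  withr::with_seed(seed, {
    for (l in loci) {
      i <- idx[[l]]
      g <- unique(sort(al[i][sample.int(length(i), 2, replace = TRUE, prob = fr[i])]))
      out_locus <- c(out_locus, rep(l, length(g)))
      out_allele <- c(out_allele, g)
    }
  })
  out <- as_str_profile(tibble(sample_id = sample_id, locus = out_locus,
                               allele = out_allele), kind = "reference")
  attr(out, "loci") <- loci
  out
}

#' Simulate a tumor (evidence) profile from a reference
#'
#' Draws `K - 1` subclone genotypes from the generative form of the descent
#' model (each allele slot: retained with `1 - phi`, lost with
#' `phi * loss_fraction`, replaced by a population allele with
#' `phi * (1 - loss_fraction) * f(a)`), then draws peak heights per allele
#' from the gamma model with mixture weights (`mxn`, equal subclone split),
#' degradation `per_base_slope^(size - 90)`, and removes peaks below the
#' analytical threshold. The applied variants are recorded in the `"truth"`
#' attribute (per-slot events and a per-locus Aadd/Anew/pLOH/LOH label).
#'
#' @param reference Reference profile tibble.
#' @param freqs Frequency table.
#' @param cfg A `tlr_sim_config`.
#' @return An evidence profile tibble with attributes `"loci"` and `"truth"`.
#' @export
simulate_tumor_profile <- function(reference, freqs, cfg = sim_config()) {
  loci <- intersect(profile_loci(reference), unique(freqs$locus))
  kit <- cfg$kit
  lambda <- cfg$phi$loss_fraction
  weights <- c(cfg$mxn, rep((1 - cfg$mxn) / (cfg$K - 1), cfg$K - 1))
  scale <- cfg$mu * cfg$omega^2
  sid <- paste0(reference$sample_id[1], "-T")

  res <- withr::with_seed(cfg$seed, {
    purrr::map(loci, function(l) {
      gn <- reference_genotype(reference, l)
      phi_m <- phi_at(cfg$phi, l)
      pops <- list(gn)
      events <- list()
      for (k in seq_len(cfg$K - 1)) {
        gt <- character(2)
        for (slot in 1:2) {
          u <- runif(1)
          if (u < 1 - phi_m) {
            gt[slot] <- gn[slot]; ev <- "retain"
          } else if (u < 1 - phi_m + phi_m * lambda) {
            gt[slot] <- ALLELE_LOSS; ev <- "loss"
          } else {
            gt[slot] <- draw_alleles(freqs, l, 1); ev <- "replace"
          }
          events[[length(events) + 1]] <- tibble(
            locus = l, subclone = k, slot = slot, event = ev,
            source = gn[slot], result = gt[slot])
        }
        pops[[k + 1]] <- sort(gt)
      }
      alleles <- setdiff(unique(unlist(pops)), ALLELE_LOSS)
      peaks <- NULL
      if (length(alleles) > 0) {
        sz <- vapply(alleles, function(a) unname(allele_size(kit, l, a)), numeric(1))
        deg <- cfg$per_base_slope^(sz - 90)
        copies <- vapply(pops, function(g) vapply(alleles, function(a) sum(g == a),
                                                  numeric(1)), numeric(length(alleles)))
        copies <- matrix(copies, nrow = length(alleles))
        shape <- drop(copies %*% weights) * deg / cfg$omega^2
        h <- rgamma(length(alleles), shape = shape, scale = scale)
        peaks <- tibble(sample_id = sid, locus = l, allele = alleles,
                        height = h, size = unname(sz))
      }
      list(peaks = peaks, events = dplyr::bind_rows(events), gn = gn)
    })
  })
  peaks <- dplyr::bind_rows(purrr::map(res, "peaks"))
  events <- dplyr::bind_rows(purrr::map(res, "events"))
  truth <- events |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(variant = classify_variants(.data$event, .data$result,
                                                 .data$source, .data$subclone),
                     n_loss = sum(.data$event == "loss"),
                     n_replace = sum(.data$event == "replace"), .groups = "drop")
  out <- as_str_profile(peaks, kind = "evidence")
  out <- apply_analytical_threshold(out, cfg$at)
  attr(out, "loci") <- loci
  attr(out, "truth") <- list(events = events, by_locus = truth,
                             mxn = cfg$mxn, weights = weights)
  out
}

# Per-locus variant class from the slot events of all subclones: complete
# loss of a subclone's pair -> LOH; a single lost slot -> pLOH; replacement
# producing an allele outside the somatic genotype -> Aadd when the source
# slots still show (normal background present), Anew bookkeeping otherwise.
classify_variants <- function(event, result, source, subclone) {
  labels <- character(0)
  for (k in unique(subclone)) {
    ev <- event[subclone == k]; rs <- result[subclone == k]; sc <- source[subclone == k]
    if (all(ev == "loss")) labels <- c(labels, "LOH")
    else if (any(ev == "loss")) labels <- c(labels, "pLOH")
    new_alleles <- rs[ev == "replace" & !rs %in% sc]
    if (length(new_alleles) > 0) {
      labels <- c(labels, if (any(ev == "retain")) "Aadd" else "Anew")
    }
  }
  if (length(labels) == 0) "none" else paste(sort(unique(labels)), collapse = "+")
}

#' Simulate a relative of a reference individual
#'
#' Parent/offspring: one allele per locus transmitted uniformly from the
#' reference, the other drawn from the population. Full sibling: the IBD
#' state per locus is drawn with probabilities (1/4, 1/2, 1/4) and alleles
#' filled in by transmission/population draws accordingly.
#'
#' @param reference Reference profile tibble.
#' @param relationship `"PO"` or `"FS"`.
#' @param freqs Frequency table.
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return A reference-kind profile tibble; the per-locus IBD states are in
#'   the `"ibd"` attribute.
#' @export
simulate_relative <- function(reference, relationship = c("PO", "FS"), freqs,
                              seed, sample_id = NULL) {
  relationship <- match.arg(relationship)
  sample_id <- sample_id %||% paste0(reference$sample_id[1], "-", relationship)
  loci <- intersect(profile_loci(reference), unique(freqs$locus))
  out <- withr::with_seed(seed, {
    purrr::map(loci, function(l) {
      gn <- reference_genotype(reference, l)
      if (relationship == "PO") {
        ibd <- 1L
        g <- c(gn[sample.int(2, 1)], draw_alleles(freqs, l, 1))
      } else {
        ibd <- sample(0:2, 1, prob = c(0.25, 0.5, 0.25))
        g <- switch(as.character(ibd),
                    "2" = gn,
                    "1" = c(gn[sample.int(2, 1)], draw_alleles(freqs, l, 1)),
                    "0" = draw_alleles(freqs, l, 2))
      }
      list(rows = tibble(sample_id = sample_id, locus = l, allele = unique(sort(g))),
           ibd = tibble(locus = l, ibd = ibd))
    })
  })
  prof <- as_str_profile(dplyr::bind_rows(purrr::map(out, "rows")), kind = "reference")
  attr(prof, "loci") <- loci
  attr(prof, "ibd") <- dplyr::bind_rows(purrr::map(out, "ibd"))
  prof
}

#' Simulate a cohort of tumor cases
#'
#' Generates one shared frequency table, then `n_cases` (reference, tumor
#' evidence) pairs. The default normal-cell fractions mirror the study
#' cohort's pathology: `mxn = 1 - mxt` with tumor-cell percentages between
#' 30% and 90% (17 values, recycled for other `n_cases`).
#'
#' @param n_cases Number of cases (default 17).
#' @param cfg A `tlr_sim_config`; its `seed` drives everything.
#' @param mxn Vector of normal-cell fractions (recycled).
#' @return Tibble with columns `case_id`, `mxn`, and list-columns
#'   `reference`, `evidence`, `truth`; the shared frequency table is the
#'   `"freqs"` attribute.
#' @export
make_case_suite <- function(n_cases = 17, cfg = sim_config(),
                            mxn = c(0.4, 0.5, 0.4, 0.7, 0.3, 0.2, 0.6, 0.3, 0.4,
                                    0.2, 0.3, 0.4, 0.6, 0.4, 0.1, 0.2, 0.2)) {
  freqs <- simulate_frequency_table(cfg)
  mxn <- rep_len(mxn, n_cases)
  cases <- purrr::map_dfr(seq_len(n_cases), function(i) {
    ref <- sample_reference_profile(freqs, seed = derive_seed(cfg$seed, 2 * i),
                                    sample_id = sprintf("CASE%02d", i))
    cfg_i <- cfg
    cfg_i$mxn <- mxn[i]
    cfg_i$seed <- derive_seed(cfg$seed, 2 * i + 1)
    ev <- simulate_tumor_profile(ref, freqs, cfg_i)
    tibble(case_id = sprintf("CASE%02d", i), mxn = mxn[i],
           reference = list(ref), evidence = list(ev),
           truth = list(attr(ev, "truth")))
  })
  attr(cases, "freqs") <- freqs
  cases
}
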