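# Small fixtures built in code.

tiny_kit <- function() {
  tibble::tibble(locus = c("L1", "L2", "L3"),
                 offset_bp = c(60, 120, 200), motif_bp = c(4, 4, 3),
                 dye = "blue")
}

tiny_freqs <- function(floor = 0.001) {
  tumorlr::frequency_table(tibble::tibble(
    locus = c(rep("L1", 3), rep("L2", 2), rep("L3", 4)),
    allele = c("10", "12", "13", "8", "9.3", "11", "12", "13", "14"),
    frequency = c(0.5, 0.3, 0.2, 0.6, 0.4, 0.25, 0.25, 0.25, 0.25)),
    floor = floor)
}

# Evidence profile with the given peaks (heights in RFU); sizes from the kit.
toy_evidence <- function(peaks, kit = tiny_kit(), sample_id = "E1") {
  peaks$sample_id <- sample_id
  peaks$size <- purrr::map2_dbl(peaks$locus, peaks$allele,
                                ~ unname(tumorlr::allele_size(kit, .x, .y)))
  tumorlr::as_str_profile(peaks, kind = "evidence")
}

toy_reference <- function(genotypes, sample_id = "R1") {
  rows <- purrr::imap_dfr(genotypes, function(g, l)
    tibble::tibble(sample_id = sample_id, locus = l, allele = unique(g)))
  tumorlr::as_str_profile(rows, kind = "reference")
}

# Noise-free evidence generated from a reference: heights equal the gamma
# expectation of the single-source model (mu per copy, degradation slope).
noiseless_evidence <- function(reference, mu = 1500, slope = 1, kit = tiny_kit()) {
  rows <- purrr::map_dfr(tumorlr::profile_loci(reference), function(l) {
    g <- tumorlr::reference_genotype(reference, l)
    al <- unique(g)
    sz <- purrr::map_dbl(al, ~ unname(tumorlr::allele_size(kit, l, .x)))
    tibble::tibble(sample_id = paste0(reference$sample_id[1], "-E"), locus = l,
                   allele = al,
                   height = purrr::map_dbl(seq_along(al), function(i)
                     sum(g == al[i]) * mu * slope^(sz[i] - 90)),
                   size = sz)
  })
  tumorlr::as_str_profile(rows, kind = "evidence")
}

# Random named frequency vector over `n` alleles plus Q (residual mass).
random_f <- function(n = 3, q_mass = NULL, seed = 1) {
  withr::with_seed(seed, {
    v <- stats::rgamma(n, 1)
    qm <- q_mass %||% stats::runif(1, 0, 0.3)
    f <- v / sum(v) * (1 - qm)
    stats::setNames(c(f, qm), c(as.character(seq(10, 10 + n - 1)), "Q"))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
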