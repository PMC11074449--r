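#' Population allele-frequency tables
#'
#' A frequency table is a tibble with columns `locus`, `allele`, `frequency`
#' plus a `"floor"` attribute: the minimum frequency assigned to alleles that
#' were not seen in the population survey. The default floor is `5 / (2 * N)`
#' with survey size `N = 500`.
#'
#' @param x Data frame with columns `locus`, `allele`, `frequency`.
#' @param floor Minimum frequency; default `5 / (2 * n_survey)`.
#' @param n_survey Survey size used for the default floor.
#' @return A validated frequency-table tibble.
#' @export
frequency_table <- function(x, floor = NULL, n_survey = 500) {
  x <- as_tibble(x)
  needed <- c("locus", "allele", "frequency")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) abort(paste0("frequency table missing column(s): ", paste(miss, collapse = ", ")))
  floor <- floor %||% (5 / (2 * n_survey))
  x$allele <- as.character(x$allele)
  x$frequency <- as.numeric(x$frequency)
  if (anyNA(x$frequency) || any(x$frequency < 0)) abort("negative or missing frequency")
  sums <- x |> dplyr::group_by(.data$locus) |> dplyr::summarise(s = sum(.data$frequency))
  bad <- sums |> dplyr::filter(.data$s > 1 + 1e-6)
  if (nrow(bad) > 0) abort(paste0("frequencies at locus ", bad$locus[1], " sum to ", signif(bad$s[1], 6), " > 1"))
  # flooring never decreases a stored frequency
  x$frequency <- pmax(x$frequency, floor)
  attr(x, "floor") <- floor
  x
}

#' Read an allele-frequency CSV (columns locus, allele, frequency)
#'
#' @inheritParams frequency_table
#' @param path CSV path.
#' @return A frequency-table tibble.
#' @export
read_frequency_table <- function(path, floor = NULL, n_survey = 500) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    locus = readr::col_character(), allele = readr::col_character(),
    frequency = readr::col_double()), progress = FALSE)
  frequency_table(x, floor = floor, n_survey = n_survey)
}

#' Look up allele frequencies with flooring
#'
#' Alleles absent from the table receive the floor frequency (with a warning
#' unless `quiet`). The reserved symbol `Q` must be resolved through
#' [q_frequency()] and is rejected here.
#'
#' @param freqs Frequency table.
#' @param locus Locus name.
#' @param alleles Character vector of allele designations.
#' @param quiet Suppress the unseen-allele warning.
#' @return Named numeric vector of frequencies.
#' @export
allele_frequency <- function(freqs, locus, alleles, quiet = FALSE) {
  if (any(alleles %in% c(ALLELE_LOSS, ALLELE_Q))) abort("LOSS/Q have no table frequency")
  sub <- freqs[freqs$locus == locus, ]
  if (nrow(sub) == 0) abort(paste0("locus absent from frequency table: ", locus))
  f <- sub$frequency[match(alleles, sub$allele)]
  floor <- attr(freqs, "floor") %||% 0.005
  unseen <- is.na(f)
  if (any(unseen)) {
    if (!quiet) warn(paste0("allele(s) ", paste(alleles[unseen], collapse = ","),
                            " unseen at ", locus, "; using floor ", floor))
    f[unseen] <- floor
  }
  setNames(f, alleles)
}

#' Residual frequency of the aggregate Q allele
#'
#' `Q` stands for every allele outside the candidate set at a locus; its
#' frequency is the residual mass `max(0, 1 - sum(f(candidates)))`.
#'
#' @param freqs Frequency table.
#' @param locus Locus name.
#' @param candidates Character vector of candidate (non-Q) alleles.
#' @return A single frequency in `[0, 1]`.
#' @export
q_frequency <- function(freqs, locus, candidates) {
  if (length(candidates) == 0) return(1)
  max(0, 1 - sum(allele_frequency(freqs, locus, candidates, quiet = TRUE)))
}
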