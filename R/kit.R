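#' Kit size maps
#'
#' A kit map is a tibble with columns `locus`, `offset_bp` (fragment size at
#' repeat number 0), `motif_bp` (base pairs per repeat unit) and `dye`
#' (informational). The fragment size of allele `r` at a locus is
#' `offset_bp + motif_bp * r`; a fractional designation such as `"9.3"` maps
#' to `offset_bp + motif_bp * 9 + 3` (the decimal part is extra base pairs).
#'
#' @param path CSV (`locus,offset_bp,motif_bp,dye`) or YAML file.
#' @return A kit-map tibble.
#' @export
read_kit_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    x <- purrr::map_dfr(names(y), function(l) {
      tibble(locus = l, offset_bp = as.numeric(y[[l]]$offset_bp),
             motif_bp = as.numeric(y[[l]]$motif_bp),
             dye = as.character(y[[l]]$dye %||% NA_character_))
    })
  } else {
    x <- readr::read_csv(path, col_types = readr::cols(
      locus = readr::col_character(), offset_bp = readr::col_double(),
      motif_bp = readr::col_double(), dye = readr::col_character()),
      progress = FALSE)
  }
  if (any(x$offset_bp <= 0) || any(x$motif_bp <= 0)) abort("kit offsets and motif lengths must be positive")
  if (anyDuplicated(x$locus)) abort("duplicated locus in kit map")
  as_tibble(x)
}

#' Bundled GlobalFiler-like kit map (synthetic size offsets)
#'
#' Real GlobalFiler autosomal locus names and repeat-motif lengths with
#' synthetic, approximate size offsets spanning roughly 70-460 bp. Adequate
#' for degradation modeling and simulation; not the vendor's bin set.
#'
#' @return A kit-map tibble with 21 autosomal loci.
#' @export
default_kit <- function() {
  read_kit_map(system.file("extdata", "kit_globalfiler_synthetic.csv", package = "tumorlr"))
}

#' Bundled per-locus STR variant incidences for colorectal tumors (synthetic)
#'
#' Synthetic stand-in for a published colorectal survey: 19 loci with
#' deterministic values spanning exactly `[0.0775, 0.4341]`, TPOX lowest.
#'
#' @return Tibble with columns `locus`, `phi`.
#' @export
default_phi <- function() {
  readr::read_csv(system.file("extdata", "phi_colorectal_synthetic.csv", package = "tumorlr"),
                  col_types = readr::cols(locus = readr::col_character(),
                                          phi = readr::col_double()),
                  progress = FALSE)
}

# "9.3" -> repeat 9 plus 3 extra bp. Returns list(rep, extra).
parse_designation <- function(allele) {
  parts <- strsplit(allele, ".", fixed = TRUE)
  rep <- purrr::map_dbl(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[1]))
    if (is.na(v)) abort(paste0("non-numeric allele designation: ", paste(p, collapse = ".")))
    v
  })
  extra <- purrr::map_dbl(parts, function(p) {
    if (length(p) < 2) return(0)
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) abort(paste0("non-numeric allele designation fraction: ", paste(p, collapse = ".")))
    v
  })
  list(rep = rep, extra = extra)
}

#' Fragment size of an allele under a kit map
#'
#' @param kit Kit-map tibble.
#' @param locus Locus name.
#' @param allele Character vector of numeric repeat designations (not LOSS/Q).
#' @return Numeric vector of fragment sizes in bp.
#' @export
allele_size <- function(kit, locus, allele) {
  row <- kit[kit$locus == locus, ]
  if (nrow(row) == 0) abort(paste0("locus absent from kit map: ", locus))
  if (any(allele %in% c(ALLELE_LOSS, ALLELE_Q))) abort("LOSS/Q have no physical size")
  d <- parse_designation(allele)
  sz <- row$offset_bp[1] + row$motif_bp[1] * d$rep + d$extra
  if (any(sz <= 0)) abort("non-positive fragment size")
  setNames(sz, allele)
}
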