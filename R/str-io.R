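#' STR profiles as tibbles
#'
#' Throughout tumorlr an STR profile is a tibble with one row per called
#' allele and columns `sample_id`, `locus`, `allele` (character repeat
#' designation, e.g. `"12"` or `"9.3"`), `height` (peak height in RFU; `NA`
#' for reference profiles) and `size` (fragment size in bp; may be `NA`).
#' Loci that lost every peak to the analytical threshold are tracked in the
#' `"loci"` attribute so that total-dropout loci stay part of the profile.
#'
#' @param x A data frame with at least `sample_id`, `locus`, `allele`.
#' @param kind `"evidence"` (heights required) or `"reference"` (1-2 alleles
#'   per locus, heights optional).
#' @return A validated profile tibble.
#' @export
as_str_profile <- function(x, kind = c("evidence", "reference")) {
  kind <- match.arg(kind)
  x <- as_tibble(x)
  needed <- c("sample_id", "locus", "allele")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("profile is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"height" %in% names(x)) x$height <- NA_real_
  if (!"size" %in% names(x)) x$size <- NA_real_
  x$allele <- as.character(x$allele)
  if (any(!nzchar(x$allele)) || anyNA(x$allele)) abort("allele designations must be non-empty")
  if (any(x$allele %in% c(ALLELE_LOSS, ALLELE_Q))) {
    abort("reserved allele symbols LOSS/Q may not appear in a profile")
  }
  dup <- dplyr::count(x, .data$sample_id, .data$locus, .data$allele) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated allele within locus: ", dup$locus[1], " allele ", dup$allele[1]))
  }
  if (kind == "evidence") {
    if (anyNA(x$height)) abort("evidence profiles must carry a height for every allele")
    if (any(x$height <= 0)) abort("peak heights must be positive")
  } else {
    n_alleles <- dplyr::count(x, .data$sample_id, .data$locus)
    if (any(n_alleles$n > 2)) {
      abort("reference profiles must have at most 2 alleles per locus")
    }
  }
  attr(x, "loci") <- union(attr(x, "loci") %||% character(), unique(x$locus))
  attr(x, "kind") <- kind
  x
}

#' Loci carried by a profile (including total-dropout loci)
#' @param profile A profile tibble.
#' @return Character vector of locus names.
#' @export
profile_loci <- function(profile) {
  union(attr(profile, "loci") %||% character(), unique(profile$locus))
}

#' Reference genotype at a locus
#'
#' A single listed allele is treated as homozygous (standard forensic
#' convention for reference profiles).
#'
#' @param reference Reference profile tibble.
#' @param locus Locus name.
#' @return Character vector of length 2 (sorted).
#' @export
reference_genotype <- function(reference, locus) {
  a <- reference$allele[reference$locus == locus]
  if (length(a) == 0) abort(paste0("reference has no alleles at locus ", locus))
  if (length(a) == 1) a <- c(a, a)
  sort(a)
}

#' Read a GeneMapper-style genotype table export
#'
#' Accepts the tab-delimited text export of GeneMapper ID-X in either the
#' "wide" layout (`Allele 1..n`, `Height 1..n`, `Size 1..n` columns) or a
#' "long" layout (one row per allele with `Allele`, `Height`, `Size`
#' columns). Mandatory columns are `Sample Name` and `Marker`.
#'
#' @param path Path to the exported text file.
#' @param layout `"wide"` or `"long"`.
#' @param kind Passed to [as_str_profile()].
#' @return A profile tibble (possibly holding several samples).
#' @export
read_genemapper <- function(path, layout = c("wide", "long"), kind = "evidence") {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("Sample Name", "Marker")) {
    if (!col %in% names(raw)) abort(paste0("missing mandatory column: ", col))
  }
  if (nrow(raw) == 0) {
    warn(paste0("no data rows in ", path))
    out <- tibble(sample_id = character(), locus = character(),
                  allele = character(), height = numeric(), size = numeric())
    return(as_str_profile(out, kind = kind))
  }
  if (layout == "wide") {
    allele_cols <- grep("^Allele ?[0-9]+$", names(raw), value = TRUE)
    if (length(allele_cols) == 0) abort("missing mandatory column: Allele 1")
    idx <- sub("^Allele ?", "", allele_cols)
    rows <- purrr::map_dfr(seq_len(nrow(raw)), function(i) {
      purrr::map_dfr(idx, function(j) {
        a <- raw[[paste0(sub("[0-9]+$", "", allele_cols[1]), j)]][i]
        if (is.na(a) || !nzchar(a)) return(NULL)
        hcol <- intersect(c(paste0("Height ", j), paste0("Height", j)), names(raw))
        scol <- intersect(c(paste0("Size ", j), paste0("Size", j)), names(raw))
        h <- if (length(hcol) > 0) raw[[hcol[1]]][i] else NA_character_
        s <- if (length(scol) > 0) raw[[scol[1]]][i] else NA_character_
        tibble(sample_id = raw[["Sample Name"]][i], locus = raw[["Marker"]][i],
               allele = a,
               height = parse_num(h, i, "Height", required = identical(kind, "evidence")),
               size = parse_num(s, i, "Size", required = FALSE))
      })
    })
  } else {
    for (col in c("Allele")) {
      if (!col %in% names(raw)) abort(paste0("missing mandatory column: ", col))
    }
    rows <- tibble(
      sample_id = raw[["Sample Name"]], locus = raw[["Marker"]],
      allele = raw[["Allele"]],
      height = purrr::map_dbl(seq_len(nrow(raw)), function(i)
        parse_num(if ("Height" %in% names(raw)) raw[["Height"]][i] else NA_character_,
                  i, "Height", required = identical(kind, "evidence"))),
      size = purrr::map_dbl(seq_len(nrow(raw)), function(i)
        parse_num(if ("Size" %in% names(raw)) raw[["Size"]][i] else NA_character_,
                  i, "Size", required = FALSE))
    ) |> dplyr::filter(!is.na(.data$allele) & nzchar(.data$allele))
  }
  as_str_profile(rows, kind = kind)
}

parse_num <- function(x, line, what, required = TRUE) {
  if (is.null(x) || is.na(x) || !nzchar(x)) {
    if (required) abort(paste0(what, " missing at data row ", line))
    return(NA_real_)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) abort(paste0(what, " not numeric at data row ", line, ": '", x, "'"))
  v
}

#' Write a profile as a GeneMapper-style table
#'
#' @param profile Profile tibble.
#' @param path Output path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_genemapper <- function(profile, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    out <- tibble(`Sample Name` = profile$sample_id, Marker = profile$locus,
                  Allele = profile$allele, Height = profile$height, Size = profile$size)
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  nested <- profile |>
    dplyr::group_by(.data$sample_id, .data$locus) |>
    dplyr::summarise(alleles = list(.data$allele), heights = list(.data$height),
                     sizes = list(.data$size), .groups = "drop")
  nmax <- max(c(1, purrr::map_int(nested$alleles, length)))
  wide <- purrr::map_dfr(seq_len(nrow(nested)), function(i) {
    row <- list(`Sample Name` = nested$sample_id[i], Marker = nested$locus[i])
    for (j in seq_len(nmax)) {
      row[[paste0("Allele ", j)]] <- nested$alleles[[i]][j]
      row[[paste0("Height ", j)]] <- nested$heights[[i]][j]
      row[[paste0("Size ", j)]] <- nested$sizes[[i]][j]
    }
    as_tibble(row)
  })
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Apply the analytical threshold
#'
#' Removes peaks below `at` RFU. Loci whose peaks are all removed remain part
#' of the profile (tracked via the `"loci"` attribute) and are interpreted
#' downstream as total dropout.
#'
#' @param profile Evidence profile tibble.
#' @param at Analytical threshold in RFU (default 175).
#' @param quiet Suppress the per-locus removal message.
#' @return Thresholded profile tibble.
#' @export
apply_analytical_threshold <- function(profile, at = 175, quiet = TRUE) {
  if (!is.numeric(at) || length(at) != 1 || at <= 0) abort("`at` must be a positive number")
  loci <- profile_loci(profile)
  removed <- profile |> dplyr::filter(.data$height < at)
  if (nrow(removed) > 0 && !quiet) {
    counts <- dplyr::count(removed, .data$locus)
    inform(paste0("sub-threshold peaks removed: ",
                  paste0(counts$locus, " (", counts$n, ")", collapse = ", ")))
  }
  out <- profile |> dplyr::filter(.data$height >= at)
  attr(out, "loci") <- loci
  attr(out, "kind") <- attr(profile, "kind")
  attr(out, "at") <- at
  out
}

#' Write / read the canonical profile JSON used between tools
#'
#' @param profile Profile tibble.
#' @param path File path.
#' @return `path` (write) or a profile tibble (read).
#' @export
write_profile_json <- function(profile, path) {
  payload <- list(kind = attr(profile, "kind") %||% "evidence",
                  loci = profile_loci(profile),
                  peaks = as.data.frame(profile))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  peaks <- as_tibble(payload$peaks)
  if (nrow(peaks) == 0) {
    peaks <- tibble(sample_id = character(), locus = character(),
                    allele = character(), height = numeric(), size = numeric())
  }
  out <- as_str_profile(peaks, kind = payload$kind)
  attr(out, "loci") <- union(profile_loci(out), unlist(payload$loci))
  out
}
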