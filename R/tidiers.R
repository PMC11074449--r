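#' Tidy and glance methods for tumorlr result objects
#'
#' `tidy()` returns the per-unit breakdown of a result (per locus, per grid
#' cell, per interval point, per scored individual, per quantile pair);
#' `glance()` returns a one-row summary.
#'
#' @param x A tumorlr result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tumorlr-tidiers
NULL

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_lr <- function(x, ...) x$per_locus

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_lr <- function(x, ...) {
  tibble(log10_lr = x$log10_lr, logL_hp = x$hp_fit$logL, logL_hd = x$hd_fit$logL,
         K = x$noc, mxn = x$mxn,
         hd_kind = unname(x$hypotheses["hd"]),
         mu_hp = x$hp_fit$params$mu, omega_hp = x$hp_fit$params$omega,
         epsilon_hp = x$hp_fit$params$epsilon,
         mu_hd = x$hd_fit$params$mu, omega_hd = x$hd_fit$params$omega,
         epsilon_hd = x$hd_fit$params$epsilon)
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_grid <- function(x, ...) {
  tidyr::expand_grid(i = seq_along(x$mxn_grid), j = seq_along(x$phi_grid)) |>
    dplyr::mutate(mxn = x$mxn_grid[.data$i], phi = x$phi_grid[.data$j],
                  log10_lr = x$log10_lr[cbind(.data$i, .data$j)]) |>
    dplyr::select("mxn", "phi", "log10_lr")
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_grid <- function(x, ...) {
  f <- x$fits
  tibble(
    lr_max = max(x$log10_lr, na.rm = TRUE), lr_min = min(x$log10_lr, na.rm = TRUE),
    mean_slope_mxn = mean(f$slope[f$axis == "mxn"], na.rm = TRUE),
    mean_slope_phi = mean(f$slope[f$axis == "phi"], na.rm = TRUE),
    min_abs_r_mxn = min(abs(f$pearson_r[f$axis == "mxn"]), na.rm = TRUE),
    min_abs_r_phi = min(abs(f$pearson_r[f$axis == "phi"]), na.rm = TRUE),
    n_missing = sum(!is.finite(x$log10_lr)))
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_interval <- function(x, ...) x$values

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_interval <- function(x, ...) {
  fit <- line_fit(x$values$mxn, x$values$log10_lr, "mxn", NA_real_)
  tibble(min = x$min, mean = x$mean, max = x$max,
         slope_mxn = fit$slope, pearson_r = fit$pearson_r)
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_noncontrib <- function(x, ...) x$values

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_noncontrib <- function(x, ...) {
  tibble(n = nrow(x$values), fraction_negative = x$fraction_negative,
         max_log10_lr = max(x$values$log10_lr),
         median_log10_lr = median(x$values$log10_lr))
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_qq <- function(x, ...) x$qq

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_qq <- function(x, ...) {
  tibble(shape = x$shape, rate = x$rate, scale = x$scale, n_loci = nrow(x$qq))
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::glance
glance.tlr_degfit <- function(x, ...) {
  tibble(per_base_slope = x$per_base_slope, p_deg = x$p_deg,
         intercept = x$intercept, epsilon = x$epsilon,
         include_degradation = x$include_degradation, n_loci = nrow(x$data))
}

#' @rdname tumorlr-tidiers
#' @exportS3Method generics::tidy
tidy.tlr_degfit <- function(x, ...) x$data
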