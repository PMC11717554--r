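#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kernel ranking into a Table-2-style tibble
#'
#' One row per successfully fitted family, in rank order (ascending SSE,
#' ties by BIC then name): family, parameters, SSE, BIC, mean establishment
#' distance (median for cauchy) and analytic skewness (`NA` where
#' undefined).
#'
#' @param x A `kernel_ranking` from [rank_fits()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kernel_ranking
#' @export
tidy.kernel_ranking <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy_kernel_fit_row))
}

tidy_kernel_fit_row <- function(fit) {
  tibble::tibble(
    family = fit$family,
    sse = fit$sse, bic = fit$bic,
    params = paste(sprintf("%.4f", fit$params), collapse = ", "),
    mean_distance = fit$mean_distance,
    skewness = fit$skewness,
    assumption = fit$assumption)
}

#' @rdname tidy.kernel_ranking
#' @method tidy kernel_fit
#' @export
tidy.kernel_fit <- function(x, ...) tidy_kernel_fit_row(x)

#' @method glance kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, loglik = x$loglik,
                 sse = x$sse, bic = x$bic)
}

#' Tidy the density GLM term table
#'
#' @param x A `density_glm`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` and, for the model terms, `partial_r2`.
#' @method tidy density_glm
#' @export
tidy.density_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(term = rownames(s), estimate = s[, 1],
                        std_error = s[, 2], statistic = s[, 3],
                        p_value = s[, 4])
  dplyr::left_join(out, x$partial_r2, by = "term")
}

#' @method glance density_glm
#' @export
glance.density_glm <- function(x, ...) {
  tibble::tibble(family = x$family, n_obs = x$n_obs,
                 r2 = x$r2[["r2"]], adj_r2 = x$r2[["adj_r2"]],
                 deviance = stats::deviance(x$fit),
                 aic = stats::AIC(x$fit))
}

#' @method tidy randomisation_result
#' @export
tidy.randomisation_result <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n) - 1,
                 median_luminance = c(x$observed_median, x$null_medians),
                 observed = c(TRUE, rep(FALSE, x$n - 1)))
}

#' @method glance randomisation_result
#' @export
glance.randomisation_result <- function(x, ...) {
  tibble::tibble(observed_median = x$observed_median,
                 null_median = stats::median(x$null_medians),
                 n = x$n, p_value = x$p_value, max_shift = x$max_shift,
                 seed = x$seed)
}

#' @method tidy occupancy_history
#' @export
tidy.occupancy_history <- function(x, ...) {
  tb <- as_tibble.spread_raster(x$mean_arrival)
  names(tb)[names(tb) == "value"] <- "mean_arrival"
  tb$n_colonised <- as.vector(x$n_colonised$values)
  tb
}
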