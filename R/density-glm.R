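#' GLM attribution of the density surface
#'
#' Regresses the per-cell normalised KDE density on z-score-normalised
#' predictors: distance from the station, distance from the closest trail,
#' elevation, and the station x trail interaction (computed from the
#' z-scored main effects). A positive interaction means the trail effect on
#' density strengthens near the station — the signature of a spread that
#' started at the station and travelled along the trails. Cells with
#' missing elevation (nodata) are excluded.
#'
#' @param density A `density_surface` from [kde_density()], or any
#'   `spread_raster` to use directly as the response.
#' @param dem Elevation raster on the same grid.
#' @param station `c(x, y)` station point.
#' @param trails Trails in any form accepted by [distance_to_trails()].
#' @param family `"gaussian"` (per the density-as-response reading) or
#'   `"poisson"` (quasi-count reading of the bounded density).
#' @param interaction Include the station x trail interaction term.
#' @return A `density_glm`: the fitted [stats::glm] plus term table,
#'   pseudo/adjusted R-squared and per-predictor partial R-squared.
#' @export
fit_density_glm <- function(density, dem, station, trails,
                            family = c("gaussian", "poisson"),
                            interaction = TRUE) {
  family <- match.arg(family)
  resp <- if (inherits(density, "density_surface")) density$raster else density
  spec <- resp$spec
  if (!same_spec(spec, dem$spec)) stop("density and dem are on different grids")
  d_station <- distance_to_point(spec, station)$values
  d_trail <- distance_to_trails(spec, trails)$values
  ok <- !is.na(dem$values)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant predictor; design would be rank-deficient")
    (v - mean(v)) / s
  }
  df <- data.frame(
    density = as.vector(resp$values)[ok],
    dist_station = zscore(as.vector(d_station)[ok]),
    dist_trail = zscore(as.vector(d_trail)[ok]),
    elevation = zscore(as.vector(dem$values)[ok]))
  form <- if (interaction) {
    density ~ dist_station * dist_trail + elevation
  } else {
    density ~ dist_station + dist_trail + elevation
  }
  fam_obj <- if (family == "gaussian") stats::gaussian() else stats::poisson()
  fit <- stats::glm(form, data = df, family = fam_obj)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  r2 <- model_r2(fit, family)
  out <- structure(
    list(fit = fit, family = family, n_obs = nrow(df), r2 = r2,
         data = df, formula = form),
    class = "density_glm")
  out$partial_r2 <- partial_r2(out)
  out
}

# Refit a glm on the same model frame with a subset of its terms
# (update() is avoided: it re-evaluates the original call in the wrong
# environment). An empty subset gives the intercept-only null model.
refit_glm <- function(fit, keep_terms) {
  df <- fit$model
  response <- names(df)[1]
  form <- if (length(keep_terms) == 0) {
    stats::reformulate("1", response = response)
  } else {
    stats::reformulate(keep_terms, response = response)
  }
  suppressWarnings(stats::glm(form, data = df, family = fit$family))
}

# Adjusted variance-explained summary: McFadden adjusted pseudo-R2
# (1 - (logL_full - k) / logL_null) for poisson; classical adjusted R2 for
# gaussian least squares, where the McFadden form is not meaningful.
model_r2 <- function(fit, family) {
  if (family == "gaussian") {
    y <- fit$model[[1]]
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    n <- length(y); k <- length(stats::coef(fit)) - 1
    r2 <- 1 - sse / sst
    c(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1))
  } else {
    # Poisson log-likelihood evaluated directly (lgamma continues log y!
    # to non-integer responses such as a normalised density)
    y <- fit$model[[1]]
    pois_ll <- function(mu) sum(y * log(mu) - mu - lgamma(y + 1))
    ll_full <- pois_ll(stats::fitted(fit))
    ll_null <- pois_ll(stats::fitted(refit_glm(fit, character(0))))
    k <- length(stats::coef(fit)) - 1
    c(r2 = 1 - ll_full / ll_null,
      adj_r2 = 1 - (ll_full - k) / ll_null)
  }
}

#' Per-predictor partial R-squared
#'
#' For each term of the fitted model, refits without that term (dropping
#' the interaction when a main effect involved in it is dropped) and
#' reports `(SSE_reduced - SSE_full) / SSE_reduced` for the gaussian family
#' and the deviance analogue `(Dev_reduced - Dev_full) / Dev_reduced` for
#' poisson: the share of the reduced model's unexplained variation that the
#' term accounts for.
#'
#' @param model A `density_glm`.
#' @return A tibble with `term` and `partial_r2`.
#' @export
partial_r2 <- function(model) {
  fit <- model$fit
  terms_all <- attr(stats::terms(fit), "term.labels")
  resid_stat <- function(f) {
    if (model$family == "gaussian") sum(stats::residuals(f)^2)
    else stats::deviance(f)
  }
  full_stat <- resid_stat(fit)
  pr2 <- vapply(terms_all, function(tm) {
    red <- refit_glm(fit, setdiff(terms_all, tm))
    red_stat <- resid_stat(red)
    if (red_stat == 0) stop("reduced model has zero residual variation for ", tm)
    (red_stat - full_stat) / red_stat
  }, numeric(1))
  tibble::tibble(term = terms_all, partial_r2 = unname(pr2))
}

#' @export
print.density_glm <- function(x, ...) {
  cat(sprintf("<density_glm> family %s, n = %d cells\n", x$family, x$n_obs))
  cat(sprintf("  %s = %.4f (adjusted %.4f)\n",
              if (x$family == "gaussian") "R2" else "McFadden R2",
              x$r2[["r2"]], x$r2[["adj_r2"]]))
  print(generics::tidy(x))
  invisible(x)
}
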