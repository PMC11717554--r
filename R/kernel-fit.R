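#' Establishment-distance samples
#'
#' A `distance_sample` holds one distance per established individual,
#' together with the source assumption under which the distances were built:
#' `"local"` (source = nearest other individual) or `"trail"` (source =
#' nearest individual lying on the trail).
#'
#' @param distances Numeric vector of non-negative distances (m).
#' @param assumption `"local"` or `"trail"`.
#' @return A `distance_sample` object.
#' @export
distance_sample <- function(distances, assumption = c("local", "trail")) {
  assumption <- match.arg(assumption)
  distances <- as.numeric(distances)
  stopifnot(all(is.finite(distances)), all(distances >= 0))
  structure(list(distances = distances, assumption = assumption,
                 n = length(distances)),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("<distance_sample> %s assumption, n = %d, mean %.2f m\n",
              x$assumption, x$n, mean(x$distances)))
  invisible(x)
}

# Minimum pairwise distance allowed. Records aggregate individuals within a
# 50-cm radius, so distances below half that radius are not resolvable;
# flooring also keeps log-support families finite for co-located pairs.
DIST_FLOOR <- 0.25

#' Establishment distances under the local-spread assumption
#'
#' Each individual's source is taken to be its nearest other individual.
#' Records are abundance-expanded: a record of abundance `k` stands for `k`
#' co-located individuals, so any individual sharing its point with another
#' gets the 0.25-m resolution floor as its nearest-neighbour distance.
#'
#' @param survey Occurrence tibble (see [occurrences()]).
#' @return A `distance_sample` with `assumption = "local"`.
#' @export
distances_local <- function(survey) {
  n_ind <- sum(survey$abundance)
  if (n_ind < 2) stop("need at least 2 individuals for local distances")
  xs <- survey$x; ys <- survey$y; k <- survey$abundance
  nn <- vapply(seq_along(xs), function(i) {
    if (k[i] >= 2) return(0)
    if (length(xs) == 1) return(Inf)
    min(sqrt((xs[-i] - xs[i])^2 + (ys[-i] - ys[i])^2))
  }, numeric(1))
  d <- pmax(nn, DIST_FLOOR)
  distance_sample(rep(d, times = k), "local")
}

#' Establishment distances under the trail-spread assumption
#'
#' Each off-trail individual's source is taken to be the nearest individual
#' on the trail (`plot_class == "trail"`); one distance per off-trail
#' individual after abundance expansion.
#'
#' @param survey Occurrence tibble with both trail and non-trail records.
#' @return A `distance_sample` with `assumption = "trail"`.
#' @export
distances_from_trail <- function(survey) {
  on <- survey[survey$plot_class == "trail", ]
  off <- survey[survey$plot_class != "trail", ]
  if (nrow(on) == 0) stop("no on-trail individuals to act as sources")
  if (nrow(off) == 0) stop("no off-trail individuals")
  d <- vapply(seq_len(nrow(off)), function(i) {
    min(sqrt((on$x - off$x[i])^2 + (on$y - off$y[i])^2))
  }, numeric(1))
  d <- pmax(d, DIST_FLOOR)
  distance_sample(rep(d, times = off$abundance), "trail")
}

#' Construct a fitted kernel from known parameters
#'
#' Builds a `kernel_fit` directly from a family name and parameter vector
#' (scipy order: shape if any, then location, then scale) — e.g. to plug in
#' a published parameter table — computing the mean establishment distance
#' (median for cauchy) and, where defined, the analytic skewness.
#'
#' @param family Family name (see [kernel_family_names()]) or a
#'   `kernel_family`.
#' @param params Numeric parameter vector.
#' @param sse,bic,loglik,n Optional fit statistics.
#' @param assumption Optional source assumption tag.
#' @return A `kernel_fit` object.
#' @export
kernel_fit <- function(family, params, sse = NA_real_, bic = NA_real_,
                       loglik = NA_real_, n = NA_integer_,
                       assumption = NA_character_) {
  fam <- if (inherits(family, "kernel_family")) family else kernel_family(family)
  p <- split_params(fam, params)
  if (p$scale <= 0) stop("scale must be > 0")
  fit <- structure(
    list(family = fam$name, params = stats::setNames(as.numeric(params), fam$param_names),
         sse = sse, bic = bic, loglik = loglik, n = n,
         assumption = assumption),
    class = "kernel_fit")
  fit$mean_distance <- kernel_mean(fit)
  fit$skewness <- tryCatch(kernel_skewness(fit, "analytic"),
                           error = function(e) NA_real_)
  fit
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> %s(%s)\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", ")))
  cat(sprintf("  mean distance %.2f m, skewness %s, SSE %.4g, BIC %.4g\n",
              x$mean_distance,
              if (is.na(x$skewness)) "undefined" else sprintf("%.2f", x$skewness),
              x$sse, x$bic))
  invisible(x)
}

fit_histogram <- function(distances) {
  # Sturges bins on [0, max distance], density-normalised
  n <- length(distances)
  n_bins <- ceiling(log2(n)) + 1
  breaks <- seq(0, max(distances) * (1 + 1e-12), length.out = n_bins + 1)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, breaks = breaks)
}

sse_against_histogram <- function(fam, params, hist) {
  sum((hist$density - fam$pdf(hist$mids, params))^2)
}

#' Fit one kernel family to an establishment-distance sample
#'
#' Parameters are estimated by maximum likelihood (Nelder-Mead on a
#' support-constrained reparameterisation: for families supported on
#' `x > location` the location is kept strictly below the sample minimum).
#' The reported SSE — used for ranking candidate families — is the sum of
#' squared differences between the density-normalised distance histogram
#' (Sturges bins on `[0, max]`) and the fitted pdf at the bin centres.
#' `method = "sse"` instead minimises that histogram SSE directly, for
#' fidelity experiments with SSE-based fitters.
#'
#' @param sample A [distance_sample()] with at least 10 distances.
#' @param family Family name or `kernel_family`.
#' @param method `"ml"` (default) or `"sse"`.
#' @return A `kernel_fit`.
#' @export
fit_family <- function(sample, family, method = c("ml", "sse")) {
  method <- match.arg(method)
  fam <- if (inherits(family, "kernel_family")) family else kernel_family(family)
  x <- sample$distances
  n <- length(x)
  if (n < 10) stop("need n >= 10 distances to fit (got ", n, ")")
  hist <- fit_histogram(x)

  xmin <- min(x)
  # theta is unconstrained; map to valid (shape, loc, scale)
  decode <- function(theta) {
    if (fam$bounded_support) loc <- xmin - exp(theta[fam$n_params - 1])
    else loc <- theta[fam$n_params - 1]
    scale <- exp(theta[fam$n_params])
    if (fam$has_shape) c(exp(theta[1]), loc, scale) else c(loc, scale)
  }
  encode <- function(params) {
    p <- split_params(fam, params)
    loc_t <- if (fam$bounded_support) log(max(xmin - p$loc, 1e-8)) else p$loc
    if (fam$has_shape) c(log(p$shape), loc_t, log(p$scale))
    else c(loc_t, log(p$scale))
  }
  objective <- if (method == "ml") {
    function(theta) {
      ll <- fam$logpdf(x, decode(theta))
      if (any(!is.finite(ll))) return(1e10)
      -sum(ll)
    }
  } else {
    function(theta) sse_against_histogram(fam, decode(theta), hist)
  }

  loc0 <- xmin - max(stats::sd(x), 1) * 0.05
  starts <- list(fam$start(x, loc0))
  # a second, more cautious start further below the minimum
  loc1 <- xmin - max(stats::sd(x), 1) * 0.5
  starts <- c(starts, list(fam$start(x, loc1)))

  best <- NULL
  last_obj <- NA_real_
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(encode(s), objective, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    last_obj <- opt$value
    if (opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop(sprintf("optimiser failed to converge for family '%s' (last objective %.4g)",
                 fam$name, last_obj))
  }
  params <- decode(best$par)
  ll <- sum(fam$logpdf(x, params))
  kernel_fit(fam, params,
             sse = sse_against_histogram(fam, params, hist),
             bic = fam$n_params * log(n) - 2 * ll,
             loglik = ll, n = n, assumption = sample$assumption)
}

#' Fit and rank all candidate kernel families
#'
#' Fits every requested family to the sample and orders the successful fits
#' by ascending histogram SSE, breaking ties by BIC and then family name.
#' Families whose optimiser fails are reported in the `failures` attribute
#' rather than aborting the ranking.
#'
#' @param sample A [distance_sample()].
#' @param families Character vector of family names (default: all six).
#' @param method Passed to [fit_family()].
#' @return A `kernel_ranking`: a list of `kernel_fit`s in rank order, with
#'   attributes `failures` (named character vector of error messages) and
#'   `assumption`.
#' @export
rank_fits <- function(sample, families = kernel_family_names(),
                      method = c("ml", "sse")) {
  method <- match.arg(method)
  fits <- list(); failures <- character()
  for (nm in families) {
    res <- tryCatch(fit_family(sample, nm, method = method),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "kernel_fit")) fits[[nm]] <- res
    else failures[nm] <- res
  }
  if (length(fits) == 0) stop("all kernel families failed to fit")
  ord <- order(vapply(fits, `[[`, numeric(1), "sse"),
               vapply(fits, `[[`, numeric(1), "bic"),
               names(fits))
  structure(fits[ord], class = "kernel_ranking",
            failures = failures, assumption = sample$assumption)
}

#' @export
print.kernel_ranking <- function(x, ...) {
  cat(sprintf("<kernel_ranking> %s assumption, %d fits\n",
              attr(x, "assumption"), length(x)))
  print(generics::tidy(x))
  invisible(x)
}

#' Mean establishment distance of a fitted kernel
#'
#' Closed forms where they exist: lognormal `loc + scale * exp(shape^2/2)`,
#' exponential `loc + scale`, rayleigh `loc + scale * sqrt(pi/2)`,
#' chi-square `loc + shape * scale`. The cauchy mean is undefined, so its
#' median (= location) is returned, matching how heavy-tailed fits are
#' reported. The exponential-power mean is integrated numerically
#' (adaptive quadrature, tolerance 1e-8).
#'
#' @param fit A `kernel_fit`.
#' @return Mean (or, for cauchy, median) establishment distance in metres.
#' @export
kernel_mean <- function(fit) {
  fam <- kernel_family(fit$family)
  p <- split_params(fam, fit$params)
  if (identical(fam$mean_fn, NA)) return(p$loc)      # cauchy: median
  if (is.function(fam$mean_fn)) return(fam$mean_fn(p))
  mom <- numeric_standard_moments(fam, p$shape)
  p$loc + p$scale * mom$mean
}

#' Skewness of a fitted kernel
#'
#' High positive skewness flags a fat upper tail, i.e. a higher chance of
#' rare long-distance establishment events relative to the common
#' mean-distance events.
#'
#' @param fit A `kernel_fit`.
#' @param method `"analytic"` (standardised third central moment; errors for
#'   cauchy whose moments are undefined) or `"sample"` (moment skewness of
#'   pseudo-random draws).
#' @param n_draws Number of draws for `method = "sample"` (>= 1e4).
#' @param seed RNG seed, required for `method = "sample"`.
#' @return Dimensionless skewness.
#' @export
kernel_skewness <- function(fit, method = c("analytic", "sample"),
                            n_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  fam <- kernel_family(fit$family)
  p <- split_params(fam, fit$params)
  if (method == "analytic") {
    if (identical(fam$skewness_fn, NA)) {
      stop("analytic skewness is undefined for the ", fam$name, " family")
    }
    if (is.function(fam$skewness_fn)) return(fam$skewness_fn(p))
    return(numeric_standard_moments(fam, p$shape)$skewness)
  }
  if (n_draws < 1e4) stop("sample skewness needs n_draws >= 1e4")
  if (is.null(seed)) stop("sample skewness needs an explicit seed")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  z <- fam$sampler(n_draws, fit$params)
  m <- mean(z)
  mean((z - m)^3) / mean((z - m)^2)^1.5
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
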