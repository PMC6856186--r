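# Ordinary kriging with an explicit variogram, on great-circle distances.
# Used to extend the log-concentration surface to unmeasured countries.

#' Variogram specification
#'
#' Semivariance models for ordinary kriging of log-concentrations.
#' Exponential: `nugget + psill * (1 - exp(-h / range))`;
#' spherical: the usual bounded polynomial up to `range`;
#' gaussian: `nugget + psill * (1 - exp(-(h / range)^2))`,
#' where `psill = sill - nugget` is the partial sill.
#'
#' @param model One of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget Nugget variance (>= 0), log-concentration scale.
#' @param sill Total sill (> 0, >= nugget).
#' @param range Range parameter in km (> 0).
#' @return Object of class `ricehg_variogram`.
#' @export
variogram_spec <- function(model = c("exponential", "spherical", "gaussian"),
                           nugget, sill, range) {
  model <- match.arg(model)
  stopifnot(nugget >= 0, sill > 0, sill >= nugget, range > 0)
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "ricehg_variogram")
}

semivariance <- function(spec, h) {
  psill <- spec$sill - spec$nugget
  g <- switch(spec$model,
    exponential = psill * (1 - exp(-h / spec$range)),
    spherical = ifelse(h >= spec$range, psill,
                       psill * (1.5 * h / spec$range - 0.5 * (h / spec$range)^3)),
    gaussian = psill * (1 - exp(-(h / spec$range)^2))
  )
  out <- spec$nugget + g
  out[h == 0] <- 0  # gamma(0) = 0 by definition; the nugget acts off-origin
  out
}

#' Great-circle distance matrix in km
#'
#' Haversine distances between two sets of (lat, lon) points.
#'
#' @param a,b Data frames with `lat` and `lon` in decimal degrees.
#' @return Matrix of distances, `nrow(a)` x `nrow(b)`, in km.
#' @export
great_circle_km <- function(a, b = a) {
  pa <- cbind(a$lon, a$lat)
  pb <- cbind(b$lon, b$lat)
  m <- matrix(0, nrow(pa), nrow(pb))
  for (j in seq_len(nrow(pb))) {
    m[, j] <- geosphere::distHaversine(pa, pb[j, , drop = TRUE]) / 1000
  }
  m
}

#' Empirical variogram of georeferenced values
#'
#' Bins squared half-differences of the value by great-circle distance.
#'
#' @param samples Data frame with `lat`, `lon`, `value`.
#' @param n_bins Number of distance bins.
#' @param max_dist Maximum pair distance considered; default half the
#'   maximum pairwise distance.
#' @return Tibble with `dist` (bin centre, km), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(samples, n_bins = 12L, max_dist = NULL) {
  stopifnot(nrow(samples) >= 2L)
  d <- great_circle_km(samples)
  v <- samples$value
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]
  g <- 0.5 * (v[iu[, 1]] - v[iu[, 2]])^2
  if (is.null(max_dist)) max_dist <- max(h) / 2
  keep <- h > 0 & h <= max_dist
  h <- h[keep]; g <- g[keep]
  if (length(h) == 0L) stop("no usable point pairs for the variogram", call. = FALSE)
  br <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(h, br, include.lowest = TRUE, labels = FALSE)
  tibble::tibble(
    dist = tapply(h, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.integer(table(factor(bin, levels = sort(unique(bin)))))
  )
}

#' Fit an exponential variogram by weighted least squares
#'
#' Fits nugget, sill and range of an exponential model to the empirical
#' variogram, weighting each bin by its pair count. If the optimiser fails
#' or the fit degenerates, falls back to nugget 0, sill = variance of the
#' values, and range = one-third of the domain diameter.
#'
#' @param samples Data frame with `lat`, `lon`, `value`.
#' @param n_bins Bins passed to [empirical_variogram()].
#' @return A `ricehg_variogram` (exponential).
#' @export
fit_variogram <- function(samples, n_bins = 12L) {
  diam <- max(great_circle_km(samples))
  fallback <- variogram_spec("exponential", nugget = 0,
                             sill = max(stats::var(samples$value), 1e-8),
                             range = max(diam / 3, 1))
  ev <- tryCatch(empirical_variogram(samples, n_bins = n_bins),
                 error = function(e) NULL)
  if (is.null(ev) || nrow(ev) < 3L) return(fallback)
  obj <- function(par) {
    sp <- variogram_spec("exponential", nugget = exp(par[1]),
                         sill = exp(par[1]) + exp(par[2]), range = exp(par[3]))
    sum(ev$n_pairs * (semivariance(sp, ev$dist) - ev$gamma)^2)
  }
  s0 <- max(mean(ev$gamma), 1e-8)
  fit <- tryCatch(
    stats::optim(c(log(s0 / 10), log(s0), log(max(diam / 3, 1))), obj),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value)) return(fallback)
  p <- fit$par
  variogram_spec("exponential", nugget = exp(p[1]),
                 sill = exp(p[1]) + exp(p[2]), range = exp(p[3]))
}

#' Ordinary kriging to target locations
#'
#' Solves the ordinary-kriging system (unbiasedness constraint: weights sum
#' to one) for each target from the variogram in `spec`. With a zero nugget
#' the predictor interpolates exactly: prediction at a sampled location
#' equals that sample. Values are typically log-concentrations; predictions
#' are returned on the same scale.
#'
#' @param samples Data frame with `lat`, `lon`, `value`; no duplicate
#'   coordinates allowed.
#' @param targets Data frame with `lat`, `lon` (extra columns carried
#'   through).
#' @param spec A `ricehg_variogram`.
#' @return `targets` with added `prediction`, `kriging_se` (square root of
#'   the kriging variance) and an attribute `"weights"` (matrix, one row
#'   per target; each row sums to 1).
#' @export
krige_country_surface <- function(samples, targets, spec) {
  stopifnot(inherits(spec, "ricehg_variogram"), nrow(samples) >= 2L)
  ds <- great_circle_km(samples)
  if (any(ds[upper.tri(ds)] < 1e-9)) {
    stop("duplicate sample coordinates make the kriging system singular",
         call. = FALSE)
  }
  n <- nrow(samples)
  G <- semivariance(spec, ds)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- great_circle_km(samples, targets)
  g0 <- rbind(semivariance(spec, d0), 1)
  sol <- tryCatch(solve(A, g0), error = function(e) {
    stop("singular kriging system", call. = FALSE)
  })
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- as.numeric(crossprod(w, samples$value))
  krig_var <- pmax(colSums(w * semivariance(spec, d0)) + mu, 0)
  out <- tibble::as_tibble(targets)
  out$prediction <- pred
  out$kriging_se <- sqrt(krig_var)
  attr(out, "weights") <- t(w)
  out
}

#' Leave-one-out cross-validation of the kriging surface
#'
#' Predicts each sample from all others and reports the squared correlation
#' between observed and predicted values, a plausibility check on the
#' interpolation.
#'
#' @param samples Data frame with `lat`, `lon`, `value`.
#' @param spec Variogram; `NULL` fits one per leave-out from the full set.
#' @return List with `r2` and the per-sample `predicted` vector.
#' @export
krige_loo <- function(samples, spec = NULL) {
  n <- nrow(samples)
  stopifnot(n >= 3L)
  if (is.null(spec)) spec <- fit_variogram(samples)
  pred <- vapply(seq_len(n), function(i) {
    kr <- krige_country_surface(samples[-i, ], samples[i, c("lat", "lon")], spec)
    kr$prediction
  }, numeric(1))
  list(r2 = stats::cor(samples$value, pred)^2, predicted = pred)
}
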