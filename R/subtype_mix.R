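# Soma-size subtype classification. One- or two-component Gaussian curves
# are fitted to the binned size histogram by nonlinear least squares (the
# histogram fit is canonical, mirroring curve fitting on histogram counts;
# it is not an EM fit on raw samples). With two components, the
# x-coordinate of the intersection of the two fitted curves defines the
# threshold: somata strictly below it are putative gamma motoneurons,
# somata at or above it putative alpha motoneurons.

bin_centers <- function(hist) {
  (head(hist$bin_edges, -1) + hist$bin_edges[-1]) / 2
}

gauss_curve <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))

# deterministic initialisation: the two largest local maxima of the
# 3-bin-smoothed histogram separated by >= 3 bins; sigma init = 2 bins
init_two_components <- function(x, y) {
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_peak <- ys > 0 &
    ys >= c(-Inf, ys[-n]) &
    ys >= c(ys[-1], -Inf)
  peaks <- which(is_peak)[order(ys[is_peak], decreasing = TRUE)]
  if (length(peaks) >= 2) {
    p1 <- peaks[1]
    p2 <- peaks[which(abs(peaks - p1) >= 3)[1]]
  } else {
    p1 <- p2 <- NA
  }
  if (is.na(p2) || length(p1) == 0) {
    # flat/degenerate smoothed shape: spread inits by distribution quantiles
    cdf <- cumsum(y) / sum(y)
    p1 <- which(cdf >= 0.25)[1]
    p2 <- which(cdf >= 0.75)[1]
    if (p2 - p1 < 3) { p1 <- max(1, p1 - 2); p2 <- min(n, p2 + 2) }
  }
  lo <- min(p1, p2); hi <- max(p1, p2)
  list(A1 = max(ys[lo], 1), mu1 = x[lo], s1 = 2 * diff(x[1:2]),
       A2 = max(ys[hi], 1), mu2 = x[hi], s2 = 2 * diff(x[1:2]))
}

#' Fit Gaussian curves to a soma-size histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the bin counts at bin
#' centres against a sum of `n_components` Gaussian curves
#' `A * exp(-(x - mu)^2 / (2 sigma^2))`, with positive-bounded parameters
#' and means constrained to the histogram range. Initialisation is
#' deterministic (see Details), so the fit is reproducible.
#'
#' @details For two components the initial means are the two largest local
#' maxima of the 3-bin-smoothed histogram at least 3 bins apart (falling
#' back to the 25th/75th percentile bins), initial sigmas are 2 bin widths.
#' Components are returned ordered by mean.
#'
#' @param hist a `size_histogram` from [histogram_volumes()].
#' @param n_components 1 or 2 (2 requires >= 6 nonzero bins).
#' @return a `mixture_fit`: list with `n_components`, `A`, `mu`, `sigma`,
#'   `rss`, `bic`, and for two components `threshold_um3` plus
#'   `threshold_fallback` (TRUE when the curves do not cross between the
#'   means and the minimum of the summed curves was used instead).
#' @export
fit_gaussians <- function(hist, n_components = 2) {
  stopifnot(inherits(hist, "size_histogram"))
  if (!n_components %in% c(1, 2)) stop_param("n_components must be 1 or 2")
  x <- bin_centers(hist)
  y <- as.numeric(hist$counts)
  if (all(y == 0)) stop_data("all-zero histogram: nothing to fit")
  if (n_components == 2 && sum(y > 0) < 6)
    stop_data("two-component fit requires >= 6 nonzero bins")
  rng <- range(hist$bin_edges)
  bw <- diff(x[1:2])
  if (n_components == 1) {
    mu0 <- sum(x * y) / sum(y)
    s0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
    s0 <- max(s0, bw / 2)
    fit <- minpack.lm::nlsLM(
      y ~ gauss_curve(x, A1, mu1, s1),
      start = list(A1 = max(y), mu1 = mu0, s1 = s0),
      lower = c(1e-9, rng[1], bw / 10), upper = c(Inf, rng[2], diff(rng)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    A <- cf[["A1"]]; mu <- cf[["mu1"]]; sig <- cf[["s1"]]
  } else {
    ini <- init_two_components(x, y)
    fit <- minpack.lm::nlsLM(
      y ~ gauss_curve(x, A1, mu1, s1) + gauss_curve(x, A2, mu2, s2),
      start = ini,
      lower = c(1e-9, rng[1], bw / 10, 1e-9, rng[1], bw / 10),
      upper = c(Inf, rng[2], diff(rng), Inf, rng[2], diff(rng)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    A <- c(cf[["A1"]], cf[["A2"]])
    mu <- c(cf[["mu1"]], cf[["mu2"]])
    sig <- c(cf[["s1"]], cf[["s2"]])
    o <- order(mu)
    A <- A[o]; mu <- mu[o]; sig <- sig[o]
  }
  rss <- sum(residuals(fit)^2)
  nb <- length(y)
  out <- structure(list(n_components = n_components, A = unname(A),
                        mu = unname(mu), sigma = unname(sig), rss = rss,
                        bic = nb * log(max(rss, 1e-12) / nb) +
                          (3 * n_components) * log(nb)),
                   class = "mixture_fit")
  if (n_components == 2) {
    thr <- intersection_threshold(out)
    out$threshold_um3 <- as.numeric(thr)
    out$threshold_fallback <- isTRUE(attr(thr, "fallback"))
  }
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d component(s)\n", x$n_components))
  for (i in seq_len(x$n_components))
    cat(sprintf("  A=%.1f mu=%.0f sigma=%.0f\n", x$A[i], x$mu[i], x$sigma[i]))
  if (!is.null(x$threshold_um3))
    cat(sprintf("  threshold = %.1f um3%s\n", x$threshold_um3,
                if (isTRUE(x$threshold_fallback)) " (fallback: curve minimum)" else ""))
  invisible(x)
}

#' Assess modality of a soma-size histogram
#'
#' Fits one- and two-component models and returns 2 iff the BIC improvement
#' of the two-component fit exceeds `delta_bic_margin` AND the fitted means
#' are separated by more than the sum of the fitted sigmas; otherwise 1.
#' The evidence (delta BIC and both fits) is attached as attributes, so an
#' underpowered histogram still yields a recorded decision rather than an
#' error.
#'
#' @param hist a `size_histogram`.
#' @param delta_bic_margin required BIC margin (default 10).
#' @return integer 1 or 2 with attributes `delta_bic`, `fit1`, `fit2`.
#' @export
assess_modality <- function(hist, delta_bic_margin = 10) {
  fit1 <- fit_gaussians(hist, 1)
  fit2 <- tryCatch(fit_gaussians(hist, 2), error = function(e) NULL)
  if (is.null(fit2)) {
    out <- 1L
    attr(out, "delta_bic") <- NA_real_
    attr(out, "fit1") <- fit1
    return(out)
  }
  delta <- fit1$bic - fit2$bic
  separated <- diff(fit2$mu) > sum(fit2$sigma)
  out <- if (delta > delta_bic_margin && separated) 2L else 1L
  attr(out, "delta_bic") <- delta
  attr(out, "fit1") <- fit1
  attr(out, "fit2") <- fit2
  out
}

#' Intersection threshold of a two-component fit
#'
#' The x-coordinate where the two fitted Gaussian curves intersect, located
#' by bisection of `A1 g1(x) - A2 g2(x)` on the open interval between the
#' means. If the curves do not cross between the means (heavy overlap), the
#' threshold falls back to the minimum of the summed curves on that
#' interval and the result carries attribute `fallback = TRUE`.
#'
#' @param fit a two-component `mixture_fit`.
#' @return threshold in µm³ (numeric, possibly with attribute `fallback`).
#' @export
intersection_threshold <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$n_components != 2)
    stop_param("intersection threshold requires a two-component fit")
  A <- fit$A; mu <- fit$mu; sig <- fit$sigma
  g <- function(x) gauss_curve(x, A[1], mu[1], sig[1]) -
    gauss_curve(x, A[2], mu[2], sig[2])
  eps <- diff(mu) * 1e-6
  xs <- seq(mu[1] + eps, mu[2] - eps, length.out = 512)
  gs <- g(xs)
  sgn <- sign(gs)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) == 0) {
    exact <- which(gs == 0)
    if (length(exact) > 0) return(xs[exact[1]])
    opt <- stats::optimize(function(x)
      gauss_curve(x, A[1], mu[1], sig[1]) + gauss_curve(x, A[2], mu[2], sig[2]),
      interval = c(mu[1], mu[2]))
    out <- opt$minimum
    attr(out, "fallback") <- TRUE
    return(out)
  }
  lo <- xs[cross[1]]; hi <- xs[cross[1] + 1]
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
  root
}

#' Classify somata by the size threshold
#'
#' Somata with volume strictly below the threshold are putative gamma
#' motoneurons; somata at or above it (ties included) putative alpha
#' motoneurons. These are size classes only, not validated identities.
#'
#' @param records data.frame with at least `volume_um3` (ids and centroids
#'   are carried through when present), e.g. from [measure_somas()].
#' @param threshold_um3 positive size threshold (µm³).
#' @return list with `calls` (records plus a `class` column) and
#'   `small_fraction` (gamma count / total; `NA` for empty input).
#' @export
classify_somas <- function(records, threshold_um3) {
  if (!is.numeric(threshold_um3) || threshold_um3 <= 0)
    stop_param("threshold must be > 0")
  if (nrow(records) == 0L) {
    calls <- records
    calls$class <- character(0)
    return(list(calls = calls, small_fraction = NA_real_))
  }
  cls <- ifelse(records$volume_um3 < threshold_um3,
                "putative_gamma", "putative_alpha")
  calls <- records
  calls$class <- factor(cls, levels = c("putative_gamma", "putative_alpha"))
  list(calls = calls,
       small_fraction = mean(cls == "putative_gamma"))
}

#' Sphere table and regional summaries for 3D rendering
#'
#' One sphere per soma: centroid, class and the volume-equivalent sphere
#' radius `(3 V / (4 pi))^(1/3)`, suitable for any 3D viewer. Optional
#' axis-aligned boxes yield per-region class counts, supporting inspection
#' of spatially non-uniform subtype distributions.
#'
#' @param calls classified records (the `calls` element of
#'   [classify_somas()]), needing `volume_um3`, `class` and centroid columns
#'   `cz_um`, `cy_um`, `cx_um`.
#' @param boxes optional data.frame with columns name, z0, z1, y0, y1, x0,
#'   x1 (µm).
#' @return list with `spheres` (data.frame) and `regions` (data.frame or
#'   NULL).
#' @export
spatial_call_table <- function(calls, boxes = NULL) {
  if (nrow(calls) == 0L) stop_param("no calls to tabulate")
  spheres <- data.frame(
    id = if (!is.null(calls$id)) calls$id else seq_len(nrow(calls)),
    cz_um = calls$cz_um, cy_um = calls$cy_um, cx_um = calls$cx_um,
    class = calls$class,
    radius_um = (3 * calls$volume_um3 / (4 * pi))^(1 / 3))
  regions <- NULL
  if (!is.null(boxes)) {
    regions <- do.call(rbind, lapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      sel <- calls$cz_um >= b$z0 & calls$cz_um <= b$z1 &
        calls$cy_um >= b$y0 & calls$cy_um <= b$y1 &
        calls$cx_um >= b$x0 & calls$cx_um <= b$x1
      data.frame(name = b$name,
                 n_gamma = sum(calls$class[sel] == "putative_gamma"),
                 n_alpha = sum(calls$class[sel] == "putative_alpha"))
    }))
  }
  list(spheres = spheres, regions = regions)
}

#' Simulate-and-recover a subtype proportion
#'
#' The core correctness check of the classification chain: draws `n` soma
#' volumes from a well-separated two-component mixture with small-component
#' weight `w`, bins them on the standard 0-38,000 µm³ grid, fits two
#' Gaussian curves, thresholds at the curve intersection, classifies, and
#' returns the fraction called small, averaged over `n_replicates` seeded
#' replicates.
#'
#' @param w small-component weight in (0, 1).
#' @param n soma count per replicate.
#' @param n_replicates number of replicates (default 20).
#' @param mixture mixture shape; the default uses means 4,000 and 15,000 µm³
#'   with SDs 1,200 and 4,000 µm³.
#' @param seed root seed; replicate r uses `seed + r`.
#' @return list with `mean_small_fraction`, `per_replicate` (numeric
#'   vector), `thresholds`.
#' @export
recover_small_fraction <- function(w, n, n_replicates = 20,
                                   mixture = list(mean1 = 4000, sd1 = 1200,
                                                  mean2 = 15000, sd2 = 4000),
                                   seed = 1L) {
  fr <- numeric(n_replicates)
  th <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    mix <- c(list(w = w), mixture)
    draws <- sample_volume_mixture(n, mix, seed = seed + r)
    hist <- histogram_volumes(draws$volume_um3)
    fit <- fit_gaussians(hist, 2)
    cl <- classify_somas(data.frame(volume_um3 = draws$volume_um3),
                         fit$threshold_um3)
    fr[r] <- cl$small_fraction
    th[r] <- fit$threshold_um3
  }
  list(mean_small_fraction = mean(fr), per_replicate = fr, thresholds = th)
}
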