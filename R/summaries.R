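#' Uniform grid of inter-cell distances
#'
#' @param r_max Largest distance (microns).
#' @param n_points Number of grid points, default 64.
#' @param r_min Smallest distance, default 0.
#' @return An object of class `r_grid`: numeric vector with attribute
#'   `spacing`.
#' @export
r_grid <- function(r_max, n_points = 64, r_min = 0) {
  stopifnot(r_max > r_min, r_min >= 0, n_points >= 2)
  r <- seq(r_min, r_max, length.out = n_points)
  structure(r, spacing = r[2] - r[1], class = "r_grid")
}

.as_rgrid <- function(grid) {
  if (inherits(grid, "r_grid")) return(grid)
  r <- as.numeric(grid)
  stopifnot(length(r) >= 2, all(r >= 0), all(diff(r) > 0))
  h <- diff(r)
  if (max(abs(h - h[1])) > 1e-9 * max(h)) {
    stop("distance grid must be uniformly spaced", call. = FALSE)
  }
  structure(r, spacing = h[1], class = "r_grid")
}

.new_curve <- function(grid, values, kind, type_pair = NULL, mark = NULL,
                       meta = list()) {
  structure(list(r = as.numeric(grid), values = as.numeric(values),
                 kind = kind, type_pair = type_pair, mark = mark, meta = meta),
            class = "summary_curve")
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary curve '%s' on %d distances in [%g, %g]\n",
              x$kind, length(x$r), min(x$r), max(x$r)))
  if (!is.null(x$type_pair))
    cat("type pair:", paste(x$type_pair, collapse = " - "), "\n")
  if (!is.null(x$mark)) cat("mark:", x$mark, "\n")
  invisible(x)
}

#' Empirical intensities of a marked point pattern
#'
#' Intensities are estimated as point counts divided by the window area.
#' When a `pair` of types is given, the unmarked intensity reported in
#' `lambda_dot` is the sum of the two type intensities.
#'
#' @param pattern An [mpp()].
#' @param pair Optional length-2 character vector of types; adds the pooled
#'   `lambda_dot` for that pair.
#' @return Named numeric vector of per-type intensities (points per squared
#'   micron); if `pair` is given, the element `lambda_dot` is appended.
#' @export
estimate_intensities <- function(pattern, pair = NULL) {
  stopifnot(inherits(pattern, "mpp"))
  area <- window_area(pattern$window)
  counts <- table(pattern$type)
  out <- as.numeric(counts) / area
  names(out) <- names(counts)
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2)
    lam <- sum(out[pair], na.rm = TRUE)
    out <- c(out, lambda_dot = lam)
  }
  out
}

# --- pairwise geometry -----------------------------------------------------

# All unordered point pairs with distance <= rmax, with translation-correction
# weights |W| / ((a - |dx|)(b - |dy|)). Columns: i, j (point indices), d, w.
.close_pairs <- function(pattern, rmax, correction = "translation") {
  n <- npoints(pattern)
  if (n < 2) {
    return(list(i = integer(), j = integer(), d = numeric(), w = numeric()))
  }
  x <- pattern$x; y <- pattern$y
  d <- as.vector(stats::dist(cbind(x, y)))
  # index bookkeeping for the condensed lower triangle of dist()
  ii <- rep.int(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  keep <- d <= rmax
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  if (correction == "translation") {
    w <- pattern$window
    a <- w$xmax - w$xmin; b <- w$ymax - w$ymin
    wgt <- (a * b) / ((a - abs(x[ii] - x[jj])) * (b - abs(y[ii] - y[jj])))
  } else if (correction == "none") {
    wgt <- rep(1, length(d))
  } else {
    stop("unknown edge correction: ", correction, call. = FALSE)
  }
  list(i = ii, j = jj, d = d, w = wgt)
}

.epanechnikov <- function(u, h) {
  k <- 0.75 / h * (1 - (u / h)^2)
  k[abs(u) > h] <- 0
  k
}

# Kernel-weighted pair sums: for each grid point r, sum of w * k_h(d - r)
# over the supplied pairs. Exact (no binning); pairs are pre-sorted by d and
# only those inside the kernel support contribute.
.kernel_pair_sums <- function(d, w, grid, h) {
  ord <- order(d)
  ds <- d[ord]; ws <- w[ord]
  lo <- findInterval(grid - h, ds) + 1L
  hi <- findInterval(grid + h, ds)
  out <- numeric(length(grid))
  for (t in seq_along(grid)) {
    if (hi[t] >= lo[t]) {
      idx <- lo[t]:hi[t]
      out[t] <- sum(ws[idx] * .epanechnikov(ds[idx] - grid[t], h))
    }
  }
  out
}

.stoyan_bandwidth <- function(lambda) 0.15 / sqrt(lambda)

.resolve_types <- function(pattern, types) {
  labs <- levels(pattern$type)
  if (identical(types, "all")) return(list(mode = "all"))
  if (length(types) == 1) {
    stopifnot(types %in% labs)
    return(list(mode = "single", i = types))
  }
  stopifnot(length(types) == 2, all(types %in% labs))
  list(mode = "cross", i = types[1], j = types[2])
}

# --- K function ------------------------------------------------------------

#' Ripley's K function and its cross-type variant
#'
#' `K(r)` is the expected number of further points within distance `r` of a
#' typical point, normalized by intensity; under complete spatial randomness
#' `K(r) = pi r^2`. The cross-type version `K_ij(r)` counts points of type
#' `j` around points of type `i`, normalized by `lambda_i lambda_j |W|`.
#' Edge effects are handled by the translation correction
#' `|W| / ((a - |dx|)(b - |dy|))`, well-defined for rectangular windows.
#'
#' @param pattern An [mpp()].
#' @param grid An [r_grid()] (or uniformly spaced numeric vector).
#' @param types `"all"` (whole pattern, default), a single type label, or a
#'   length-2 vector `c(i, j)` for the cross-type version.
#' @param correction `"translation"` (default) or `"none"`.
#' @return A `summary_curve` of kind `"K"` or `"crossK"`.
#' @export
k_function <- function(pattern, grid, types = "all",
                       correction = "translation") {
  grid <- .as_rgrid(grid)
  tp <- .resolve_types(pattern, types)
  p <- switch(tp$mode,
              all = pattern,
              single = .subset_mpp(pattern, pattern$type == tp$i),
              cross = .subset_mpp(pattern, pattern$type %in% c(tp$i, tp$j)))
  area <- window_area(p$window)
  if (tp$mode == "cross") {
    ni <- npoints(p, tp$i); nj <- npoints(p, tp$j)
    if (ni < 1 || nj < 1) stop("need at least one point of each type",
                               call. = FALSE)
    if (ni + nj < 2) stop("need at least 2 points", call. = FALSE)
  } else if (npoints(p) < 2) {
    stop("need at least 2 points", call. = FALSE)
  }
  cp <- .close_pairs(p, max(grid), correction)
  if (tp$mode == "cross") {
    ti <- p$type[cp$i]; tj <- p$type[cp$j]
    keep <- (ti == tp$i & tj == tp$j) | (ti == tp$j & tj == tp$i)
    d <- cp$d[keep]; w <- cp$w[keep]
    norm <- (ni * nj) / area          # lambda_i lambda_j |W|
    kind <- "crossK"; pairlab <- c(tp$i, tp$j)
  } else {
    n <- npoints(p)
    d <- cp$d; w <- 2 * cp$w          # ordered pairs
    norm <- (n * (n - 1)) / area      # lambda^2 |W|, unbiased under CSR
    kind <- "K"; pairlab <- if (tp$mode == "single") c(tp$i, tp$i) else NULL
  }
  ord <- order(d)
  ds <- d[ord]; cw <- cumsum(w[ord])
  pos <- findInterval(grid, ds)
  vals <- ifelse(pos > 0, cw[pmax(pos, 1)], 0) / norm
  vals[grid == 0] <- 0
  .new_curve(grid, vals, kind, type_pair = pairlab,
             meta = list(correction = correction,
                         intensities = estimate_intensities(pattern),
                         n_pairs = length(d)))
}

# --- pair correlation ------------------------------------------------------

#' Pair correlation function and its cross-type variant
#'
#' The pair correlation function `g(r) = K'(r) / (2 pi r)` describes the
#' density of inter-point distances; it equals 1 under complete spatial
#' randomness. It is estimated directly by Epanechnikov kernel smoothing of
#' the translation-weighted pair distances (mathematically an estimator of
#' the same quantity as differentiating a smoothed K, without the noise
#' amplification of numerical differentiation). The value at `r = 0` is
#' undefined and returned as `NaN`.
#'
#' @inheritParams k_function
#' @param bandwidth Epanechnikov kernel half-width; default is Stoyan's rule
#'   `0.15 / sqrt(lambda)` with `lambda` the intensity of the points used.
#' @return A `summary_curve` of kind `"g"` or `"crossg"`.
#' @export
pair_correlation <- function(pattern, grid, types = "all", bandwidth = NULL,
                             correction = "translation") {
  grid <- .as_rgrid(grid)
  tp <- .resolve_types(pattern, types)
  p <- switch(tp$mode,
              all = pattern,
              single = .subset_mpp(pattern, pattern$type == tp$i),
              cross = .subset_mpp(pattern, pattern$type %in% c(tp$i, tp$j)))
  area <- window_area(p$window)
  n <- npoints(p)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- .stoyan_bandwidth(n / area)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  cp <- .close_pairs(p, max(grid) + bandwidth, correction)
  if (tp$mode == "cross") {
    ni <- npoints(p, tp$i); nj <- npoints(p, tp$j)
    if (ni < 1 || nj < 1) stop("need at least one point of each type",
                               call. = FALSE)
    ti <- p$type[cp$i]; tj <- p$type[cp$j]
    keep <- (ti == tp$i & tj == tp$j) | (ti == tp$j & tj == tp$i)
    d <- cp$d[keep]; w <- cp$w[keep]
    norm <- (ni * nj) / area
    kind <- "crossg"; pairlab <- c(tp$i, tp$j)
  } else {
    d <- cp$d; w <- 2 * cp$w
    norm <- (n * (n - 1)) / area
    kind <- "g"; pairlab <- if (tp$mode == "single") c(tp$i, tp$i) else NULL
  }
  sums <- .kernel_pair_sums(d, w, grid, bandwidth)
  vals <- sums / (2 * pi * grid * norm)
  vals[grid == 0] <- NaN
  .new_curve(grid, vals, kind, type_pair = pairlab,
             meta = list(correction = correction, bandwidth = bandwidth,
                         n_pairs = length(d)))
}

# --- mark connection function ---------------------------------------------

# Shared geometry for mcf computations: pooled i/j points, close pairs, and
# which points carry which label. Reused across random relabelings.
.mcf_geometry <- function(pattern, i, j, grid, bandwidth, correction) {
  p <- .subset_mpp(pattern, pattern$type %in% c(i, j))
  area <- window_area(p$window)
  n <- npoints(p)
  ni <- npoints(p, i); nj <- npoints(p, j)
  if (ni < 2 || nj < 2) {
    stop("need at least 2 points of each of types '", i, "' and '", j, "'",
         call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- .stoyan_bandwidth(n / area)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  cp <- .close_pairs(p, max(grid) + bandwidth, correction)
  ord <- order(cp$d)
  list(pattern = p, area = area, n = n, ni = ni, nj = nj, i = i, j = j,
       bandwidth = bandwidth, grid = grid,
       pi = cp$i[ord], pj = cp$j[ord], d = cp$d[ord], w = cp$w[ord],
       lo = findInterval(grid - bandwidth, cp$d[ord]) + 1L,
       hi = findInterval(grid + bandwidth, cp$d[ord]))
}

# numerator/denominator kernel sums for one labeling (factor over pooled pts)
.mcf_sums <- function(geom, labels) {
  cross <- labels[geom$pi] != labels[geom$pj]
  num <- den <- numeric(length(geom$grid))
  for (t in seq_along(geom$grid)) {
    if (geom$hi[t] >= geom$lo[t]) {
      idx <- geom$lo[t]:geom$hi[t]
      k <- geom$w[idx] * .epanechnikov(geom$d[idx] - geom$grid[t],
                                       geom$bandwidth)
      den[t] <- sum(k)
      num[t] <- sum(k[cross[idx]])
    }
  }
  list(num = num, den = den)
}

.mcf_values <- function(geom, labels, normalised) {
  s <- .mcf_sums(geom, labels)
  area <- geom$area; n <- geom$n
  ni <- sum(labels == geom$i); nj <- n - ni
  # g_ij over ordered i x j pairs (each unordered cross pair counted once in
  # the condensed sum, matching the ordered-pair count n_i * n_j)
  g_ij <- s$num / (geom$norm_2pir * ni * nj / area)
  g_all <- (2 * s$den) / (geom$norm_2pir * n * (n - 1) / area)
  if (normalised) {
    vals <- g_ij / g_all
  } else {
    lam_i <- ni / area; lam_j <- nj / area; lam_dot <- lam_i + lam_j
    vals <- lam_i * lam_j * g_ij / (lam_dot * g_all)
  }
  vals[!is.finite(vals)] <- NaN
  vals
}

#' Mark connection function between two cell types
#'
#' The mark connection function measures the propensity of points of types
#' `i` and `j` to occur at distance `r` from one another,
#' `lambda_i lambda_j g_ij(r) / (lambda_dot g(r))`, with `g_ij` the
#' cross-type and `g` the pooled (unmarked) pair correlation of the two
#' types. That raw ratio has random-labeling baseline
#' `lambda_i lambda_j / lambda_dot`; the default normalised form divides by
#' that baseline — equivalently returns `g_ij(r) / g(r)` — so that complete
#' randomness sits exactly at 1: values below 1 indicate same-type
#' clustering (compartmentalized tissue), values above 1 cross-type mixing.
#'
#' @inheritParams pair_correlation
#' @param i,j Type labels of the two subpatterns.
#' @param normalised If `TRUE` (default) the baseline-1 form `g_ij/g`; if
#'   `FALSE` the literal intensity-weighted ratio.
#' @return A `summary_curve` of kind `"mcf"`; values are `NaN` where the
#'   pooled pair correlation is zero or undefined (including `r = 0`).
#' @export
mark_connection <- function(pattern, i, j, grid, bandwidth = NULL,
                            normalised = TRUE, correction = "translation") {
  grid <- .as_rgrid(grid)
  geom <- .mcf_geometry(pattern, i, j, grid, bandwidth, correction)
  geom$norm_2pir <- 2 * pi * as.numeric(grid)
  vals <- .mcf_values(geom, geom$pattern$type, normalised)
  lam <- estimate_intensities(pattern, pair = c(i, j))
  .new_curve(grid, vals, "mcf", type_pair = c(i, j),
             meta = list(correction = correction,
                         bandwidth = geom$bandwidth,
                         normalised = normalised, intensities = lam,
                         n_pairs = length(geom$d)))
}

#' Random-labeling envelope for the mark connection function
#'
#' Builds a Monte Carlo envelope for the normalised mark connection function
#' under the random-labeling null: type labels are permuted over the pooled
#' points of types `i` and `j` while all locations stay fixed, so the
#' envelope reflects labeling noise conditional on the observed geometry.
#' The default `"global"` envelope is simultaneous over `region`: the
#' max-studentized-deviation statistic is ranked against the simulations, so
#' a true random labeling falls inside with probability `level` for the whole
#' curve. `"pointwise"` gives per-distance quantile bands instead (whose
#' joint coverage over many distances is necessarily below `level`).
#'
#' @inheritParams mark_connection
#' @param nsim Number of label permutations, default 199.
#' @param level Envelope coverage, default 0.95.
#' @param type `"global"` (default) or `"pointwise"`.
#' @param region Integer indices of grid points over which the envelope is
#'   assessed; default all points with `r > 0`.
#' @return List with the observed curve, `lo`/`hi` envelope vectors, logical
#'   `inside` per assessed grid point, the observed rank statistic, and
#'   `pass` (all assessed points inside).
#' @export
mcf_envelope <- function(pattern, i, j, grid, bandwidth = NULL, nsim = 199,
                         level = 0.95, type = c("global", "pointwise"),
                         region = NULL, correction = "translation") {
  type <- match.arg(type)
  grid <- .as_rgrid(grid)
  geom <- .mcf_geometry(pattern, i, j, grid, bandwidth, correction)
  geom$norm_2pir <- 2 * pi * as.numeric(grid)
  labs0 <- geom$pattern$type
  obs <- .mcf_values(geom, labs0, normalised = TRUE)
  sims <- matrix(NA_real_, nsim, length(grid))
  for (s in seq_len(nsim)) {
    sims[s, ] <- .mcf_values(geom, sample(labs0), normalised = TRUE)
  }
  if (is.null(region)) region <- which(as.numeric(grid) > 0)
  ok <- region[colSums(!is.finite(sims[, region, drop = FALSE])) == 0 &
               is.finite(obs[region])]
  m <- colMeans(sims[, ok, drop = FALSE])
  sdev <- apply(sims[, ok, drop = FALSE], 2, stats::sd)
  sdev[sdev == 0] <- 1
  lo <- hi <- rep(NA_real_, length(grid))
  if (type == "global") {
    tsim <- apply(abs(sweep(sweep(sims[, ok, drop = FALSE], 2, m), 2, sdev, "/")),
                  1, max)
    tobs <- max(abs((obs[ok] - m) / sdev))
    # rank of observed among {obs, sims}: pass iff not in the upper tail
    crit <- stats::quantile(tsim, probs = level, type = 1)
    rank_p <- (1 + sum(tsim >= tobs)) / (nsim + 1)
    lo[ok] <- m - crit * sdev
    hi[ok] <- m + crit * sdev
    inside <- obs[ok] >= lo[ok] & obs[ok] <= hi[ok]
    pass <- tobs <= crit
  } else {
    alpha <- 1 - level
    lo[ok] <- apply(sims[, ok, drop = FALSE], 2, stats::quantile,
                    probs = alpha / 2, type = 1)
    hi[ok] <- apply(sims[, ok, drop = FALSE], 2, stats::quantile,
                    probs = 1 - alpha / 2, type = 1)
    inside <- obs[ok] >= lo[ok] & obs[ok] <= hi[ok]
    pass <- all(inside)
    rank_p <- NA_real_
  }
  list(r = as.numeric(grid), obs = obs, lo = lo, hi = hi, region = ok,
       inside = inside, pass = pass, rank_p = rank_p, type = type,
       nsim = nsim, level = level)
}

# --- Moran's I profile -----------------------------------------------------

#' Cross-type Moran's I profile of a continuous mark
#'
#' For each grid distance `r`, correlates the values of mark `m` between
#' points of type `i` and points of type `j` that are approximately `r`
#' apart: the numerator sums `(m_s - mean_i)(m_t - mean_j)` over cross-type
#' pairs whose distance lies within `band_halfwidth` of `r`; the denominator
#' is the pooled sum of squares `sum_s (m_s - mean_pool)^2 +
#' sum_t (m_t - mean_pool)^2`, computed once over all points of the two
#' types. No edge correction is applied (the statistic is a ratio of raw
#' sums). Distances with no cross-type pair in the band yield 0 with a
#' recorded pair count of 0.
#'
#' @inheritParams mark_connection
#' @param mark Name of the numeric mark.
#' @param band_halfwidth Half-width of the distance band; default half the
#'   grid spacing.
#' @return A `summary_curve` of kind `"moran"`; `meta$pair_counts` records
#'   the number of cross-type pairs per band. If the pooled denominator is
#'   zero (all marks equal), values are `NaN` and `meta$degenerate` is set.
#' @export
morans_i_profile <- function(pattern, i, j, mark, grid,
                             band_halfwidth = NULL) {
  grid <- .as_rgrid(grid)
  if (is.null(band_halfwidth)) band_halfwidth <- attr(grid, "spacing") / 2
  stopifnot(band_halfwidth > 0)
  if (!mark %in% names(pattern$marks)) stop("unknown mark: ", mark,
                                            call. = FALSE)
  si <- which(pattern$type == i); sj <- which(pattern$type == j)
  if (length(si) == 0 || length(sj) == 0) {
    stop("both types must be present", call. = FALSE)
  }
  mi <- pattern$marks[[mark]][si]; mj <- pattern$marks[[mark]][sj]
  if (any(!is.finite(mi)) || any(!is.finite(mj))) {
    stop("mark '", mark, "' must be finite on all points of types '",
         i, "' and '", j, "'", call. = FALSE)
  }
  mbar_i <- mean(mi); mbar_j <- mean(mj)
  mbar_pool <- mean(c(mi, mj))
  den <- sum((mi - mbar_pool)^2) + sum((mj - mbar_pool)^2)
  # cross-type pair distances and mark products
  dx <- outer(pattern$x[si], pattern$x[sj], "-")
  dy <- outer(pattern$y[si], pattern$y[sj], "-")
  d <- sqrt(dx^2 + dy^2)
  prod <- outer(mi - mbar_i, mj - mbar_j)
  ord <- order(d)
  ds <- d[ord]; ps <- prod[ord]
  cps <- cumsum(ps)
  lo <- findInterval(as.numeric(grid) - band_halfwidth, ds,
                     left.open = TRUE)  # d >= r - h
  hi <- findInterval(as.numeric(grid) + band_halfwidth, ds)
  counts <- pmax(hi - lo, 0L)
  num <- numeric(length(grid))
  nonzero <- counts > 0
  num[nonzero] <- cps[hi[nonzero]] -
    ifelse(lo[nonzero] > 0, cps[pmax(lo[nonzero], 1)], 0)
  degenerate <- den <= 0
  vals <- if (degenerate) rep(NaN, length(grid)) else num / den
  .new_curve(grid, vals, "moran", type_pair = c(i, j), mark = mark,
             meta = list(band_halfwidth = band_halfwidth,
                         pair_counts = as.integer(counts),
                         degenerate = degenerate,
                         means = c(i = mbar_i, j = mbar_j, pool = mbar_pool),
                         denominator = den))
}

# --- cohort-level plumbing -------------------------------------------------

#' Common distance grid for a cohort of images
#'
#' The reference distance range is taken from the densest image (maximum
#' cell count): distances run from 0 to one quarter of that image's shorter
#' window side — the usual cap limiting edge-effect dominance — on a uniform
#' grid.
#'
#' @param patterns List of [mpp()] objects.
#' @param n_points Number of grid points, default 64.
#' @return An [r_grid()].
#' @export
common_reference_grid <- function(patterns, n_points = 64) {
  stopifnot(length(patterns) >= 1)
  ns <- vapply(patterns, npoints, integer(1))
  p <- patterns[[which.max(ns)]]
  short <- min(p$window$xmax - p$window$xmin, p$window$ymax - p$window$ymin)
  r_grid(short / 4, n_points)
}

#' Assemble per-subject curves into a functional covariate matrix
#'
#' Linearly interpolates each curve onto the shared grid. Leading `NaN`
#' values (the undefined `r = 0` region of kernel estimators) are filled
#' with the nearest defined value; a curve whose defined range stops short
#' of the top of the target grid raises an error naming the subject.
#'
#' @param curves Named list of `summary_curve` objects (names = subjects).
#' @param grid Target [r_grid()].
#' @return Numeric matrix, subjects in rows, grid points in columns, free of
#'   non-finite values. Row names are the curve names.
#' @export
curves_to_matrix <- function(curves, grid) {
  grid <- .as_rgrid(grid)
  gr <- as.numeric(grid)
  stopifnot(length(curves) >= 1)
  nm <- names(curves) %||% as.character(seq_along(curves))
  out <- matrix(NA_real_, length(curves), length(gr),
                dimnames = list(nm, NULL))
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    stopifnot(inherits(cv, "summary_curve"))
    def <- is.finite(cv$values)
    if (!any(def)) stop("curve '", nm[k], "' has no defined values",
                        call. = FALSE)
    rd <- cv$r[def]; vd <- cv$values[def]
    if (max(rd) < max(gr) - 1e-9 * max(gr)) {
      stop("curve '", nm[k], "' does not cover the target grid (defined up to ",
           max(rd), ", need ", max(gr), ")", call. = FALSE)
    }
    out[k, ] <- stats::approx(rd, vd, xout = gr, rule = 2)$y
  }
  stopifnot(all(is.finite(out)))
  out
}

#' Write a set of curves as a wide CSV plus metadata sidecar
#'
#' First column `r`, one column per subject; estimator metadata of the first
#' curve is written alongside as JSON.
#'
#' @param curves Named list of `summary_curve` objects on one common grid.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  r <- curves[[1]]$r
  for (cv in curves) stopifnot(isTRUE(all.equal(cv$r, r)))
  df <- data.frame(r = r)
  for (nm in names(curves)) df[[nm]] <- curves[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  meta <- curves[[1]][c("kind", "type_pair", "mark", "meta")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a wide curve CSV written by [write_curves_csv()]
#' @param path CSV path.
#' @return List with `r` (grid vector) and `values` (subjects x grid matrix).
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  r <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  list(r = r, values = m)
}
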