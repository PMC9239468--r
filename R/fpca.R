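#' Functional principal component analysis of a set of curves
#'
#' Eigen-decomposition of the sample covariance surface of curves observed
#' on a common grid, using trapezoid quadrature weights so the recovered
#' eigenfunctions are orthonormal with respect to the grid inner product and
#' the eigenvalues estimate the Karhunen-Loeve variances. The number of
#' retained components `M` is the smallest count whose cumulative proportion
#' of variance explained reaches `pve`.
#'
#' @param curves Subjects-by-grid numeric matrix (>= 2 curves).
#' @param s_grid Grid on which curves are observed.
#' @param pve Proportion of variance explained, default 0.99.
#' @return Object of class `fpca_model`: `mu` (mean curve), `values`
#'   (retained eigenvalues, nonincreasing), `funs` (grid x M eigenfunction
#'   matrix), `M`, `pve_seq` (cumulative PVE over all components),
#'   `all_values`, `s_grid`, `quad_w`.
#' @export
fpca_fit <- function(curves, s_grid, pve = 0.99) {
  curves <- as.matrix(curves)
  N <- nrow(curves)
  if (N < 2) stop("need at least 2 curves", call. = FALSE)
  stopifnot(ncol(curves) == length(s_grid), all(is.finite(curves)))
  h <- diff(s_grid)
  w <- c(h / 2, 0) + c(0, h / 2)
  mu <- colMeans(curves)
  Xc <- sweep(curves, 2, mu)
  C <- crossprod(Xc) / (N - 1)
  sw <- sqrt(w)
  A <- C * outer(sw, sw)               # W^{1/2} C W^{1/2}
  ed <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  tot <- sum(vals)
  pve_seq <- if (tot > 0) cumsum(vals) / tot else rep(1, length(vals))
  M <- if (tot > 0) which(pve_seq >= pve)[1] else 0L
  funs <- if (M > 0) {
    f <- ed$vectors[, seq_len(M), drop = FALSE] / sw
    # fix sign: positive integral against the grid (deterministic output)
    for (m in seq_len(M)) {
      s <- sum(f[, m] * w)
      if (s < 0 || (s == 0 && f[1, m] < 0)) f[, m] <- -f[, m]
    }
    f
  } else {
    matrix(0, length(s_grid), 0)
  }
  structure(list(mu = mu, values = vals[seq_len(M)], funs = funs, M = M,
                 pve_seq = pve_seq, all_values = vals, s_grid = s_grid,
                 quad_w = w),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("FPCA model: %d component(s) on %d grid points\n",
              x$M, length(x$s_grid)))
  if (x$M > 0) cat("eigenvalues:", signif(x$values, 4), "\n")
  invisible(x)
}

#' Construct an FPCA model directly from known components
#'
#' Used for fully specified generators (e.g. the declared stand-in of the
#' simulation engine); validates orthonormality of the supplied
#' eigenfunctions under the grid quadrature.
#'
#' @param mu Mean curve on `s_grid`.
#' @param values Nonnegative, nonincreasing eigenvalues.
#' @param funs Grid x M eigenfunction matrix.
#' @param s_grid Observation grid.
#' @return An `fpca_model`.
#' @export
fpca_model <- function(mu, values, funs, s_grid) {
  funs <- as.matrix(funs)
  stopifnot(length(mu) == length(s_grid), nrow(funs) == length(s_grid),
            length(values) == ncol(funs), all(values >= 0),
            all(diff(values) <= 1e-12))
  h <- diff(s_grid)
  w <- c(h / 2, 0) + c(0, h / 2)
  Gram <- t(funs) %*% (funs * w)
  if (ncol(funs) > 0 && max(abs(Gram - diag(ncol(funs)))) > 1e-6) {
    stop("eigenfunctions are not orthonormal under the grid quadrature",
         call. = FALSE)
  }
  structure(list(mu = mu, values = values, funs = funs, M = ncol(funs),
                 pve_seq = cumsum(values) / sum(values),
                 all_values = values, s_grid = s_grid, quad_w = w),
            class = "fpca_model")
}

#' Declared stand-in curve generator
#'
#' A fully specified FPCA model emulating smooth distance-summary curves:
#' mean `0.6 + 0.5 s`, two orthonormal components `sqrt(2) sin(pi s)` and
#' `sqrt(2) cos(pi s)` with eigenvalues `(0.09, 0.02)`, on a uniform grid
#' over [0, 1].
#'
#' @param n_s Number of grid points, default 30.
#' @return An `fpca_model`.
#' @export
standin_fpca <- function(n_s = 30) {
  s <- seq(0, 1, length.out = n_s)
  fpca_model(mu = 0.6 + 0.5 * s, values = c(0.09, 0.02),
             funs = cbind(sqrt(2) * sin(pi * s), sqrt(2) * cos(pi * s)),
             s_grid = s)
}
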