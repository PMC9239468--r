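#' Tensor-product spline configuration for the additive functional Cox model
#'
#' The smooth surface over (distance, curve value) is a tensor product of two
#' cubic regression spline bases with second-derivative marginal penalties.
#' The defaults (5 x 5 = 25 tensor coefficients) keep cohorts of a few dozen
#' subjects estimable; increase for large cohorts.
#'
#' @param K_s,K_x Marginal basis dimensions (>= 4).
#' @return List of class `afcm_config`.
#' @export
afcm_config <- function(K_s = 5, K_x = 5) {
  stopifnot(K_s >= 4, K_x >= 4)
  structure(list(K_s = K_s, K_x = K_x), class = "afcm_config")
}

#' Build a marginal cubic-regression-spline basis with its curvature penalty
#'
#' Knots are placed at empirical quantiles of the supplied values with
#' boundary knots at the observed range (optionally padded). The penalty is
#' the exact integrated squared second derivative; its quadratic form
#' vanishes on straight lines.
#'
#' @param values Numeric vector the basis must cover (>= `K` distinct values).
#' @param K Basis dimension.
#' @param pad Fractional range padding applied to the boundary knots,
#'   default 0.
#' @return List with `X` (evaluations at `values`), `S` (K x K penalty),
#'   `knots`, and the mgcv smooth object used for later evaluation.
#' @export
build_marginal_basis <- function(values, K, pad = 0) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)))
  if (length(unique(values)) < K) {
    stop("need at least K = ", K, " distinct values to place knots",
         call. = FALSE)
  }
  rng <- range(values)
  span <- diff(rng)
  knots <- as.numeric(stats::quantile(unique(values),
                                      probs = seq(0, 1, length.out = K),
                                      type = 7))
  knots[1] <- rng[1] - pad * span
  knots[K] <- rng[2] + pad * span
  # quantiles of near-duplicate values can collide; fall back to uniform
  if (any(diff(knots) <= 0)) {
    knots <- seq(knots[1], knots[K], length.out = K)
  }
  sm <- mgcv::smoothCon(mgcv::s(v, bs = "cr", k = K),
                        data = data.frame(v = values),
                        knots = list(v = knots), absorb.cons = FALSE,
                        scale.penalty = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]], knots = sm$xp, sm = sm)
}

# evaluate a marginal basis at new values (linear extrapolation beyond knots)
.eval_basis <- function(mb, values) {
  mgcv::PredictMat(mb$sm, data.frame(v = as.numeric(values)))
}

#' Build the functional design matrix of the additive functional Cox model
#'
#' For each subject the functional term contributes
#' `integral of F(s, X_i(s)) ds` with
#' `F(s,x) = sum_jk theta_jk B_j(s) B_k(x)`, so the design row is the vector
#' `V_i` with entries `integral of B_j(s) B_k(X_i(s)) ds`, evaluated by
#' trapezoid quadrature on the observed grid after rescaling the functional
#' domain to [0, 1]. Column order is `(j - 1) * K_x + k`.
#'
#' @param curves Subjects-by-grid matrix of functional covariate values.
#' @param s_grid Grid on which the curves are observed (any scale; it is
#'   affinely mapped to [0, 1]).
#' @param config An [afcm_config()].
#' @param s_basis,x_basis Optional pre-built marginal bases (used for
#'   prediction with training bases); built from `s_grid` and the pooled
#'   curve values otherwise.
#' @return List of class `functional_design`: `V` (N x K_s*K_x), the two
#'   marginal bases, quadrature weights `quad_w`, the rescaled grid `s01`,
#'   and the penalty embeddings `S_s`, `S_x` (each K_s*K_x square).
#' @export
build_functional_design <- function(curves, s_grid, config = afcm_config(),
                                    s_basis = NULL, x_basis = NULL) {
  curves <- as.matrix(curves)
  stopifnot(all(is.finite(curves)), ncol(curves) == length(s_grid))
  s01 <- (s_grid - min(s_grid)) / (max(s_grid) - min(s_grid))
  K_s <- config$K_s; K_x <- config$K_x
  if (is.null(s_basis)) s_basis <- build_marginal_basis(s01, K_s)
  if (is.null(x_basis)) {
    x_basis <- build_marginal_basis(as.numeric(curves), K_x)
  } else {
    rng <- range(x_basis$knots)
    out <- curves < rng[1] | curves > rng[2]
    if (any(out)) {
      warning(sprintf(
        "%d curve value(s) outside the x-basis knot range; linear extension used",
        sum(out)), call. = FALSE)
    }
  }
  ns <- length(s01)
  # trapezoid weights on the rescaled grid
  h <- diff(s01)
  quad_w <- c(h / 2, 0) + c(0, h / 2)
  Bs <- .eval_basis(s_basis, s01)               # ns x K_s
  Bx_flat <- .eval_basis(x_basis, as.numeric(curves))  # (N*ns) x K_x
  N <- nrow(curves)
  V <- matrix(0, N, K_s * K_x)
  Bsw <- Bs * quad_w                            # ns x K_s
  for (l in seq_len(ns)) {
    Bxl <- Bx_flat[(l - 1L) * N + seq_len(N), , drop = FALSE]  # N x K_x
    for (j in seq_len(K_s)) {
      cols <- (j - 1L) * K_x + seq_len(K_x)
      V[, cols] <- V[, cols] + Bsw[l, j] * Bxl
    }
  }
  stopifnot(all(is.finite(V)))
  S_s <- kronecker(s_basis$S, diag(K_x))
  S_x <- kronecker(diag(K_s), x_basis$S)
  structure(list(V = V, s_basis = s_basis, x_basis = x_basis,
                 quad_w = quad_w, s01 = s01, config = config,
                 S_s = S_s, S_x = S_x),
            class = "functional_design")
}

# --- Cox partial likelihood machinery -------------------------------------

# Breslow-ties partial log-likelihood, gradient, and negative Hessian at
# gamma. Risk-set sums are computed by cumulative sums over times sorted in
# decreasing order; tied times share the risk set of the last (largest-index)
# occurrence.
.cox_parts <- function(W, time, status, gamma, hessian = TRUE) {
  N <- nrow(W); q <- ncol(W)
  ord <- order(time, decreasing = TRUE)
  Wo <- W[ord, , drop = FALSE]
  to <- time[ord]; do <- status[ord]
  eta <- drop(Wo %*% gamma)
  c0 <- max(eta)
  ee <- exp(eta - c0)
  S0 <- cumsum(ee)
  S1 <- apply(Wo * ee, 2, cumsum)
  if (is.null(dim(S1))) S1 <- matrix(S1, nrow = 1)
  # index of the last element sharing each time (risk-set boundary)
  rl <- rle(to)
  last <- cumsum(rl$lengths)
  riskend <- rep(last, rl$lengths)
  ev <- which(do == 1)
  if (length(ev) == 0) stop("no events in the data", call. = FALSE)
  # group events by unique event time
  re <- riskend[ev]
  dk <- table(re)
  uk <- as.integer(names(dk)); dk <- as.numeric(dk)
  lp <- sum(eta[ev]) - sum(dk * (log(S0[uk]) + c0))
  mu <- S1[uk, , drop = FALSE] / S0[uk]
  G <- colSums(Wo[ev, , drop = FALSE]) - colSums(mu * dk)
  Hn <- NULL
  if (hessian) {
    bi <- rep(seq_len(q), times = q)
    bj <- rep(seq_len(q), each = q)
    E <- Wo[, bi, drop = FALSE] * Wo[, bj, drop = FALSE] * ee
    S2 <- apply(E, 2, cumsum)
    if (is.null(dim(S2))) S2 <- matrix(S2, nrow = 1)
    Hn <- matrix(colSums(S2[uk, , drop = FALSE] * (dk / S0[uk])), q, q)
    Hn <- Hn - crossprod(mu * sqrt(dk))
    Hn <- (Hn + t(Hn)) / 2
  }
  list(lp = lp, G = G, Hn = Hn, eta_ord = eta + c0 - c0, ord = ord)
}

#' Penalized Cox partial-likelihood Newton solver
#'
#' Maximizes the penalized partial log-likelihood
#' `l_p(gamma | lambda) = l(gamma) - 0.5 * gamma' P gamma` with
#' `P = sum_m lambda_m S_m`, using Newton-Raphson with step halving so the
#' penalized log-likelihood is nondecreasing across accepted steps. Ties are
#' handled by Breslow's approximation. Convergence requires the max-norm of
#' the penalized gradient below `tol * (1 + |l_p|)`.
#'
#' @param W Design matrix (scalar columns first, then functional columns).
#' @param time,status Observed times and event indicators (>= 1 event).
#' @param penalties List of symmetric penalty matrices embedded in the full
#'   coefficient space (zero blocks for unpenalized scalar coefficients);
#'   may be empty for an unpenalized fit.
#' @param lambda Numeric vector of smoothing parameters, one per penalty.
#' @param init Starting coefficients, default zero.
#' @param tol Gradient tolerance factor, default `1e-8`.
#' @param max_iter Maximum Newton iterations, default 100.
#' @return List with `gamma`, penalized log-likelihood `lp_pen`, unpenalized
#'   `lp`, penalized gradient `G_pen` and negative Hessian `Hn_pen`,
#'   iteration count, and `converged` flag.
#' @export
penalized_cox_newton <- function(W, time, status, penalties = list(),
                                 lambda = numeric(), init = NULL,
                                 tol = 1e-8, max_iter = 100) {
  W <- as.matrix(W)
  q <- ncol(W)
  stopifnot(length(lambda) == length(penalties), sum(status) >= 1)
  P <- matrix(0, q, q)
  for (m in seq_along(penalties)) P <- P + lambda[m] * penalties[[m]]
  gamma <- if (is.null(init)) rep(0, q) else as.numeric(init)
  pen_lp <- function(parts, g) parts$lp - 0.5 * sum(g * (P %*% g))
  parts <- .cox_parts(W, time, status, gamma)
  f <- pen_lp(parts, gamma)
  converged <- FALSE
  iter <- 0
  stalled <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- parts$G - drop(P %*% gamma)
    Hp <- parts$Hn + P
    if (max(abs(Gp)) < tol * (1 + abs(f))) { converged <- TRUE; break }
    step <- tryCatch(solve(Hp, Gp), error = function(e) {
      solve(Hp + diag(1e-8 * (1 + mean(diag(Hp))), q), Gp)
    })
    ok <- FALSE
    for (hh in 0:30) {
      gnew <- gamma + step / 2^hh
      pnew <- tryCatch(.cox_parts(W, time, status, gnew),
                       error = function(e) NULL)
      if (!is.null(pnew)) {
        fnew <- pen_lp(pnew, gnew)
        if (is.finite(fnew) && fnew >= f - 1e-12 * (1 + abs(f))) {
          if (fnew - f < 1e-11 * (1 + abs(f))) stalled <- TRUE
          gamma <- gnew; parts <- pnew; f <- fnew; ok <- TRUE
          break
        }
      }
    }
    if (!ok) { stalled <- TRUE; break }  # no ascent step representable
    if (stalled) break
  }
  Gp <- parts$G - drop(P %*% gamma)
  if (!converged) {
    # the objective is concave: once step halving can no longer make
    # meaningful progress, we are at the optimum up to rounding in
    # P %*% gamma, which for very large lambda dominates the absolute
    # gradient tolerance; accept if the gradient is tiny on the
    # likelihood scale
    converged <- max(abs(Gp)) < (if (stalled) 1e-5 else tol) * (1 + abs(f))
  }
  if (!converged) {
    stop(sprintf(
      "Newton did not converge in %d iterations (|G|_inf = %.3g, lp = %.6g)",
      max_iter, max(abs(Gp)), f), call. = FALSE)
  }
  list(gamma = gamma, lp_pen = f, lp = parts$lp, G_pen = Gp,
       Hn_pen = parts$Hn + P, Hn = parts$Hn, P = P, iter = iter,
       converged = converged)
}

#' Cox partial log-likelihood (Breslow ties)
#'
#' Convenience evaluator used by tests and smoothing selection; returns the
#' unpenalized partial log-likelihood, its gradient, and negative Hessian.
#'
#' @inheritParams penalized_cox_newton
#' @param gamma Coefficient vector.
#' @param hessian Compute the Hessian block (default `TRUE`).
#' @return List with `lp`, `G`, `Hn`.
#' @export
cox_partial_loglik <- function(W, time, status, gamma, hessian = TRUE) {
  p <- .cox_parts(as.matrix(W), time, status, as.numeric(gamma), hessian)
  list(lp = p$lp, G = p$G, Hn = p$Hn)
}

# log of product of positive eigenvalues + count of (numerically) zero ones
.logdet_plus <- function(P, tol = 1e-10) {
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  thr <- tol * max(abs(ev), 1e-300)
  pos <- ev > thr
  list(logdet = sum(log(ev[pos])), M_p = sum(!pos))
}

#' Laplace approximate marginal likelihood of a converged penalized fit
#'
#' `V(lambda) = l_p(gamma_hat) + 0.5 log|P|_+ - 0.5 log|H_p| +
#' (M_p / 2) log(2 pi)`, where `P = sum lambda_m S_m`, `|P|_+` is the
#' product of positive eigenvalues of `P`, `M_p` the number of its zero
#' eigenvalues (including unpenalized scalar directions), and `H_p` the
#' negative Hessian of the penalized partial log-likelihood at the optimum.
#'
#' @param fit Result of [penalized_cox_newton()].
#' @return List with `V`, `M_p`, and the individual terms.
#' @export
laml_criterion <- function(fit) {
  ld <- .logdet_plus(fit$P)
  cHp <- chol(fit$Hn_pen)
  log_det_Hp <- 2 * sum(log(diag(cHp)))
  V <- fit$lp_pen + 0.5 * ld$logdet - 0.5 * log_det_Hp +
    ld$M_p / 2 * log(2 * pi)
  list(V = V, M_p = ld$M_p, lp_pen = fit$lp_pen,
       logdet_P_plus = ld$logdet, logdet_Hp = log_det_Hp)
}

#' Select smoothing parameters by maximizing the LAML criterion
#'
#' Derivative-free search over `log10(lambda)` in `[-8, 8]` per margin: a
#' coarse grid locates the basin, then Nelder-Mead refines, with warm-started
#' Newton fits throughout.
#'
#' @inheritParams penalized_cox_newton
#' @param coarse Vector of `log10(lambda)` values for the initial grid.
#' @param tie If `TRUE`, a single smoothing parameter is shared by all
#'   penalties (the single-lambda notation of the model).
#' @param maxit Nelder-Mead iteration cap.
#' @return List with `lambda`, the final `fit`, the LAML value `V`, and the
#'   coarse-grid search path.
#' @export
select_smoothing_laml <- function(W, time, status, penalties,
                                  coarse = c(-1, 1, 3, 5), tie = FALSE,
                                  init = NULL, maxit = 40) {
  nlam <- if (tie) 1L else length(penalties)
  warm <- new.env(parent = emptyenv())
  warm$gamma <- init
  evalV <- function(loglam) {
    loglam <- pmin(pmax(loglam, -8), 8)
    lam <- 10^(if (tie) rep(loglam, length(penalties)) else loglam)
    fit <- tryCatch(
      penalized_cox_newton(W, time, status, penalties, lam,
                           init = warm$gamma),
      error = function(e) NULL)
    if (is.null(fit) && !is.null(warm$gamma)) {
      # a distant warm start can strand Newton; retry from zero
      fit <- tryCatch(
        penalized_cox_newton(W, time, status, penalties, lam),
        error = function(e) NULL)
    }
    if (is.null(fit)) return(list(V = -Inf, fit = NULL))
    warm$gamma <- fit$gamma
    V <- tryCatch(laml_criterion(fit)$V, error = function(e) -Inf)
    list(V = V, fit = fit)
  }
  pts <- as.matrix(do.call(expand.grid, rep(list(coarse), nlam)))
  path <- data.frame(pts, V = NA_real_)
  best <- list(V = -Inf, par = NULL, fit = NULL)
  for (g in seq_len(nrow(pts))) {
    r <- evalV(pts[g, ])
    path$V[g] <- r$V
    if (r$V > best$V) best <- list(V = r$V, par = pts[g, ], fit = r$fit)
  }
  if (!is.finite(best$V)) {
    stop("no smoothing parameter candidate produced a converged fit",
         call. = FALSE)
  }
  if (nlam == 1) {
    opt <- stats::optimize(function(ll) -evalV(ll)$V,
                           interval = best$par + c(-2, 2), tol = 1e-3)
    cand <- opt$minimum; candV <- -opt$objective
  } else {
    opt <- stats::optim(as.numeric(best$par), function(ll) -evalV(ll)$V,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-4))
    cand <- opt$par; candV <- -opt$value
  }
  if (candV >= best$V) best <- list(V = candV, par = cand, fit = NULL)
  final <- evalV(best$par)
  loglam <- pmin(pmax(best$par, -8), 8)
  lam <- 10^(if (tie) rep(loglam, length(penalties)) else as.numeric(loglam))
  list(lambda = lam, log10_lambda = as.numeric(loglam), fit = final$fit,
       V = final$V, path = path,
       at_boundary = any(abs(loglam) >= 8 - 1e-6))
}

# --- full model ------------------------------------------------------------

# Identifiability constraint over training subjects, reparameterizing
# theta = Q ttheta. Removes (a) the sum-to-zero direction colMeans(V) — the
# constant the partial likelihood cannot identify — and (b) any direction in
# the penalty null space whose contribution V theta is constant across
# subjects (e.g. surfaces depending on s alone integrate to the same value
# for everyone): such directions carry neither data information nor penalty
# and would make the penalized Hessian singular.
.constraint_transform <- function(V, S_sum = NULL) {
  cons <- matrix(colMeans(V), nrow = 1)
  Vc <- sweep(V, 2, colMeans(V))
  if (!is.null(S_sum)) {
    es <- eigen((S_sum + t(S_sum)) / 2, symmetric = TRUE)
    nulldim <- sum(es$values < 1e-10 * max(es$values))
    if (nulldim > 0) {
      Np <- es$vectors[, ncol(V) - seq_len(nulldim) + 1L, drop = FALSE]
      A <- Vc %*% Np
      sv <- svd(A)
      tolA <- 1e-9 * max(sv$d[1], norm(Vc, "F"), 1e-12)
      zero <- sv$d < tolA
      if (any(zero)) {
        cons <- rbind(cons, t(Np %*% sv$v[, zero, drop = FALSE]))
      }
    }
  }
  qq <- qr(t(cons))
  r <- qq$rank
  qr.Q(qq, complete = TRUE)[, -seq_len(r), drop = FALSE]
}

#' Fit the additive functional Cox model
#'
#' Log hazard: `log lambda_0(t) + Z' beta + integral of F(s, X(s)) ds`, with
#' `F` a penalized tensor-product cubic regression spline surface. Scalar
#' coefficients are unpenalized; each tensor margin carries its own
#' smoothing parameter selected by Laplace approximate marginal likelihood
#' (set `tie_lambda = TRUE` for the single-parameter variant). A sum-to-zero
#' identifiability constraint over the training subjects' functional
#' contributions removes the constant the partial likelihood cannot
#' identify. Either covariate block may be omitted: scalar-only reduces to
#' an ordinary (unpenalized) Cox fit; functional-only is supported.
#'
#' @param time,status Observed survival times and event indicators.
#' @param Z Scalar covariate matrix (or `NULL` for functional-only).
#' @param curves Subjects-by-grid functional covariate matrix (or `NULL`
#'   for scalar-only).
#' @param s_grid Grid on which curves are observed.
#' @param config An [afcm_config()].
#' @param lambda Optional fixed smoothing parameters (length 2, or 1 when
#'   `tie_lambda`); selected by LAML when `NULL`.
#' @param tie_lambda Share one smoothing parameter across both margins.
#' @param ... Passed to [select_smoothing_laml()].
#' @return Object of class `afcm_fit`.
#' @export
fit_afcm <- function(time, status, Z = NULL, curves = NULL, s_grid = NULL,
                     config = afcm_config(), lambda = NULL,
                     tie_lambda = FALSE, ...) {
  stopifnot(length(time) == length(status), all(time > 0),
            all(status %in% c(0, 1)))
  N <- length(time)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == N, all(is.finite(Z)))
  }
  design <- NULL; Qcon <- NULL; Vc <- NULL
  if (!is.null(curves)) {
    stopifnot(!is.null(s_grid), nrow(as.matrix(curves)) == N)
    design <- build_functional_design(curves, s_grid, config)
    Qcon <- .constraint_transform(design$V, design$S_s + design$S_x)
    Vc <- design$V %*% Qcon
  }
  W <- cbind(Z, Vc)
  if (is.null(W) || ncol(W) == 0) stop("no covariates supplied", call. = FALSE)
  p_scalar <- if (is.null(Z)) 0L else ncol(Z)
  q <- ncol(W)
  penalties <- list()
  if (!is.null(design)) {
    embed <- function(S) {
      full <- matrix(0, q, q)
      idx <- p_scalar + seq_len(ncol(Qcon))
      full[idx, idx] <- t(Qcon) %*% S %*% Qcon
      full
    }
    penalties <- list(s = embed(design$S_s), x = embed(design$S_x))
  }
  if (length(penalties) == 0) {
    nf <- penalized_cox_newton(W, time, status)
    sel <- NULL
    lambda_used <- numeric()
  } else if (!is.null(lambda)) {
    lambda_used <- if (tie_lambda) rep(lambda[1], 2) else lambda
    nf <- penalized_cox_newton(W, time, status, penalties, lambda_used)
    sel <- NULL
  } else {
    sel <- select_smoothing_laml(W, time, status, penalties,
                                 tie = tie_lambda, ...)
    nf <- sel$fit
    lambda_used <- sel$lambda
  }
  beta <- if (p_scalar > 0) nf$gamma[seq_len(p_scalar)] else numeric()
  names(beta) <- colnames(Z)
  theta <- NULL
  if (!is.null(design)) {
    ttheta <- nf$gamma[p_scalar + seq_len(ncol(Qcon))]
    theta <- drop(Qcon %*% ttheta)
  }
  eta <- drop(W %*% nf$gamma)
  fit <- structure(list(
    beta = beta, theta = theta, gamma = nf$gamma, lambda = lambda_used,
    config = config, design = design, Qcon = Qcon,
    p_scalar = p_scalar, s_grid = s_grid,
    time = time, status = status, eta = eta, W = W,
    newton = nf[c("lp", "lp_pen", "G_pen", "iter", "converged")],
    laml = if (!is.null(sel)) sel[c("V", "log10_lambda", "at_boundary")],
    diagnostics = list(grad_max = max(abs(nf$G_pen)),
                       hessian_condition = kappa(nf$Hn_pen, exact = FALSE))),
    class = "afcm_fit")
  fit$baseline <- breslow_cumulative_baseline(fit)
  fit
}

#' @export
print.afcm_fit <- function(x, ...) {
  cat("additive functional Cox model fit\n")
  cat(sprintf("  subjects: %d (%d events)\n", length(x$time), sum(x$status)))
  if (x$p_scalar > 0) {
    cat("  scalar coefficients:\n")
    print(x$beta)
  }
  if (!is.null(x$theta)) {
    cat(sprintf("  functional term: %d x %d tensor spline, lambda = (%s)\n",
                x$config$K_s, x$config$K_x,
                paste(signif(x$lambda, 3), collapse = ", ")))
  }
  cat(sprintf("  max |penalized score|: %.2e\n", x$diagnostics$grad_max))
  invisible(x)
}

#' Evaluate the fitted smooth surface
#'
#' `F_hat(s, x) = sum_jk theta_hat_jk B_j(s) B_k(x)` on a grid. `s` is on
#' the rescaled [0, 1] domain. Evaluation outside the knot range triggers an
#' extrapolation warning.
#'
#' @param fit An `afcm_fit` with a functional term.
#' @param s,x Evaluation grids; default 40 equally spaced points over the
#'   training ranges.
#' @return List with `s`, `x`, and matrix `F` (length(s) x length(x)).
#' @export
evaluate_surface <- function(fit, s = NULL, x = NULL) {
  stopifnot(inherits(fit, "afcm_fit"), !is.null(fit$theta))
  des <- fit$design
  if (is.null(s)) s <- seq(0, 1, length.out = 40)
  if (is.null(x)) x <- seq(min(des$x_basis$knots), max(des$x_basis$knots),
                           length.out = 40)
  if (min(s) < min(des$s_basis$knots) - 1e-9 ||
      max(s) > max(des$s_basis$knots) + 1e-9 ||
      min(x) < min(des$x_basis$knots) - 1e-9 ||
      max(x) > max(des$x_basis$knots) + 1e-9) {
    warning("surface evaluated outside the knot range: linear extrapolation",
            call. = FALSE)
  }
  K_s <- fit$config$K_s; K_x <- fit$config$K_x
  Theta <- matrix(fit$theta, K_s, K_x, byrow = TRUE)
  Bs <- .eval_basis(des$s_basis, s)
  Bx <- .eval_basis(des$x_basis, x)
  list(s = s, x = x, F = Bs %*% Theta %*% t(Bx))
}

#' Linear predictor for new subjects
#'
#' `eta_i = Z_i' beta_hat + V_i' theta_hat`, with `V_i` rebuilt from the new
#' curves using the training bases, quadrature and identifiability
#' constraint. New curves must be observed on the training grid.
#'
#' @param object An `afcm_fit`.
#' @param Z New scalar covariates (matrix), if the fit has scalar terms.
#' @param curves New functional covariates on the training `s_grid`.
#' @param ... Unused.
#' @return Numeric vector of linear predictors.
#' @export
predict.afcm_fit <- function(object, Z = NULL, curves = NULL, ...) {
  eta <- NULL
  if (object$p_scalar > 0) {
    stopifnot(!is.null(Z))
    Z <- as.matrix(Z)
    stopifnot(ncol(Z) == object$p_scalar)
    eta <- drop(Z %*% object$beta)
  }
  if (!is.null(object$theta)) {
    stopifnot(!is.null(curves))
    curves <- as.matrix(curves)
    if (ncol(curves) != length(object$s_grid)) {
      stop("new curves must be observed on the training distance grid",
           call. = FALSE)
    }
    des <- suppressWarnings(build_functional_design(
      curves, object$s_grid, object$config,
      s_basis = object$design$s_basis, x_basis = object$design$x_basis))
    etaf <- drop(des$V %*% object$theta)
    eta <- if (is.null(eta)) etaf else eta + etaf
  }
  eta
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' `Lambda_0(t) = sum over event times t_k <= t of d_k / sum_{Y_j >= t_k}
#' exp(eta_j)`: a right-continuous nondecreasing step function, 0 before the
#' first event.
#'
#' @param fit An `afcm_fit` (or any list with `time`, `status`, `eta`).
#' @return List with sorted unique event `times`, cumulative `hazard`, and
#'   `fun`, a step function of `t`.
#' @export
breslow_cumulative_baseline <- function(fit) {
  time <- fit$time; status <- fit$status; eta <- fit$eta
  ev <- sort(unique(time[status == 1]))
  c0 <- max(eta)
  ee <- exp(eta - c0)
  haz <- vapply(ev, function(tk) {
    sum(time == tk & status == 1) / (sum(ee[time >= tk]) * exp(c0))
  }, numeric(1))
  cumhaz <- cumsum(haz)
  fun <- if (length(ev) > 0) {
    stats::stepfun(ev, c(0, cumhaz), right = FALSE)
  } else {
    function(t) rep(0, length(t))
  }
  list(times = ev, hazard = cumhaz, fun = fun)
}

#' Dump a fitted model to JSON
#'
#' Writes configuration, knots, coefficients, smoothing parameters, the
#' Breslow baseline as (time, value) pairs, and diagnostics.
#'
#' @param fit An `afcm_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_afcm_json <- function(fit, path) {
  obj <- list(
    config = unclass(fit$config),
    beta = as.list(fit$beta),
    theta = fit$theta,
    lambda = fit$lambda,
    s_knots = if (!is.null(fit$design)) fit$design$s_basis$knots,
    x_knots = if (!is.null(fit$design)) fit$design$x_basis$knots,
    constraint = "sum-to-zero over training functional contributions",
    baseline = list(time = fit$baseline$times, cumhaz = fit$baseline$hazard),
    diagnostics = fit$diagnostics,
    laml = fit$laml)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
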