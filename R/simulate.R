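#' Simulate functional and scalar covariates from an FPCA model
#'
#' Curves follow the Karhunen-Loeve expansion
#' `X_i(s) = mu(s) + sum_j score_ij phi_j(s)`. By default the scores are
#' `sqrt(lambda_j) e_ij` with `e_ij` standard normal, so the component
#' variances equal the eigenvalues; `score_scale = "eigenvalue"` uses
#' `lambda_j e_ij` instead (score variance `lambda_j^2`). The pooled curve
#' values are affinely rescaled onto `x_range` (default [0, 1.2]) so the
#' covariate occupies a bounded, interpretable range; set `rescale = FALSE`
#' to keep raw values, or `clip = TRUE` to clamp instead of rescale. The
#' scalar covariate is i.i.d. normal.
#'
#' @param fpca An `fpca_model`.
#' @param N Number of subjects.
#' @param z_mean,z_sd Scalar covariate law.
#' @param score_scale `"sqrt"` (default) or `"eigenvalue"`.
#' @param x_range Target range of pooled curve values.
#' @param rescale Affinely rescale pooled values onto `x_range`.
#' @param clip Clamp to `x_range` instead of rescaling.
#' @return List with `curves` (N x grid), `Z` (length N), `scores`.
#' @export
simulate_covariates <- function(fpca, N, z_mean = 0, z_sd = 1,
                                score_scale = c("sqrt", "eigenvalue"),
                                x_range = c(0, 1.2), rescale = TRUE,
                                clip = FALSE) {
  score_scale <- match.arg(score_scale)
  stopifnot(inherits(fpca, "fpca_model"), N >= 1)
  M <- fpca$M
  e <- matrix(stats::rnorm(N * M), N, M)
  sc <- if (score_scale == "sqrt") sqrt(fpca$values) else fpca$values
  scores <- sweep(e, 2, sc, "*")
  X <- matrix(rep(fpca$mu, each = N), N, length(fpca$s_grid))
  if (M > 0) X <- X + scores %*% t(fpca$funs)
  if (rescale) {
    rng <- range(X)
    if (diff(rng) > 0) {
      X <- (X - rng[1]) / diff(rng) * diff(x_range) + x_range[1]
    }
  } else if (clip) {
    X <- pmin(pmax(X, x_range[1]), x_range[2])
  }
  Z <- stats::rnorm(N, z_mean, z_sd)
  list(curves = X, Z = Z, scores = scores)
}

#' True linear predictor of the simulation model
#'
#' `eta_i = beta Z_i + T_F(X_i)` where the functional term applies the true
#' surface `F(s, x)` along each curve. Two conventions for aggregating over
#' the grid are supported: `"grid_sum"` (default) is the literal sum
#' `sum_{s in grid} F(s, X_i(s))`, whose magnitude grows with grid
#' resolution; `"quadrature"` is the trapezoid integral
#' `integral F(s, X_i(s)) ds`, matching the convention the model fit uses.
#'
#' @param Z Scalar covariate vector.
#' @param curves Subjects-by-grid curve matrix on `s_grid`.
#' @param s_grid Grid (rescaled internally to [0, 1] for the surface).
#' @param beta True scalar coefficient, default 1.
#' @param surface Function of `(s, x)`, default `x^3 * s`.
#' @param convention `"grid_sum"` or `"quadrature"`.
#' @return Numeric vector of true linear predictors.
#' @export
true_eta <- function(Z, curves, s_grid, beta = 1,
                     surface = function(s, x) x^3 * s,
                     convention = c("grid_sum", "quadrature")) {
  convention <- match.arg(convention)
  curves <- as.matrix(curves)
  if (ncol(curves) != length(s_grid)) {
    stop("curves are not on the supplied grid", call. = FALSE)
  }
  s01 <- (s_grid - min(s_grid)) / (max(s_grid) - min(s_grid))
  Fvals <- t(apply(curves, 1, function(xi) surface(s01, xi)))
  if (nrow(curves) == 1) Fvals <- matrix(Fvals, nrow = 1)
  tf <- if (convention == "grid_sum") {
    rowSums(Fvals)
  } else {
    h <- diff(s01)
    w <- c(h / 2, 0) + c(0, h / 2)
    drop(Fvals %*% w)
  }
  beta * Z + tf
}

# evaluate a baseline cumulative hazard spec at times t
.baseline_cumhaz <- function(baseline, t) {
  switch(baseline$type,
         weibull = (t / baseline$scale)^baseline$shape,
         step = baseline$fun(t),
         stop("unknown baseline type", call. = FALSE))
}

#' Default Weibull stand-in baseline hazard
#' @param scale,shape Weibull parameters; default `Lambda_0(t) = (t/5)^1.2`.
#' @return Baseline specification list.
#' @export
weibull_baseline <- function(scale = 5, shape = 1.2) {
  list(type = "weibull", scale = scale, shape = shape)
}

#' Step-function baseline from a fitted model
#' @param times,cumhaz Event times and cumulative hazard values (e.g. from
#'   [breslow_cumulative_baseline()]).
#' @return Baseline specification list.
#' @export
step_baseline <- function(times, cumhaz) {
  stopifnot(length(times) == length(cumhaz), all(diff(cumhaz) >= 0),
            all(cumhaz >= 0))
  list(type = "step", times = times, cumhaz = cumhaz,
       fun = stats::stepfun(times, c(0, cumhaz), right = FALSE))
}

#' Simulate survival times by inverting the cumulative hazard
#'
#' Each subject's survival function is
#' `S_i(t) = exp(-exp(eta_i) Lambda_0(t))`; times are drawn by inverse
#' transform: with `U ~ Uniform(0,1)`,
#' `T = inf{ t : Lambda_0(t) exp(eta) >= -log U }`. For a Weibull baseline
#' the inverse is closed-form; for a step baseline the inversion lands on
#' the event-time atoms and draws exceeding the supported range are capped
#' at the last time with an `capped` attribute counting them.
#'
#' @param eta Linear predictors.
#' @param baseline A [weibull_baseline()] or [step_baseline()] spec.
#' @return Numeric vector of latent survival times.
#' @export
simulate_survival <- function(eta, baseline) {
  n <- length(eta)
  U <- stats::runif(n)
  target <- -log(U) * exp(-eta)
  if (baseline$type == "weibull") {
    tt <- baseline$scale * target^(1 / baseline$shape)
    attr(tt, "capped") <- 0L
    return(tt)
  }
  if (baseline$type == "step") {
    ch <- baseline$cumhaz
    if (max(ch) <= 0) stop("baseline cumulative hazard is identically zero",
                           call. = FALSE)
    idx <- findInterval(target, ch, left.open = TRUE) + 1L
    capped <- idx > length(baseline$times)
    idx[capped] <- length(baseline$times)
    tt <- baseline$times[idx]
    attr(tt, "capped") <- sum(capped)
    return(tt)
  }
  stop("unknown baseline type", call. = FALSE)
}

#' Simulate censoring times
#'
#' Either resampling (with replacement) from a list of observed censoring
#' times — the empirical-distribution option — or an exponential stand-in
#' with a configured rate.
#'
#' @param n Number of draws.
#' @param model `list(type = "resample", times = ...)` or
#'   `list(type = "exponential", rate = ...)`.
#' @return Numeric vector of censoring times.
#' @export
simulate_censoring <- function(n, model) {
  if (model$type == "resample") {
    if (length(model$times) == 0) {
      stop("empty empirical censoring list", call. = FALSE)
    }
    return(model$times[sample.int(length(model$times), n, replace = TRUE)])
  }
  if (model$type == "exponential") {
    stopifnot(model$rate > 0)
    return(stats::rexp(n, model$rate))
  }
  stop("unknown censoring model", call. = FALSE)
}

#' Calibrate an exponential censoring rate to a target censoring fraction
#'
#' Generator-only pilot: simulates a large cohort of latent survival times
#' from the configured generator and root-finds the exponential rate whose
#' expected censoring fraction matches `target`.
#'
#' @param config A [simulation_config()].
#' @param target Desired censoring fraction.
#' @param n_pilot Pilot cohort size, default 4000.
#' @return Exponential rate (scalar).
#' @export
calibrate_censoring_rate <- function(config, target = 0.35, n_pilot = 4000) {
  # the pooled covariate rescale makes the survival-time law depend on the
  # cohort size, so the pilot simulates cohorts of the configured size
  n_batches <- max(1L, ceiling(n_pilot / config$N))
  T <- unlist(lapply(seq_len(n_batches), function(b) {
    cov <- simulate_covariates(config$fpca, config$N, config$z_mean,
                               config$z_sd, config$score_scale,
                               config$x_range)
    eta <- true_eta(cov$Z, cov$curves, config$fpca$s_grid, config$beta,
                    config$surface, config$convention)
    as.numeric(simulate_survival(eta, config$baseline))
  }))
  cens_frac <- function(log_rate) {
    # P(C < T | T) for C ~ Exp(r): 1 - exp(-r T)
    mean(1 - exp(-exp(log_rate) * T)) - target
  }
  lo <- log(1 / (stats::median(T) + .Machine$double.xmin)) - 40
  hi <- lo + 80
  stats::uniroot(cens_frac, c(lo, hi), tol = 1e-10)$root |> exp()
}

#' Configuration of the three-model MSE simulation experiment
#'
#' Declares the full generative model: the FPCA curve generator, the scalar
#' covariate law, the true coefficient and surface, the baseline hazard,
#' the censoring target, and the train/test split. The scalar standard
#' deviation defaults to the value that puts the functional and scalar
#' signal variances in the reference ratio `signal_ratio` (functional to
#' scalar, default 1.6), measured on a generator-only pilot.
#'
#' @param N Cohort size per replicate.
#' @param n_reps Number of replicates, default 100.
#' @param fpca Curve generator, default [standin_fpca()].
#' @param beta True scalar coefficient, default 1.
#' @param surface True surface, default `x^3 * s`.
#' @param convention Aggregation convention of [true_eta()].
#' @param z_mean Scalar covariate mean, default 0 (standardized age).
#' @param z_sd Scalar covariate sd; `NULL` (default) triggers the
#'   ratio-based calibration.
#' @param signal_ratio Target Var(functional)/Var(scalar), default 1.6.
#' @param x_range Curve value range, default [0, 1.2].
#' @param score_scale Score convention, see [simulate_covariates()].
#' @param baseline Baseline hazard spec, default [weibull_baseline()].
#' @param censoring_target Censoring fraction for the exponential stand-in,
#'   default 0.35; or supply `censoring` directly.
#' @param censoring Optional explicit censoring model (see
#'   [simulate_censoring()]).
#' @param train_frac Training fraction, default 0.75.
#' @param seed Master seed; every source of randomness derives from it.
#' @param config Spline configuration for the fitted models.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(N, n_reps = 100, fpca = standin_fpca(),
                              beta = 1, surface = function(s, x) x^3 * s,
                              convention = "grid_sum",
                              z_mean = 0, z_sd = NULL, signal_ratio = 1.6,
                              x_range = c(0, 1.2),
                              score_scale = "sqrt",
                              baseline = weibull_baseline(),
                              censoring_target = 0.35, censoring = NULL,
                              train_frac = 0.75, seed = 1,
                              config = afcm_config()) {
  stopifnot(N >= 8, n_reps >= 1, train_frac > 0, train_frac < 1)
  cfg <- list(N = N, n_reps = n_reps, fpca = fpca, beta = beta,
              surface = surface, convention = convention,
              z_mean = z_mean, z_sd = z_sd, signal_ratio = signal_ratio,
              x_range = x_range, score_scale = score_scale,
              baseline = baseline, censoring_target = censoring_target,
              censoring = censoring, train_frac = train_frac, seed = seed,
              config = config)
  class(cfg) <- "simulation_config"
  if (is.null(cfg$z_sd)) {
    old <- .save_seed()
    set.seed((seed + 777L) %% .Machine$integer.max)
    pilot <- simulate_covariates(fpca, 4000, 0, 1, score_scale, x_range)
    tf <- true_eta(rep(0, 4000), pilot$curves, fpca$s_grid, 0, surface,
                   convention)
    s_tf <- stats::sd(tf)
    cfg$z_sd <- if (s_tf > 0 && abs(beta) > 0) {
      s_tf / sqrt(signal_ratio) / abs(beta)
    } else 1

    .restore_seed(old)
  }
  cfg
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one cohort from a simulation configuration
#'
#' @param config A [simulation_config()].
#' @return List with `curves`, `Z`, `eta` (true linear predictor), latent
#'   `T` and `C`, observed `time` and `status`.
#' @export
simulate_cohort <- function(config) {
  cov <- simulate_covariates(config$fpca, config$N, config$z_mean,
                             config$z_sd, config$score_scale, config$x_range)
  eta <- true_eta(cov$Z, cov$curves, config$fpca$s_grid, config$beta,
                  config$surface, config$convention)
  T <- simulate_survival(eta, config$baseline)
  cens <- config$censoring
  if (is.null(cens)) {
    rate <- calibrate_censoring_rate(config, config$censoring_target)
    cens <- list(type = "exponential", rate = rate)
  }
  C <- simulate_censoring(config$N, cens)
  list(curves = cov$curves, Z = cov$Z, eta = eta, T = as.numeric(T), C = C,
       time = pmin(T, C), status = as.numeric(T <= C))
}

#' Run the three-model MSE experiment
#'
#' For each replicate: simulate a cohort of size `N`, split into training
#' (`train_frac`) and testing sets, fit (1) the additive functional Cox
#' model with scalar and functional terms, (2) the functional-only model,
#' and (3) the scalar-only Cox model on the training set, and score each by
#' the test-set mean squared error between predicted and true linear
#' predictors. Because the partial likelihood identifies the linear
#' predictor only up to an additive constant, both predictor vectors are
#' centered within the test set before squaring (set `center = FALSE` for
#' the raw version). Replicates whose fit fails are skipped and counted;
#' more than 10% failures is an error.
#'
#' @param config A [simulation_config()].
#' @param keep_beta Record the scalar coefficient of model (1) per
#'   replicate (default `TRUE`).
#' @param keep_surfaces Record the fitted surface of model (1) on a
#'   `surface_grid` x `surface_grid` grid per replicate.
#' @param surface_grid Surface evaluation resolution, default 20.
#' @param center Center predictors within the test set (default `TRUE`).
#' @return Object of class `mse_table`: `replicates` (long data frame of
#'   per-replicate MSEs), `summary` (mean and sd per model), `beta_hat`,
#'   `surfaces`, `n_test`, `n_failed`, `config`.
#' @export
run_mse_experiment <- function(config, keep_beta = TRUE,
                               keep_surfaces = FALSE, surface_grid = 20,
                               center = TRUE) {
  set.seed(config$seed %% .Machine$integer.max)
  # censoring calibrated once per experiment (generator-only pilot)
  if (is.null(config$censoring)) {
    rate <- calibrate_censoring_rate(config, config$censoring_target)
    config$censoring <- list(type = "exponential", rate = rate)
  }
  models <- c("both", "functional", "scalar")
  reps <- list()
  beta_hat <- numeric()
  surfaces <- list()
  n_failed <- 0L
  n_test <- integer()
  for (rep_i in seq_len(config$n_reps)) {
    coh <- simulate_cohort(config)
    idx <- sample.int(config$N)
    n_train <- round(config$train_frac * config$N)
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    s_grid <- config$fpca$s_grid
    res <- tryCatch({
      f1 <- fit_afcm(coh$time[tr], coh$status[tr],
                     Z = matrix(coh$Z[tr], ncol = 1),
                     curves = coh$curves[tr, , drop = FALSE],
                     s_grid = s_grid, config = config$config)
      f2 <- fit_afcm(coh$time[tr], coh$status[tr], Z = NULL,
                     curves = coh$curves[tr, , drop = FALSE],
                     s_grid = s_grid, config = config$config)
      f3 <- fit_afcm(coh$time[tr], coh$status[tr],
                     Z = matrix(coh$Z[tr], ncol = 1), curves = NULL)
      eta_hat <- list(
        both = predict(f1, Z = matrix(coh$Z[te], ncol = 1),
                       curves = coh$curves[te, , drop = FALSE]),
        functional = predict(f2, curves = coh$curves[te, , drop = FALSE]),
        scalar = predict(f3, Z = matrix(coh$Z[te], ncol = 1)))
      list(fit1 = f1, eta_hat = eta_hat)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    eta_true <- coh$eta[te]
    mses <- vapply(res$eta_hat, function(eh) {
      if (center) {
        mean(((eh - mean(eh)) - (eta_true - mean(eta_true)))^2)
      } else {
        mean((eh - eta_true)^2)
      }
    }, numeric(1))
    reps[[length(reps) + 1L]] <- data.frame(
      replicate = rep_i, model = models, mse = as.numeric(mses[models]))
    n_test <- c(n_test, length(te))
    if (keep_beta) beta_hat <- c(beta_hat, unname(res$fit1$beta[1]))
    if (keep_surfaces) {
      sg <- seq(0, 1, length.out = surface_grid)
      xg <- seq(config$x_range[1], config$x_range[2],
                length.out = surface_grid)
      surfaces[[length(surfaces) + 1L]] <-
        suppressWarnings(evaluate_surface(res$fit1, s = sg, x = xg))
    }
  }
  if (n_failed > 0.1 * config$n_reps) {
    stop(sprintf("%d of %d replicates failed to fit", n_failed,
                 config$n_reps), call. = FALSE)
  }
  replicates <- do.call(rbind, reps)
  agg_m <- tapply(replicates$mse, replicates$model, mean)
  agg_s <- tapply(replicates$mse, replicates$model, stats::sd)
  summary <- data.frame(model = models,
                        mean_mse = as.numeric(agg_m[models]),
                        sd_mse = as.numeric(agg_s[models]),
                        n_replicates = as.integer(table(replicates$model)[models]))
  structure(list(replicates = replicates, summary = summary,
                 beta_hat = beta_hat, surfaces = surfaces,
                 n_test = n_test, n_failed = n_failed, config = config),
            class = "mse_table")
}

#' @export
print.mse_table <- function(x, ...) {
  cat(sprintf("MSE experiment: N = %d, %d replicates (%d failed)\n",
              x$config$N, x$config$n_reps, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an MSE experiment to CSV
#' @param x An `mse_table`.
#' @param dir Output directory; writes `mse_summary.csv` and
#'   `mse_replicates.csv`.
#' @return Invisibly, the paths.
#' @export
write_mse_table <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "mse_summary.csv")
  rp <- file.path(dir, "mse_replicates.csv")
  utils::write.csv(cbind(N = x$config$N, x$summary), sp, row.names = FALSE)
  utils::write.csv(cbind(N = x$config$N, x$replicates), rp, row.names = FALSE)
  invisible(c(summary = sp, replicates = rp))
}

#' Rank correlation between a fitted surface and a reference surface
#'
#' Because the functional term enters the hazard only through
#' `integral F(s, X(s)) ds`, any component of `F` additive in the distance
#' `s` contributes a subject-independent constant and is unidentifiable;
#' the fitted surface fixes it at zero. The default `"per_distance"`
#' centering therefore removes, from both surfaces, the mean over curve
#' values at each distance before computing the Spearman correlation over
#' the grid — comparing exactly the estimable parts. `"global"` centering
#' subtracts only the overall mean.
#'
#' @param surface A list with `s`, `x`, `F` as returned by
#'   [evaluate_surface()].
#' @param reference Function of `(s, x)` giving the reference surface.
#' @param center `"per_distance"` (default) or `"global"`.
#' @return Spearman correlation (scalar).
#' @export
surface_spearman <- function(surface, reference,
                             center = c("per_distance", "global")) {
  center <- match.arg(center)
  truth <- outer(surface$s, surface$x, reference)
  est <- surface$F
  if (center == "per_distance") {
    truth <- truth - rowMeans(truth)
    est <- est - rowMeans(est)
  } else {
    truth <- truth - mean(truth)
    est <- est - mean(est)
  }
  stats::cor(as.vector(est), as.vector(truth), method = "spearman")
}
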