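#' Configuration for synthetic two-type point patterns
#'
#' Declares a generator of planar marked point patterns emulating tissue
#' images: homogeneous Poisson (`"poisson"`), Poisson with i.i.d. type
#' labels (`"random_labeling"`), or a pair of Thomas cluster processes
#' (`"two_type_thomas"`) whose second type's parents are displaced by a
#' configurable offset — zero displacement gives "mixed" tissue, a large
#' displacement "compartmentalized" tissue. Continuous marks are generated
#' from a shared smooth latent field (a fixed low-frequency sinusoid basis
#' with random coefficients) plus a type-specific mean shift and independent
#' noise, which induces positive cross-type mark correlation decaying over
#' the field's range.
#'
#' @param window An [obs_window()].
#' @param process One of `"poisson"`, `"random_labeling"`,
#'   `"two_type_thomas"`.
#' @param intensity Point intensity (points per squared micron) for Poisson
#'   and random labeling.
#' @param p Probability of the first type under random labeling.
#' @param kappa Parent intensity per type (Thomas).
#' @param sigma Offspring displacement sd (Thomas).
#' @param mu_off Mean offspring per parent (Thomas).
#' @param displacement Horizontal shift applied to type-2 parents (microns).
#' @param types Pair of type labels, default `c("tumor", "stroma")`.
#' @param mark_name Name of the generated mark, or `NULL` for no marks.
#' @param mark_range Spatial range (microns) of the latent mark field.
#' @param mark_shift Length-2 type-specific mean shifts.
#' @param mark_noise_sd Independent mark noise sd.
#' @return List of class `pattern_sim_config`.
#' @export
pattern_sim_config <- function(window = obs_window(0, 1000, 0, 1000),
                               process = c("poisson", "random_labeling",
                                           "two_type_thomas"),
                               intensity = 0.002, p = 0.5,
                               kappa = 5e-5, sigma = 30, mu_off = 20,
                               displacement = 0,
                               types = c("tumor", "stroma"),
                               mark_name = "marker", mark_range = 150,
                               mark_shift = c(0, 0), mark_noise_sd = 0.25) {
  process <- match.arg(process)
  stopifnot(intensity > 0, p > 0, p < 1, kappa > 0, sigma > 0, mu_off > 0,
            mark_range > 0, mark_noise_sd >= 0, length(types) == 2)
  structure(list(window = window, process = process, intensity = intensity,
                 p = p, kappa = kappa, sigma = sigma, mu_off = mu_off,
                 displacement = displacement, types = types,
                 mark_name = mark_name, mark_range = mark_range,
                 mark_shift = mark_shift, mark_noise_sd = mark_noise_sd),
            class = "pattern_sim_config")
}

# Smooth latent field via random Fourier features: a superposition of
# cosines with Gaussian-distributed frequencies of scale 1/rho has
# covariance exp(-d^2 / (2 rho^2)) — unit variance, monotone decay over the
# configured range.
.latent_field <- function(rho, n_feat = 24) {
  wx <- stats::rnorm(n_feat, 0, 1 / rho)
  wy <- stats::rnorm(n_feat, 0, 1 / rho)
  phase <- stats::runif(n_feat, 0, 2 * pi)
  function(x, y) {
    v <- 0
    for (k in seq_len(n_feat)) {
      v <- v + cos(wx[k] * x + wy[k] * y + phase[k])
    }
    v * sqrt(2 / n_feat)
  }
}

.thomas_points <- function(win, kappa, sigma, mu_off, shift_x = 0) {
  a <- win$xmax - win$xmin; b <- win$ymax - win$ymin
  pad <- 4 * sigma
  n_par <- stats::rpois(1, kappa * (a + 2 * pad) * (b + 2 * pad))
  if (n_par == 0) return(cbind(x = numeric(), y = numeric()))
  px <- stats::runif(n_par, win$xmin - pad, win$xmax + pad) + shift_x
  py <- stats::runif(n_par, win$ymin - pad, win$ymax + pad)
  n_off <- stats::rpois(n_par, mu_off)
  cx <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  cy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  keep <- cx >= win$xmin & cx <= win$xmax & cy >= win$ymin & cy <= win$ymax
  cbind(x = cx[keep], y = cy[keep])
}

#' Simulate a marked point pattern
#'
#' @param config A [pattern_sim_config()].
#' @param subject_id,image_id Identifiers for the generated pattern.
#' @return An [mpp()].
#' @export
simulate_pattern <- function(config, subject_id = "sim", image_id = "1") {
  stopifnot(inherits(config, "pattern_sim_config"))
  win <- config$window
  area <- window_area(win)
  expected <- switch(config$process,
                     poisson = config$intensity * area,
                     random_labeling = config$intensity * area,
                     two_type_thomas = 2 * config$kappa * area * config$mu_off)
  if (expected > 1e6) stop("expected point count exceeds 1e6; refusing",
                           call. = FALSE)
  if (config$process %in% c("poisson", "random_labeling")) {
    n <- stats::rpois(1, config$intensity * area)
    x <- stats::runif(n, win$xmin, win$xmax)
    y <- stats::runif(n, win$ymin, win$ymax)
    type <- if (config$process == "poisson") {
      rep(config$types[1], n)
    } else {
      ifelse(stats::runif(n) < config$p, config$types[1], config$types[2])
    }
  } else {
    p1 <- .thomas_points(win, config$kappa, config$sigma, config$mu_off)
    p2 <- .thomas_points(win, config$kappa, config$sigma, config$mu_off,
                         shift_x = config$displacement)
    x <- c(p1[, 1], p2[, 1]); y <- c(p1[, 2], p2[, 2])
    type <- c(rep(config$types[1], nrow(p1)), rep(config$types[2], nrow(p2)))
  }
  marks <- NULL
  if (!is.null(config$mark_name) && length(x) > 0) {
    field <- .latent_field(config$mark_range)
    shift <- config$mark_shift[match(type, config$types)]
    v <- field(x, y) + shift + stats::rnorm(length(x), 0, config$mark_noise_sd)
    marks <- stats::setNames(data.frame(v), config$mark_name)
  }
  mpp(x, y, type, marks = marks, window = win, subject_id = subject_id,
      image_id = image_id, type_levels = config$types)
}

#' Fixed four-point oracle pattern
#'
#' A deterministic pattern in the unit square used as the anchor of
#' brute-force oracle comparisons: type `t1` at (0.20, 0.20) with mark 1
#' and (0.30, 0.20) with mark 3; type `t2` at (0.70, 0.70) with mark 2 and
#' (0.80, 0.70) with mark 4.
#'
#' @return An [mpp()] with mark column `marker`.
#' @export
toy4 <- function() {
  mpp(x = c(0.20, 0.30, 0.70, 0.80), y = c(0.20, 0.20, 0.70, 0.70),
      type = c("t1", "t1", "t2", "t2"),
      marks = data.frame(marker = c(1, 3, 2, 4)),
      window = obs_window(0, 1, 0, 1),
      subject_id = "toy", image_id = "1", type_levels = c("t1", "t2"))
}

#' Configuration for an end-to-end synthetic cohort
#'
#' Each subject receives a two-type Thomas pattern whose mixing parameter
#' `m` (0 = fully compartmentalized, 1 = fully mixed; it scales the
#' between-type parent displacement) is drawn uniformly from `mixing_range`,
#' and a survival time whose hazard is multiplied by `exp(c * (m - 0.5))`
#' with `c = link_coef` — so positive `c` means mixed tissue is harmful.
#'
#' @param n Number of subjects (>= 2).
#' @param link_coef Log-hazard coefficient on the centered mixing parameter.
#' @param mixing_range Range of the per-subject mixing parameter.
#' @param window Image window shared by subjects.
#' @param kappa,sigma,mu_off Thomas parameters per type.
#' @param baseline Baseline hazard spec, default [weibull_baseline()].
#' @param censoring_rate Exponential censoring rate, default `0.1`.
#' @param types Type labels.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 100, link_coef = 1,
                              mixing_range = c(0, 1),
                              window = obs_window(0, 600, 0, 600),
                              kappa = 8e-5, sigma = 25, mu_off = 15,
                              baseline = weibull_baseline(),
                              censoring_rate = 0.1,
                              types = c("tumor", "stroma")) {
  stopifnot(n >= 2)
  structure(list(n = n, link_coef = link_coef, mixing_range = mixing_range,
                 window = window, kappa = kappa, sigma = sigma,
                 mu_off = mu_off, baseline = baseline,
                 censoring_rate = censoring_rate, types = types),
            class = "cohort_sim_config")
}

#' Simulate a full synthetic cohort: cell tables plus survival table
#'
#' Generates one pattern per subject with a subject-specific mixing
#' parameter, survival times driven by the known linear predictor
#' `c * (m - 0.5)`, and exponential censoring. Optionally writes the
#' canonical CSV pair plus `survival.csv` into `dir`.
#'
#' @param config A [cohort_sim_config()].
#' @param dir Optional output directory.
#' @return List with `patterns` (list of [mpp()]), `survival` (data frame
#'   `subject_id,time,event`), `mixing` (true parameters), `eta`.
#' @export
simulate_cohort_end_to_end <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n
  m <- stats::runif(n, config$mixing_range[1], config$mixing_range[2])
  side <- config$window$xmax - config$window$xmin
  patterns <- vector("list", n)
  ids <- sprintf("s%03d", seq_len(n))
  for (k in seq_len(n)) {
    pc <- pattern_sim_config(window = config$window,
                             process = "two_type_thomas",
                             kappa = config$kappa, sigma = config$sigma,
                             mu_off = config$mu_off,
                             displacement = (1 - m[k]) * side / 2,
                             types = config$types)
    patterns[[k]] <- simulate_pattern(pc, subject_id = ids[k])
  }
  names(patterns) <- ids
  eta <- config$link_coef * (m - 0.5)
  T <- simulate_survival(eta, config$baseline)
  C <- simulate_censoring(n, list(type = "exponential",
                                  rate = config$censoring_rate))
  surv <- data.frame(subject_id = ids, time = pmin(T, C),
                     event = as.numeric(T <= C))
  if (!is.null(dir)) {
    write_cohort(patterns, dir)
    utils::write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  }
  list(patterns = patterns, survival = surv, mixing = m, eta = eta)
}
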