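# Independent brute-force oracles: direct double-loop enumeration of the
# estimator definitions, kept deliberately separate from the package's
# vectorized implementations.

oracle_translation_weight <- function(p, a, b) {
  w <- p$window
  A <- (w$xmax - w$xmin) * (w$ymax - w$ymin)
  A / ((w$xmax - w$xmin - abs(p$x[a] - p$x[b])) *
       (w$ymax - w$ymin - abs(p$y[a] - p$y[b])))
}

oracle_dist <- function(p, a, b) {
  sqrt((p$x[a] - p$x[b])^2 + (p$y[a] - p$y[b])^2)
}

# K(r): ordered-pair sum of edge weights for d <= r, / (lambda^2 |W|)
oracle_k <- function(p, r, correction = "translation") {
  n <- length(p$x)
  area <- window_area(p$window)
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (oracle_dist(p, a, b) <= r) {
      acc <- acc + if (correction == "translation") {
        oracle_translation_weight(p, a, b)
      } else 1
    }
  }
  acc / (n * (n - 1) / area)
}

oracle_cross_k <- function(p, i, j, r, correction = "translation") {
  si <- which(p$type == i); sj <- which(p$type == j)
  area <- window_area(p$window)
  acc <- 0
  for (a in si) for (b in sj) {
    if (oracle_dist(p, a, b) <= r) {
      acc <- acc + if (correction == "translation") {
        oracle_translation_weight(p, a, b)
      } else 1
    }
  }
  acc / (length(si) * length(sj) / area)
}

oracle_epan <- function(u, h) ifelse(abs(u) <= h, 0.75 / h * (1 - (u / h)^2), 0)

oracle_g <- function(p, r, h, correction = "translation") {
  n <- length(p$x)
  area <- window_area(p$window)
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    w <- if (correction == "translation") oracle_translation_weight(p, a, b) else 1
    acc <- acc + w * oracle_epan(oracle_dist(p, a, b) - r, h)
  }
  acc / (2 * pi * r * n * (n - 1) / area)
}

oracle_cross_g <- function(p, i, j, r, h, correction = "translation") {
  si <- which(p$type == i); sj <- which(p$type == j)
  area <- window_area(p$window)
  acc <- 0
  for (a in si) for (b in sj) {
    w <- if (correction == "translation") oracle_translation_weight(p, a, b) else 1
    acc <- acc + w * oracle_epan(oracle_dist(p, a, b) - r, h)
  }
  acc / (2 * pi * r * length(si) * length(sj) / area)
}

# normalised mcf = g_ij / g over the pooled two-type pattern
oracle_mcf <- function(p, i, j, r, h, normalised = TRUE) {
  keep <- p$type %in% c(i, j)
  pp <- list(x = p$x[keep], y = p$y[keep], type = p$type[keep],
             window = p$window)
  val <- oracle_cross_g(pp, i, j, r, h) / oracle_g(pp, r, h)
  if (!normalised) {
    area <- window_area(p$window)
    li <- sum(pp$type == i) / area
    lj <- sum(pp$type == j) / area
    val <- val * li * lj / (li + lj)
  }
  val
}

# literal Moran's I at one distance band
oracle_moran <- function(p, i, j, mark, r, halfwidth) {
  si <- which(p$type == i); sj <- which(p$type == j)
  mi <- p$marks[[mark]][si]; mj <- p$marks[[mark]][sj]
  mpool <- mean(c(mi, mj))
  den <- sum((mi - mpool)^2) + sum((mj - mpool)^2)
  num <- 0
  for (a in seq_along(si)) for (b in seq_along(sj)) {
    d <- oracle_dist(p, si[a], sj[b])
    if (abs(d - r) <= halfwidth) {
      num <- num + (mi[a] - mean(mi)) * (mj[b] - mean(mj))
    }
  }
  num / den
}

# Breslow-ties Cox partial log-likelihood by direct risk-set loops
oracle_cox_loglik <- function(W, time, status, gamma) {
  eta <- drop(as.matrix(W) %*% gamma)
  acc <- 0
  for (k in which(status == 1)) {
    acc <- acc + eta[k] - log(sum(exp(eta[time >= time[k]])))
  }
  acc
}

numeric_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

numeric_hessian <- function(f, x, eps = 1e-4) {
  q <- length(x)
  H <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in seq_len(q)) {
    xpp <- x; xpp[a] <- xpp[a] + eps; xpp[b] <- xpp[b] + eps
    xpm <- x; xpm[a] <- xpm[a] + eps; xpm[b] <- xpm[b] - eps
    xmp <- x; xmp[a] <- xmp[a] - eps; xmp[b] <- xmp[b] + eps
    xmm <- x; xmm[a] <- xmm[a] - eps; xmm[b] <- xmm[b] - eps
    H[a, b] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}

# random small two-type marked pattern for property tests
random_test_pattern <- function(n = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(n, 8)
  x <- runif(n); y <- runif(n)
  type <- c("t1", "t2", "t1", "t2",
            sample(c("t1", "t2"), n - 4, replace = TRUE))
  mpp(x, y, type, marks = data.frame(marker = rnorm(n)),
      window = obs_window(0, 1, 0, 1), subject_id = "rnd", image_id = "1",
      type_levels = c("t1", "t2"))
}

# small survival data with a binary covariate and ties
toy_surv <- function() {
  list(W = matrix(c(1, 0, 1, 0, 1), ncol = 1),
       time = c(2, 2, 3, 5, 7),
       status = c(1, 1, 1, 0, 1))
}
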