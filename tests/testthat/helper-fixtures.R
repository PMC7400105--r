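# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, closed forms) and never call the code paths they check.

# Build a measurement_set from a wide data.frame of readings.
toy_ms <- function(df, sensors) {
  measurement_set(df[, setdiff(names(df), sensors), drop = FALSE],
                  as.matrix(df[, sensors, drop = FALSE]), sensors)
}

# Random multi-session set: well-separated class means plus optional
# per-session additive drift, isotropic Gaussian noise.
rand_ms <- function(seed = 1, sessions = 2, rounds = 4,
                    classes = c("A", "B", "C"),
                    sensors = c("s1", "s2", "s3"),
                    sep = 10, sd = 1, drift = 0) {
  set.seed(seed)
  p <- length(sensors)
  K <- length(classes)
  mu <- matrix(stats::rnorm(K * p, sd = sep), K, p,
               dimnames = list(classes, sensors))
  d <- matrix(0, sessions, p)
  if (sessions > 1 && drift > 0) {
    for (w in 2:sessions) d[w, ] <- d[w - 1, ] + stats::rnorm(p, sd = drift)
  }
  meta <- expand.grid(class = classes, round = seq_len(rounds) - 1L,
                      session = seq_len(sessions) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("session", "round", "class")]
  meta$sample_id <- meta$class
  vals <- mu[meta$class, , drop = FALSE] + d[meta$session + 1L, , drop = FALSE] +
    matrix(stats::rnorm(nrow(meta) * p, sd = sd), ncol = p)
  measurement_set(meta, vals, sensors)
}

# Brute-force robust z-scores of centroid distances for one group.
oracle_robust_z <- function(x) {
  ctr <- colMeans(x)
  d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) d[i] <- sqrt(sum((x[i, ] - ctr)^2))
  med <- stats::median(d)
  madv <- stats::median(abs(d - med))
  0.6745 * (d - med) / madv
}

# Closed-form simple OLS via normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Equal-covariance Gaussian classifier from first principles: explicit
# per-class log-likelihood with pooled covariance and count priors.
oracle_lda_predict <- function(Xtr, ytr, Xte) {
  labels <- sort(unique(ytr))
  p <- ncol(Xtr)
  n <- nrow(Xtr)
  mus <- list()
  Sw <- matrix(0, p, p)
  for (cl in labels) {
    xc <- Xtr[ytr == cl, , drop = FALSE]
    mus[[cl]] <- colMeans(xc)
    cc <- sweep(xc, 2, mus[[cl]])
    Sw <- Sw + t(cc) %*% cc
  }
  Sw <- Sw / (n - length(labels))
  Si <- solve(Sw)
  pred <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    ll <- vapply(labels, function(cl) {
      d <- Xte[i, ] - mus[[cl]]
      -0.5 * drop(t(d) %*% Si %*% d) + log(sum(ytr == cl) / n)
    }, numeric(1))
    pred[i] <- labels[which.max(ll)]
  }
  pred
}

expect_ms_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tolerance)
  expect_identical(a$meta$session, b$meta$session)
  expect_identical(a$meta$class, b$meta$class)
}
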