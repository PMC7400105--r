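#' Fit a canonical linear discriminant analysis model
#'
#' Classic multiclass LDA with a shared within-class covariance: the
#' canonical discriminant axes `W` solve the generalized eigenproblem of
#' between-class versus pooled within-class scatter, scaled so that
#' `t(W) %*% S_W %*% W = I` (scatter-orthonormal), and are ordered by
#' decreasing between/within eigenvalue. At most `min(K - 1, p)` axes are
#' retained (3 for 4 classes in 7-sensor space). Classification uses linear
#' discriminant scores under the equal-covariance Gaussian model with priors
#' proportional to training counts.
#'
#' If the pooled scatter is numerically singular a ridge `eps * I` is added
#' with a warning (`ridge = FALSE` turns this into an error).
#'
#' @param ms measurement_set, normally restricted to the model-building
#'   session (see `session`)
#' @param session optional session index to restrict to before fitting
#' @param ridge logical: fall back to a ridge-regularized pooled scatter when
#'   it is singular (default TRUE, with a warning)
#' @return object of class `etongue_lda` with elements `labels`, `means`,
#'   `cov_within` (pooled within-class covariance), `cov_inv`, `scaling`
#'   (the canonical basis W), `eigenvalues`, `priors`, `grand_mean`,
#'   `sensors`, `counts`
#' @export
fit_lda <- function(ms, session = NULL, ridge = TRUE) {
  if (!is.null(session)) ms <- subset_sessions(ms, session)
  X <- ms$values
  y <- ms$meta$class
  labels <- sort(unique(y))
  K <- length(labels)
  p <- ncol(X)
  n <- nrow(X)
  if (K < 2L) stop("LDA needs at least two classes")
  counts <- vapply(labels, function(cl) sum(y == cl), integer(1))
  if (any(counts < 2L)) {
    stop("every class needs at least two observations")
  }
  means <- t(vapply(labels, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  grand_mean <- colMeans(X)
  Sw <- matrix(0, p, p)
  for (i in seq_len(K)) {
    xc <- sweep(X[y == labels[i], , drop = FALSE], 2L, means[i, ])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - K)
  Sb <- matrix(0, p, p)
  for (i in seq_len(K)) {
    d <- means[i, ] - grand_mean
    Sb <- Sb + counts[i] * tcrossprod(d)
  }
  Sb <- Sb / (K - 1)
  ew <- eigen(Sw, symmetric = TRUE)
  tol <- max(ew$values) * p * .Machine$double.eps
  ridged <- FALSE
  if (min(ew$values) <= tol) {
    if (!ridge) stop("pooled within-class scatter is singular")
    eps <- max(ew$values) * 1e-8
    warning(sprintf(
      "pooled within-class scatter is singular; adding ridge %.3g * I", eps))
    Sw <- Sw + diag(eps, p)
    ew <- eigen(Sw, symmetric = TRUE)
    ridged <- TRUE
  }
  Sw_isqrt <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  A <- Sw_isqrt %*% Sb %*% Sw_isqrt
  A <- (A + t(A)) / 2
  ea <- eigen(A, symmetric = TRUE)
  r <- min(K - 1L, p)
  W <- Sw_isqrt %*% ea$vectors[, seq_len(r), drop = FALSE]
  # deterministic sign: largest-magnitude element of each axis positive
  for (j in seq_len(r)) {
    piv <- which.max(abs(W[, j]))
    if (W[piv, j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(ms$sensors, paste0("LD", seq_len(r)))
  structure(
    list(labels = labels, means = means, cov_within = Sw,
         cov_inv = Sw_isqrt %*% Sw_isqrt, scaling = W,
         eigenvalues = ea$values[seq_len(r)],
         priors = counts / n, grand_mean = grand_mean,
         sensors = ms$sensors, counts = counts, ridged = ridged),
    class = "etongue_lda"
  )
}

#' @export
print.etongue_lda <- function(x, ...) {
  cat(sprintf("canonical LDA: %d classes, %d sensors, %d discriminant axes\n",
              length(x$labels), length(x$sensors), ncol(x$scaling)))
  cat("  between/within eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Predict class labels and discriminant coordinates
#'
#' Labels are the argmax of the linear discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`; coordinates are the
#' projection of the (grand-mean-centered) readings onto the canonical basis.
#'
#' @param object `etongue_lda` model
#' @param ms measurement_set (or bare numeric matrix with matching columns)
#' @param ... unused
#' @return list with `label` (character vector), `coords` (n x r matrix of
#'   discriminant-space coordinates) and `score` (n x K matrix of
#'   discriminant scores)
#' @export
predict.etongue_lda <- function(object, ms, ...) {
  X <- if (inherits(ms, "measurement_set")) {
    if (!identical(ms$sensors, object$sensors)) {
      stop("sensor channels of data and model do not match")
    }
    ms$values
  } else {
    X <- as.matrix(ms)
    if (ncol(X) != length(object$sensors)) {
      stop("sensor channels of data and model do not match")
    }
    X
  }
  K <- length(object$labels)
  score <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, object$labels))
  for (k in seq_len(K)) {
    mu <- object$means[k, ]
    a <- object$cov_inv %*% mu
    score[, k] <- X %*% a - 0.5 * sum(mu * a) + log(object$priors[k])
  }
  lab <- object$labels[max.col(score, ties.method = "first")]
  coords <- sweep(X, 2L, object$grand_mean) %*% object$scaling
  list(label = lab, coords = coords, score = score)
}
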