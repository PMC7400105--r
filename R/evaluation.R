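#' Threefold cross-validated evaluation of a multi-session experiment
#'
#' Implements the evaluation protocol for long-term drift experiments: an
#' LDA classifier is built on the base session (session 0), validated by
#' stratified threefold cross-validation, and used to predict every later
#' session. Per fold, two thirds of each class of the base session train the
#' model, the held-out third validates it, and all later-session data are
#' projected and classified. Accuracies and confusion matrices are reported
#' per (session, class), averaged over folds with their fold spread; if a
#' `target_class` and `norm_pair` are given, relative centroid distances in
#' discriminant space (see [relative_centroid_distance()]) are reported the
#' same way.
#'
#' Fold assignment is a deterministic stratified round-robin over a seeded
#' shuffle; the seed is recorded in the report.
#'
#' @param ms measurement_set (corrected or raw) containing the base session
#' @param base_session model-building session (default 0)
#' @param seed integer seed for the fold shuffle (default 1)
#' @param target_class optional class whose session-to-session centroid
#'   displacement is tracked (e.g. the apple-juice analog)
#' @param norm_pair optional character pair of classes whose base-session
#'   centroid distance normalizes the displacement
#' @param n_folds number of folds (default 3)
#' @param label free-text identifier recorded in the report (e.g. the
#'   correction method)
#' @return object of class `evaluation_report`
#' @export
threefold_cv <- function(ms, base_session = 0L, seed = 1L,
                         target_class = NULL, norm_pair = NULL,
                         n_folds = 3L, label = "raw") {
  meta <- ms$meta
  sessions <- sort(unique(meta$session))
  if (!base_session %in% sessions) {
    stop(sprintf("base session %d not present in the data", base_session))
  }
  classes <- sort(unique(meta$class[meta$session == base_session]))
  base_rows <- which(meta$session == base_session)
  fold_of <- integer(nrow(meta))
  set.seed(seed)
  for (cl in classes) {
    idx <- which(meta$session == base_session & meta$class == cl)
    if (length(idx) < n_folds) {
      stop(sprintf("class %s has %d observation(s) in session %d; need >= %d",
                   cl, length(idx), base_session, n_folds))
    }
    shuffled <- idx[sample.int(length(idx))]
    fold_of[shuffled] <- rep_len(seq_len(n_folds), length(shuffled))
  }
  if (!is.null(target_class) || !is.null(norm_pair)) {
    if (is.null(target_class) || is.null(norm_pair) ||
        length(norm_pair) != 2L) {
      stop("`target_class` and a 2-element `norm_pair` must be given together")
    }
    if (!all(c(target_class, norm_pair) %in% classes)) {
      stop("target/norm classes must be present in the base session")
    }
  }

  acc_folds <- expand.grid(fold = seq_len(n_folds), session = sessions,
                           class = classes, KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  acc_folds$accuracy <- NA_real_
  conf_folds <- vector("list", n_folds)
  dist_folds <- NULL
  if (!is.null(target_class)) {
    dist_folds <- expand.grid(fold = seq_len(n_folds), session = sessions,
                              KEEP.OUT.ATTRS = FALSE)
    dist_folds$distance <- NA_real_
  }
  models <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    train_rows <- base_rows[fold_of[base_rows] != f]
    train_ms <- measurement_set(meta[train_rows, , drop = FALSE],
                                ms$values[train_rows, , drop = FALSE],
                                ms$sensors)
    model <- fit_lda(train_ms)
    models[[f]] <- model
    conf_folds[[f]] <- list()
    for (s in sessions) {
      eval_rows <- if (s == base_session) {
        base_rows[fold_of[base_rows] == f]
      } else {
        which(meta$session == s)
      }
      truth <- meta$class[eval_rows]
      pred <- predict(model, ms$values[eval_rows, , drop = FALSE])$label
      conf <- table(factor(truth, levels = classes),
                    factor(pred, levels = classes))
      conf_folds[[f]][[as.character(s)]] <- unclass(conf)
      for (cl in intersect(classes, unique(truth))) {
        hit <- acc_folds$fold == f & acc_folds$session == s &
          acc_folds$class == cl
        acc_folds$accuracy[hit] <-
          100 * mean(pred[truth == cl] == cl)
      }
    }
    if (!is.null(target_class)) {
      d <- relative_centroid_distance(model, ms, target_class, norm_pair,
                                      base_session = base_session)
      dist_folds$distance[dist_folds$fold == f] <-
        d[match(dist_folds$session[dist_folds$fold == f], as.integer(names(d)))]
    }
  }

  agg <- stats::aggregate(accuracy ~ session + class, data = acc_folds,
                          FUN = mean, na.action = stats::na.pass)
  names(agg)[names(agg) == "accuracy"] <- "mean"
  sdv <- stats::aggregate(accuracy ~ session + class, data = acc_folds,
                          FUN = stats::sd, na.action = stats::na.pass)
  agg$sd <- sdv$accuracy
  agg <- agg[order(agg$session, agg$class), , drop = FALSE]
  rownames(agg) <- NULL

  confusion <- list()
  for (s in sessions) {
    mats <- lapply(conf_folds, `[[`, as.character(s))
    confusion[[as.character(s)]] <- if (s == base_session) {
      Reduce(`+`, mats)            # held-out thirds tile session 0 exactly once
    } else {
      Reduce(`+`, mats) / n_folds  # every observation scored in each fold
    }
  }

  distances <- NULL
  if (!is.null(dist_folds)) {
    distances <- stats::aggregate(distance ~ session, data = dist_folds,
                                  FUN = mean)
    names(distances)[2L] <- "mean"
    distances$sd <- stats::aggregate(distance ~ session, data = dist_folds,
                                     FUN = stats::sd)$distance
  }

  structure(
    list(label = label, accuracy = agg, accuracy_folds = acc_folds,
         confusion = confusion, confusion_folds = conf_folds,
         distances = distances, distance_folds = dist_folds,
         folds = data.frame(row = base_rows, fold = fold_of[base_rows]),
         models = models, seed = as.integer(seed),
         base_session = as.integer(base_session),
         target_class = target_class, norm_pair = norm_pair,
         classes = classes, sessions = sessions),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report ('%s'): %d sessions, %d classes, seed %d\n",
              x$label, length(x$sessions), length(x$classes), x$seed))
  cat("per-(session, class) accuracy (%), mean over folds:\n")
  wide <- stats::reshape(x$accuracy[, c("session", "class", "mean")],
                         idvar = "session", timevar = "class",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Session accuracy of one class
#'
#' Convenience accessor for the per-fold-mean accuracy of one class across
#' sessions.
#'
#' @param report evaluation_report
#' @param class class label
#' @return named numeric vector, one entry per session, in %
#' @export
class_accuracy <- function(report, class) {
  sub <- report$accuracy[report$accuracy$class == class, , drop = FALSE]
  stats::setNames(sub$mean, sub$session)
}

#' Relative centroid displacement of a class across sessions
#'
#' In the discriminant space of `model`, computes for every session `w` the
#' Euclidean distance between the target-class centroid at session `w` and
#' at the base session, normalized by the base-session distance between the
#' two `norm_pair` class centroids.
#'
#' @param model `etongue_lda`
#' @param ms measurement_set covering the sessions of interest
#' @param target_class class whose displacement is tracked
#' @param norm_pair character vector of two class labels whose base-session
#'   centroid distance is the unit
#' @param base_session baseline session (default 0)
#' @return named numeric vector of relative distances, one per session
#' @export
relative_centroid_distance <- function(model, ms, target_class, norm_pair,
                                       base_session = 0L) {
  stopifnot(inherits(model, "etongue_lda"), length(norm_pair) == 2L)
  pr <- predict(model, ms)
  meta <- ms$meta
  sessions <- sort(unique(meta$session))
  cen <- function(rows) colMeans(pr$coords[rows, , drop = FALSE])
  tgt0_rows <- meta$session == base_session & meta$class == target_class
  a_rows <- meta$session == base_session & meta$class == norm_pair[1L]
  b_rows <- meta$session == base_session & meta$class == norm_pair[2L]
  if (!any(tgt0_rows) || !any(a_rows) || !any(b_rows)) {
    stop("target and norm-pair classes must be observed in the base session")
  }
  tgt0 <- cen(tgt0_rows)
  normalizer <- sqrt(sum((cen(a_rows) - cen(b_rows))^2))
  if (normalizer == 0) stop("norm-pair centroids coincide: zero normalizer")
  out <- vapply(sessions, function(s) {
    rows <- meta$session == s & meta$class == target_class
    if (!any(rows)) return(NA_real_)
    sqrt(sum((cen(rows) - tgt0)^2)) / normalizer
  }, numeric(1))
  stats::setNames(out, sessions)
}

#' Euclidean distances between group centroids in sensor space
#'
#' Full sensor-space (e.g. seven-dimensional) distances of every group
#' centroid from a reference group's centroid; groups are any stated factor
#' such as temperature level or concentration.
#'
#' @param ms measurement_set (or numeric matrix)
#' @param group vector of group labels, one per observation
#' @param reference the reference group label
#' @return named numeric vector of distances, one per group
#' @export
centroid_distances_sensor_space <- function(ms, group, reference) {
  X <- if (inherits(ms, "measurement_set")) ms$values else as.matrix(ms)
  group <- as.character(group)
  if (length(group) != nrow(X)) {
    stop("`group` must have one label per observation")
  }
  levels <- unique(group)
  if (!reference %in% levels) stop("empty reference group")
  cen <- function(g) {
    rows <- group == g
    if (!any(rows)) stop(sprintf("empty group: %s", g))
    colMeans(X[rows, , drop = FALSE])
  }
  ref <- cen(as.character(reference))
  vapply(stats::setNames(levels, levels),
         function(g) sqrt(sum((cen(g) - ref)^2)), numeric(1))
}

#' Univariate ordinary-least-squares trend
#'
#' @param x predictor (e.g. repeat number, temperature difference)
#' @param y response (e.g. pH, centroid distance)
#' @return object of class `trend_fit` with `slope`, `intercept`,
#'   `r_squared` and `n`. A constant response yields slope 0 and, by
#'   convention, R^2 = 0 with a warning.
#' @export
fit_trend <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("`x` is constant; no trend is identifiable")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("constant response: R^2 set to 0 by convention")
    r2 <- 0
  } else {
    r2 <- 1 - sum((y - (intercept + slope * x))^2) / sst
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: y = %.6g + %.6g * x  (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Column-centered principal component analysis
#'
#' Thin wrapper used for order-dependence (memory-effect) inspection and for
#' drift-direction diagnostics: column-centered PCA with unit-norm loadings
#' and non-increasing explained variance.
#'
#' @param ms measurement_set or numeric matrix
#' @param n_components number of components to keep (default: all)
#' @return list with `scores`, `loadings`, `explained_variance` (proportions)
#'   and `sdev`
#' @export
pca_scores <- function(ms, n_components = NULL) {
  X <- if (inherits(ms, "measurement_set")) ms$values else as.matrix(ms)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  r <- length(pc$sdev)
  k <- if (is.null(n_components)) r else min(as.integer(n_components), r)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

#' Serialize an evaluation report to JSON
#'
#' @param report evaluation_report
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_evaluation_report <- function(report, path) {
  doc <- list(
    label = report$label,
    seed = report$seed,
    base_session = report$base_session,
    sessions = report$sessions,
    classes = report$classes,
    target_class = report$target_class,
    norm_pair = report$norm_pair,
    accuracy = report$accuracy,
    confusion = lapply(report$confusion, function(m) {
      list(classes = rownames(m), counts = unname(apply(m, 1L, as.list)))
    }),
    distances = report$distances,
    software_version = as.character(utils::packageVersion("etdrift"))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the per-(session, class) accuracy table as CSV
#'
#' @param report evaluation_report
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_accuracy_csv <- function(report, path) {
  df <- report$accuracy
  df <- cbind(label = report$label, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
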