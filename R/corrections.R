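#' @title Drift-correction methods for multi-session sensor-array data
#'
#' @description
#' Four corrections are provided, each as a fit/apply pair:
#'
#' * **Additive, relative to all samples** ([fit_additive_all()]): within
#'   every (session, round) block the per-sensor mean over *all* samples is
#'   subtracted, zero-centering each repeat. Requires every repeat to measure
#'   the same sample set in the same sequence.
#' * **Additive, relative to reference samples** ([fit_additive_reference()]):
#'   as above, but the subtracted mean is computed over designated reference
#'   classes only, so the remaining samples may vary between repeats.
#' * **Multi-sensor linear correction** ([fit_linear_map()]): drift between
#'   sessions may be multiplicative as well as additive, so for every sensor
#'   an affine map `y = m*x + b` is regressed from the later-session
#'   reference-class centroids (x) onto the base-session ones (y) and applied
#'   to every reading of that session. At least two reference classes are
#'   required. Fitted per session, not per round.
#' * **Component correction** ([fit_drift_component()]): the dominant
#'   principal-component loading `p` of pooled reference-sample readings from
#'   a session pair estimates the drift direction; the projection onto `p` is
#'   removed from the data (classic variant), or subtracted twice from the
#'   later session only (modified variant), reflecting later sessions onto
#'   the baseline while keeping the baseline — and the information along the
#'   drift direction — intact.
#'
#' [correct()] dispatches over all methods by name.
#' @name corrections
NULL

blocks_of <- function(meta) {
  key <- paste(meta$session, meta$round, sep = "\r")
  ub <- !duplicated(key)
  list(key = key, blocks = meta[ub, c("session", "round"), drop = FALSE],
       block_key = key[ub])
}

#' Fit the additive correction relative to all samples
#'
#' Computes, for every (session, round) block and sensor, the mean reading
#' over all samples in that block. Subtracting it (see [apply_additive()])
#' zero-centers every repeat, absorbing any offset-type drift. Every block
#' must contain the complete sample-class set, since the method assumes the
#' same sample set and sequence in every repeat.
#'
#' @param ms measurement_set
#' @return object of class `additive_offsets`
#' @export
fit_additive_all <- function(ms) {
  bl <- blocks_of(ms$meta)
  classes <- sort(unique(ms$meta$class))
  offs <- matrix(NA_real_, nrow = nrow(bl$blocks), ncol = length(ms$sensors),
                 dimnames = list(NULL, ms$sensors))
  for (i in seq_len(nrow(bl$blocks))) {
    rows <- bl$key == bl$block_key[i]
    have <- sort(unique(ms$meta$class[rows]))
    if (!identical(have, classes)) {
      stop(sprintf(
        "block (session=%d, round=%d) is incomplete: missing class(es) %s",
        bl$blocks$session[i], bl$blocks$round[i],
        paste(setdiff(classes, have), collapse = ", ")
      ))
    }
    offs[i, ] <- colMeans(ms$values[rows, , drop = FALSE])
  }
  structure(
    list(blocks = bl$blocks, offsets = offs, basis = "all_samples",
         reference_classes = character(0), sensors = ms$sensors),
    class = "additive_offsets"
  )
}

#' Fit the additive correction relative to reference samples
#'
#' As [fit_additive_all()], but the per-block per-sensor mean is taken over
#' observations of the designated reference classes only; the shift of the
#' references stands in for the drift of the whole block.
#'
#' @param ms measurement_set
#' @param reference_classes character vector of class labels used as
#'   references; every block must contain at least one observation of each.
#' @return object of class `additive_offsets`
#' @export
fit_additive_reference <- function(ms, reference_classes) {
  reference_classes <- as.character(reference_classes)
  if (length(reference_classes) < 1L) {
    stop("at least one reference class is required")
  }
  missing_cls <- setdiff(reference_classes, unique(ms$meta$class))
  if (length(missing_cls) > 0L) {
    stop("reference class(es) absent from the data: ",
         paste(missing_cls, collapse = ", "))
  }
  bl <- blocks_of(ms$meta)
  offs <- matrix(NA_real_, nrow = nrow(bl$blocks), ncol = length(ms$sensors),
                 dimnames = list(NULL, ms$sensors))
  for (i in seq_len(nrow(bl$blocks))) {
    rows <- bl$key == bl$block_key[i] & ms$meta$class %in% reference_classes
    have <- unique(ms$meta$class[rows])
    if (!all(reference_classes %in% have)) {
      stop(sprintf(
        "block (session=%d, round=%d) lacks reference class(es) %s",
        bl$blocks$session[i], bl$blocks$round[i],
        paste(setdiff(reference_classes, have), collapse = ", ")
      ))
    }
    offs[i, ] <- colMeans(ms$values[rows, , drop = FALSE])
  }
  structure(
    list(blocks = bl$blocks, offsets = offs, basis = "reference_classes",
         reference_classes = reference_classes, sensors = ms$sensors),
    class = "additive_offsets"
  )
}

#' Apply a fitted additive correction
#'
#' Subtracts the fitted per-(session, round, sensor) offset from every cell:
#' `X' = X - Xbar`, yielding zero-centered values over the fitted basis set.
#'
#' @param ms measurement_set
#' @param model `additive_offsets` from [fit_additive_all()] or
#'   [fit_additive_reference()]
#' @return corrected measurement_set
#' @export
apply_additive <- function(ms, model) {
  stopifnot(inherits(model, "additive_offsets"))
  if (!identical(ms$sensors, model$sensors)) {
    stop("sensor channels of data and model do not match")
  }
  key <- paste(ms$meta$session, ms$meta$round, sep = "\r")
  bkey <- paste(model$blocks$session, model$blocks$round, sep = "\r")
  idx <- match(key, bkey)
  if (anyNA(idx)) {
    bad <- ms$meta[which(is.na(idx))[1L], ]
    stop(sprintf("block (session=%d, round=%d) is not covered by the model",
                 bad$session, bad$round))
  }
  measurement_set(ms$meta, ms$values - model$offsets[idx, , drop = FALSE],
                  ms$sensors)
}

class_centroids <- function(ms, classes, session) {
  rows <- ms$meta$session == session & ms$meta$class %in% classes
  sub <- ms$values[rows, , drop = FALSE]
  cls <- ms$meta$class[rows]
  t(vapply(classes, function(cl) colMeans(sub[cls == cl, , drop = FALSE]),
           numeric(ncol(ms$values))))
}

#' Fit the multi-sensor linear correction
#'
#' For every session other than the base session and every sensor, fits by
#' ordinary least squares the line `y = m*x + b` through the points
#' (later-session reference-class centroid, base-session reference-class
#' centroid), one point per reference class. The base session maps to the
#' identity (m = 1, b = 0).
#'
#' @param ms measurement_set
#' @param reference_classes at least two class labels, present in the base
#'   and every other session
#' @param base_session session regressed onto (default 0)
#' @return object of class `affine_sensor_map`
#' @export
fit_linear_map <- function(ms, reference_classes, base_session = 0L) {
  reference_classes <- as.character(reference_classes)
  if (length(reference_classes) < 2L) {
    stop("multi-sensor linear correction requires at least two reference classes")
  }
  sessions <- sort(unique(ms$meta$session))
  if (!base_session %in% sessions) {
    stop(sprintf("base session %d not present in the data", base_session))
  }
  for (s in sessions) {
    have <- unique(ms$meta$class[ms$meta$session == s])
    miss <- setdiff(reference_classes, have)
    if (length(miss) > 0L) {
      stop(sprintf("session %d lacks reference class(es) %s",
                   s, paste(miss, collapse = ", ")))
    }
  }
  p <- length(ms$sensors)
  m <- matrix(1, nrow = length(sessions), ncol = p,
              dimnames = list(NULL, ms$sensors))
  b <- matrix(0, nrow = length(sessions), ncol = p,
              dimnames = list(NULL, ms$sensors))
  y_cent <- class_centroids(ms, reference_classes, base_session)
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    if (s == base_session) next
    x_cent <- class_centroids(ms, reference_classes, s)
    for (j in seq_len(p)) {
      x <- x_cent[, j]
      y <- y_cent[, j]
      vx <- sum((x - mean(x))^2)
      if (vx == 0) {
        stop(sprintf(
          "sensor %s has zero variance across reference centroids in session %d",
          ms$sensors[j], s
        ))
      }
      m[i, j] <- sum((x - mean(x)) * (y - mean(y))) / vx
      b[i, j] <- mean(y) - m[i, j] * mean(x)
    }
  }
  structure(
    list(sessions = sessions, m = m, b = b,
         reference_classes = reference_classes,
         base_session = as.integer(base_session), sensors = ms$sensors),
    class = "affine_sensor_map"
  )
}

#' Apply a fitted multi-sensor linear correction
#'
#' Transforms every cell of session `w` by its fitted per-sensor affine map:
#' `X' = m*X + b`. The base session is left unchanged (identity map). Applied
#' per session, not per round.
#'
#' @param ms measurement_set
#' @param model `affine_sensor_map` from [fit_linear_map()]
#' @return corrected measurement_set
#' @export
apply_linear_map <- function(ms, model) {
  stopifnot(inherits(model, "affine_sensor_map"))
  if (!identical(ms$sensors, model$sensors)) {
    stop("sensor channels of data and model do not match")
  }
  idx <- match(ms$meta$session, model$sessions)
  if (anyNA(idx)) {
    stop(sprintf("session %d is not covered by the model",
                 ms$meta$session[which(is.na(idx))[1L]]))
  }
  vals <- model$m[idx, , drop = FALSE] * ms$values +
    model$b[idx, , drop = FALSE]
  measurement_set(ms$meta, vals, ms$sensors)
}

#' Fit drift components for component correction
#'
#' For each session pair (base, w) dictated by `pairing`, reference-class
#' observations of the two sessions are pooled; the pooled mean `c` and the
#' first principal-component loading `p` of the mean-centered pool estimate
#' the drift position and direction. The sign of `p` is fixed so that the
#' base-to-later centroid displacement has a non-negative projection
#' (cosmetic: the correction is invariant to the sign of `p`).
#'
#' @param ms measurement_set
#' @param reference_class single class label used to trace the drift
#' @param pairing `"each_week_to_week0"` (one component per later session,
#'   paired with the base) or `"first_last"` (a single component from the
#'   base and the last session)
#' @param base_session baseline session (default 0)
#' @param multiplier 1 for the classic correction (drift projection removed
#'   from every targeted session) or 2 for the modified correction (twice the
#'   drift subtracted from the later session only)
#' @return object of class `drift_correction` holding one component per pair
#' @export
fit_drift_component <- function(ms, reference_class,
                                pairing = c("each_week_to_week0", "first_last"),
                                base_session = 0L, multiplier = 1L) {
  pairing <- match.arg(pairing)
  multiplier <- as.integer(multiplier)
  if (!multiplier %in% c(1L, 2L)) stop("`multiplier` must be 1 or 2")
  reference_class <- as.character(reference_class)
  if (length(reference_class) != 1L) {
    stop("component correction uses a single reference class")
  }
  sessions <- sort(unique(ms$meta$session))
  if (!base_session %in% sessions) {
    stop(sprintf("base session %d not present in the data", base_session))
  }
  later <- setdiff(sessions, base_session)
  if (length(later) == 0L) stop("need at least two sessions")
  pairs <- if (pairing == "first_last") max(later) else later
  comps <- lapply(pairs, function(w) {
    rows <- ms$meta$class == reference_class &
      ms$meta$session %in% c(base_session, w)
    for (s in c(base_session, w)) {
      if (!any(rows & ms$meta$session == s)) {
        stop(sprintf("reference class %s not observed in session %d",
                     reference_class, s))
      }
    }
    x <- ms$values[rows, , drop = FALSE]
    ctr <- colMeans(x)
    xc <- sweep(x, 2L, ctr)
    if (max(abs(xc)) == 0) {
      stop("pooled reference observations have zero variance (rank 0)")
    }
    p <- svd(xc, nu = 0L, nv = 1L)$v[, 1L]
    p <- p / sqrt(sum(p^2))
    mu_base <- colMeans(ms$values[rows & ms$meta$session == base_session, ,
                                  drop = FALSE])
    mu_w <- colMeans(ms$values[rows & ms$meta$session == w, , drop = FALSE])
    if (sum((mu_w - mu_base) * p) < 0) p <- -p
    list(base = as.integer(base_session), later = as.integer(w),
         center = ctr, loading = p)
  })
  structure(
    list(components = comps, pairing = pairing, multiplier = multiplier,
         reference_class = reference_class,
         base_session = as.integer(base_session), sensors = ms$sensors),
    class = "drift_correction"
  )
}

#' Apply a fitted component correction
#'
#' For every targeted observation `x`, the drift score `t = (x - c) . p` is
#' computed and `multiplier * t * p` subtracted. With `multiplier = 1` the
#' targets are all sessions (pairing `"first_last"`, the classic correction)
#' or both sessions of each pair; with `multiplier = 2` only the later
#' session of each pair is touched, so the baseline session passes through
#' bit-identically and later sessions are reflected onto it.
#'
#' @param ms measurement_set
#' @param model `drift_correction` from [fit_drift_component()]
#' @return corrected measurement_set
#' @export
apply_component_correction <- function(ms, model) {
  stopifnot(inherits(model, "drift_correction"))
  if (!identical(ms$sensors, model$sensors)) {
    stop("sensor channels of data and model do not match")
  }
  vals <- ms$values
  all_sessions <- unique(ms$meta$session)
  for (comp in model$components) {
    targets <- if (model$multiplier == 2L) {
      comp$later
    } else if (model$pairing == "first_last") {
      all_sessions
    } else {
      c(comp$base, comp$later)
    }
    rows <- ms$meta$session %in% targets
    if (!any(rows)) next
    tt <- sweep(vals[rows, , drop = FALSE], 2L, comp$center) %*% comp$loading
    vals[rows, ] <- vals[rows, , drop = FALSE] -
      model$multiplier * tt %*% t(comp$loading)
  }
  measurement_set(ms$meta, vals, ms$sensors)
}

#' Correction method registry
#' @return character vector of method names accepted by [correct()]
#' @export
correction_methods <- function() {
  c("none", "additive_all", "additive_ref", "linear_ref", "cc", "cc_modified")
}

#' Fit and apply a drift correction by name
#'
#' Dispatches over the method registry:
#' `none` (raw passthrough), `additive_all`, `additive_ref`, `linear_ref`
#' (multi-sensor linear correction), `cc` (classic component correction:
#' single first/last-session component applied to all sessions) and
#' `cc_modified` (per-session pairing with the base, twice the drift
#' subtracted from later sessions only).
#'
#' @param ms measurement_set
#' @param method one of [correction_methods()]
#' @param reference_classes class labels for `additive_ref` / `linear_ref`
#' @param reference_class single class label for `cc` / `cc_modified`
#' @param base_session baseline session (default 0)
#' @return list with elements `corrected` (measurement_set) and `model`
#'   (the fitted model object; for `none`, a marker list)
#' @export
correct <- function(ms, method = correction_methods(),
                    reference_classes = NULL, reference_class = NULL,
                    base_session = 0L) {
  method <- match.arg(method)
  switch(method,
    none = list(corrected = ms,
                model = structure(list(method = "none"), class = "no_correction")),
    additive_all = {
      model <- fit_additive_all(ms)
      list(corrected = apply_additive(ms, model), model = model)
    },
    additive_ref = {
      if (is.null(reference_classes)) {
        stop("method 'additive_ref' requires `reference_classes`")
      }
      model <- fit_additive_reference(ms, reference_classes)
      list(corrected = apply_additive(ms, model), model = model)
    },
    linear_ref = {
      if (is.null(reference_classes)) {
        stop("method 'linear_ref' requires `reference_classes`")
      }
      model <- fit_linear_map(ms, reference_classes, base_session)
      list(corrected = apply_linear_map(ms, model), model = model)
    },
    cc = {
      if (is.null(reference_class)) {
        stop("method 'cc' requires `reference_class`")
      }
      model <- fit_drift_component(ms, reference_class,
                                   pairing = "first_last",
                                   base_session = base_session,
                                   multiplier = 1L)
      list(corrected = apply_component_correction(ms, model), model = model)
    },
    cc_modified = {
      if (is.null(reference_class)) {
        stop("method 'cc_modified' requires `reference_class`")
      }
      model <- fit_drift_component(ms, reference_class,
                                   pairing = "each_week_to_week0",
                                   base_session = base_session,
                                   multiplier = 2L)
      list(corrected = apply_component_correction(ms, model), model = model)
    }
  )
}

#' Serialize a fitted correction model to JSON
#'
#' Writes method name, fitted parameters, reference classes and the package
#' version, for audit and re-application.
#'
#' @param model a fitted correction model (`additive_offsets`,
#'   `affine_sensor_map`, `drift_correction`, or the `none` marker)
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_correction_model <- function(model, path) {
  doc <- correction_model_json(model)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

correction_model_json <- function(model) {
  version <- as.character(utils::packageVersion("etdrift"))
  if (inherits(model, "no_correction")) {
    return(list(method = "none", software_version = version))
  }
  if (inherits(model, "additive_offsets")) {
    return(list(
      method = if (model$basis == "all_samples") "additive_all" else "additive_ref",
      basis = model$basis,
      reference_classes = model$reference_classes,
      sensors = model$sensors,
      blocks = model$blocks,
      offsets = unname(apply(model$offsets, 1L, as.list)),
      software_version = version
    ))
  }
  if (inherits(model, "affine_sensor_map")) {
    return(list(
      method = "linear_ref",
      reference_classes = model$reference_classes,
      base_session = model$base_session,
      sensors = model$sensors,
      sessions = model$sessions,
      slope = unname(apply(model$m, 1L, as.list)),
      intercept = unname(apply(model$b, 1L, as.list)),
      software_version = version
    ))
  }
  if (inherits(model, "drift_correction")) {
    return(list(
      method = if (model$multiplier == 2L) "cc_modified" else "cc",
      reference_class = model$reference_class,
      pairing = model$pairing,
      multiplier = model$multiplier,
      base_session = model$base_session,
      sensors = model$sensors,
      components = lapply(model$components, function(cp) {
        list(base = cp$base, later = cp$later,
             center = cp$center, loading = cp$loading)
      }),
      software_version = version
    ))
  }
  stop("unknown correction model class")
}
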