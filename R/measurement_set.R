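#' Construct a measurement set
#'
#' A `measurement_set` holds one multi-session sensor-array experiment: a
#' numeric matrix of readings (one row per immersion of the sensor head, one
#' column per sensor channel) together with the metadata identifying each row
#' by `(session, round, sample_id)` and its class label. Sessions index the
#' repeated (e.g. weekly) experiments, session 0 being the model-building
#' baseline; a round is one complete pass of the autosampler through the
#' sample set within a session.
#'
#' @param meta data.frame with columns `session` (integer >= 0), `round`
#'   (integer >= 0), `sample_id` (character), `class` (character) and
#'   optionally `temperature` (deg C) and `seq_pos` (integer position in the
#'   physical measurement sequence).
#' @param values numeric matrix, `nrow(meta)` rows, one named column per
#'   sensor channel. No missing values are allowed.
#' @param sensors ordered character vector of channel names; defaults to
#'   `colnames(values)`.
#' @return An object of class `measurement_set` with elements `meta`,
#'   `values` and `sensors`.
#' @export
measurement_set <- function(meta, values, sensors = colnames(values)) {
  if (!is.data.frame(meta)) stop("`meta` must be a data.frame")
  required <- c("session", "round", "sample_id", "class")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("`meta` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sensors)) stop("sensor names are required (named value columns)")
  colnames(values) <- sensors
  if (nrow(values) != nrow(meta)) {
    stop("`values` and `meta` disagree on the number of observations")
  }
  if (anyNA(values)) stop("`values` contains missing readings after validation")
  meta$session <- as.integer(meta$session)
  meta$round <- as.integer(meta$round)
  meta$sample_id <- as.character(meta$sample_id)
  meta$class <- as.character(meta$class)
  if (any(meta$session < 0L) || any(meta$round < 0L)) {
    stop("session and round indices must be >= 0")
  }
  key <- paste(meta$session, meta$round, meta$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- meta[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate observation for (session=%d, round=%d, sample_id=%s)",
      dup$session, dup$round, dup$sample_id
    ))
  }
  rownames(values) <- NULL
  rownames(meta) <- NULL
  structure(
    list(meta = meta, values = values, sensors = as.character(sensors)),
    class = "measurement_set"
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "measurement_set: %d observations, %d sensors (%s)\n",
    nrow(x$values), length(x$sensors), paste(x$sensors, collapse = ", ")
  ))
  cat(sprintf(
    "  sessions: %s | classes: %s\n",
    paste(sort(unique(x$meta$session)), collapse = ", "),
    paste(sort(unique(x$meta$class)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of observations in a measurement set
#' @param ms measurement_set
#' @return integer
#' @export
n_obs <- function(ms) nrow(ms$values)

#' Coerce a measurement set to a long-format data.frame
#'
#' @param x measurement_set
#' @param row.names,optional unused (S3 signature)
#' @param ... unused
#' @return data.frame with one row per (observation, sensor) cell; columns
#'   `session, round, sample_id, class, sensor, value` plus any covariates.
#' @export
as.data.frame.measurement_set <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n <- nrow(x$values)
  p <- length(x$sensors)
  covars <- intersect(c("temperature", "seq_pos"), names(x$meta))
  out <- data.frame(
    session = rep(x$meta$session, each = p),
    round = rep(x$meta$round, each = p),
    sample_id = rep(x$meta$sample_id, each = p),
    class = rep(x$meta$class, each = p),
    sensor = rep(x$sensors, times = n),
    value = as.vector(t(x$values)),
    stringsAsFactors = FALSE
  )
  for (cv in covars) out[[cv]] <- rep(x$meta[[cv]], each = p)
  out
}

# %.17g round-trips IEEE doubles through text exactly
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

#' Read sensor-array measurements from CSV
#'
#' Long layout (canonical) has columns
#' `session,round,sample_id,class,sensor,value` plus optional `temperature`
#' and `seq_pos`. Wide layout has `session,round,sample_id,class` (plus
#' optional covariates) and one numeric column per sensor.
#'
#' @param path CSV file path (RFC 4180, UTF-8, header row mandatory).
#' @param layout `"long"` or `"wide"`.
#' @param sensors for wide layout, which columns are sensors; defaults to all
#'   non-metadata columns. For long layout, an optional expected channel set:
#'   any sensor in the file outside this set is a hard error.
#' @param on_missing what to do with observations that lack some sensor
#'   cells: `"error"` (default) or `"drop"` (dropped with a warning).
#' @return measurement_set
#' @export
read_measurements <- function(path, layout = c("long", "wide"),
                              sensors = NULL,
                              on_missing = c("error", "drop")) {
  layout <- match.arg(layout)
  on_missing <- match.arg(on_missing)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("session", "round", "sample_id", "class")
  covar_cols <- c("temperature", "seq_pos")
  if (layout == "long") {
    need <- c(meta_cols, "sensor", "value")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("long CSV is missing column(s): ", paste(miss, collapse = ", "))
    }
    if (!is.null(sensors)) {
      bad <- setdiff(unique(df$sensor), sensors)
      if (length(bad) > 0L) {
        stop("unknown sensor channel(s) in file: ", paste(bad, collapse = ", "))
      }
    }
    cellkey <- paste(df$session, df$round, df$sample_id, df$sensor, sep = "\r")
    if (anyDuplicated(cellkey)) {
      dup <- df[duplicated(cellkey), , drop = FALSE][1L, ]
      stop(sprintf(
        "duplicate cell for (session=%s, round=%s, sample_id=%s, sensor=%s)",
        dup$session, dup$round, dup$sample_id, dup$sensor
      ))
    }
    sens <- if (is.null(sensors)) unique(df$sensor) else
      intersect(sensors, unique(df$sensor))
    obskey <- paste(df$session, df$round, df$sample_id, sep = "\r")
    uobs <- !duplicated(obskey)
    meta <- df[uobs, intersect(c(meta_cols, covar_cols), names(df)),
               drop = FALSE]
    cls_per_obs <- tapply(df$class, obskey, function(z) length(unique(z)))
    if (any(cls_per_obs > 1L)) {
      stop("inconsistent class label within an observation")
    }
    vals <- matrix(NA_real_, nrow = nrow(meta), ncol = length(sens),
                   dimnames = list(NULL, sens))
    ridx <- match(obskey, obskey[uobs])
    cidx <- match(df$sensor, sens)
    vals[cbind(ridx, cidx)] <- df$value
  } else {
    miss <- setdiff(meta_cols, names(df))
    if (length(miss) > 0L) {
      stop("wide CSV is missing column(s): ", paste(miss, collapse = ", "))
    }
    cand <- setdiff(names(df), c(meta_cols, covar_cols))
    if (is.null(sensors)) {
      sens <- cand
    } else {
      bad <- setdiff(cand, sensors)
      if (length(bad) > 0L) {
        stop("unknown sensor column(s): ", paste(bad, collapse = ", "))
      }
      sens <- intersect(sensors, cand)
    }
    if (length(sens) == 0L) stop("no sensor columns found")
    meta <- df[, intersect(c(meta_cols, covar_cols), names(df)), drop = FALSE]
    vals <- as.matrix(df[, sens, drop = FALSE])
  }
  if (anyNA(vals)) {
    bad_rows <- which(rowSums(is.na(vals)) > 0L)
    if (on_missing == "error") {
      stop(sprintf("%d observation(s) have missing sensor cells", length(bad_rows)))
    }
    warning(sprintf("dropping %d observation(s) with missing sensor cells",
                    length(bad_rows)))
    meta <- meta[-bad_rows, , drop = FALSE]
    vals <- vals[-bad_rows, , drop = FALSE]
  }
  measurement_set(meta, vals, sensors = colnames(vals))
}

#' Write sensor-array measurements to CSV
#'
#' Numeric readings are serialized with 17 significant digits so that a
#' write/read cycle reproduces the doubles bit-exactly.
#'
#' @param ms measurement_set
#' @param path output CSV path
#' @param layout `"long"` (canonical) or `"wide"`
#' @return `path`, invisibly
#' @export
write_measurements <- function(ms, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    df <- as.data.frame(ms)
    df$value <- fmt_num(df$value)
  } else {
    covars <- intersect(c("temperature", "seq_pos"), names(ms$meta))
    df <- ms$meta[, c("session", "round", "sample_id", "class", covars),
                  drop = FALSE]
    for (j in seq_along(ms$sensors)) {
      df[[ms$sensors[j]]] <- fmt_num(ms$values[, j])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a measurement set to selected sessions
#' @param ms measurement_set
#' @param sessions integer vector of session indices to keep
#' @return measurement_set
#' @export
subset_sessions <- function(ms, sessions) {
  keep <- ms$meta$session %in% sessions
  if (!any(keep)) stop("no observations in the requested session(s)")
  measurement_set(ms$meta[keep, , drop = FALSE],
                  ms$values[keep, , drop = FALSE], ms$sensors)
}

#' Remove conditioning rounds at the start of every session
#'
#' The first few passes through the sample set are routinely unusable while
#' the sensors equilibrate; the default removes the first three rounds of
#' every session. Remaining round indices are re-based to start at 0.
#'
#' @param ms measurement_set
#' @param k number of initial rounds to drop per session (default 3)
#' @return measurement_set
#' @export
drop_initial_rounds <- function(ms, k = 3L) {
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0")
  if (k == 0L) return(ms)
  meta <- ms$meta
  keep <- rep(TRUE, nrow(meta))
  new_round <- meta$round
  for (s in unique(meta$session)) {
    in_s <- meta$session == s
    rounds <- sort(unique(meta$round[in_s]))
    if (length(rounds) <= k) {
      stop(sprintf("session %d has only %d round(s); cannot drop %d",
                   s, length(rounds), k))
    }
    dropped <- rounds[seq_len(k)]
    kept_rounds <- rounds[-seq_len(k)]
    keep[in_s & meta$round %in% dropped] <- FALSE
    new_round[in_s] <- match(meta$round[in_s], kept_rounds) - 1L
  }
  meta$round <- new_round
  measurement_set(meta[keep, , drop = FALSE],
                  ms$values[keep, , drop = FALSE], ms$sensors)
}

#' Flag outlying observations by robust distance to the class centroid
#'
#' Within each (session, class) group, the Euclidean distance of every
#' observation to the group centroid in sensor space is scored with a robust
#' z (0.6745 * (d - median) / MAD). Observations with z above `z_thresh` are
#' flagged. Purely advisory: nothing is removed — component correction in
#' particular is sensitive to outliers, so removal is left as an explicit,
#' manual step.
#'
#' @param ms measurement_set
#' @param z_thresh robust z threshold (default 3.5)
#' @param min_n minimum group size required (default 5)
#' @return data.frame with columns `session, round, sample_id, class,
#'   distance, robust_z`, one row per flagged observation (possibly empty).
#' @export
flag_outliers <- function(ms, z_thresh = 3.5, min_n = 5L) {
  meta <- ms$meta
  out <- list()
  for (s in sort(unique(meta$session))) {
    for (cl in sort(unique(meta$class[meta$session == s]))) {
      idx <- which(meta$session == s & meta$class == cl)
      if (length(idx) < min_n) {
        stop(sprintf(
          "group (session=%d, class=%s) has %d observation(s); need >= %d",
          s, cl, length(idx), min_n
        ))
      }
      x <- ms$values[idx, , drop = FALSE]
      ctr <- colMeans(x)
      d <- sqrt(rowSums(sweep(x, 2L, ctr)^2))
      med <- stats::median(d)
      madv <- stats::median(abs(d - med))
      if (madv == 0) {
        warning(sprintf(
          "degenerate group (session=%d, class=%s): MAD of centroid distances is 0; nothing flagged",
          s, cl
        ))
        next
      }
      z <- 0.6745 * (d - med) / madv
      hit <- which(z > z_thresh)
      if (length(hit) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          session = meta$session[idx[hit]],
          round = meta$round[idx[hit]],
          sample_id = meta$sample_id[idx[hit]],
          class = meta$class[idx[hit]],
          distance = d[hit],
          robust_z = z[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      session = integer(0), round = integer(0),
      sample_id = character(0), class = character(0),
      distance = numeric(0), robust_z = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}
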