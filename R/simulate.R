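#' Default sensor channel names
#' @return character vector of the seven channel names
#' @export
default_sensors <- function() c("ZZ", "BA", "BB", "CA", "GA", "HA", "JB")

#' Default class fingerprints
#'
#' Fixed per-class mean response vectors ("fingerprints") for the four
#' default classes over the seven default channels, in raw potential units.
#' They sit on a shared base level of roughly 800-1500 units with
#' class-specific offsets chosen so that, at the default noise level of 1
#' unit, pairwise class separations range from ~20 (citric-acid vs
#' apple-juice analogs, deliberately the closest pair) to ~50 units.
#'
#' @param sensors channel names (length 7 by default)
#' @param classes class labels
#' @return numeric matrix, one row per class, one column per sensor
#' @export
default_fingerprints <- function(sensors = default_sensors(),
                                 classes = default_classes()) {
  base <- c(1520, 1180, 845, 1060, 930, 1100, 1310)
  offsets <- rbind(
    citric_acid = c(-20, 15, -10, 8, -12, 6, -15),
    NaCl        = c(18, -14, 12, -6, 10, -8, 14),
    MSG         = c(10, 12, -14, -10, 8, 14, -6),
    apple_juice = c(-12, 5, -2, 12, -4, -2, -8)
  )
  if (length(sensors) != 7L || !all(classes %in% rownames(offsets))) {
    stop("default fingerprints are defined for the 7 default sensors and 4 default classes")
  }
  fp <- sweep(offsets[classes, , drop = FALSE], 2L, base, `+`)
  dimnames(fp) <- list(classes, sensors)
  fp
}

#' Default class labels
#' @return character vector: the three basic-taste model solutions plus the
#'   apple-juice analog
#' @export
default_classes <- function() c("citric_acid", "NaCl", "MSG", "apple_juice")

#' Build a simulation configuration
#'
#' The generative model for one observation of class `c` in session `w`,
#' round `r` is, in measurement order,
#' `x = g_w * mu_c + d_w + beta * (T - temp_ref) + eps`, `eps ~ N(0, sd^2)`,
#' followed by optional cross-contamination dilution toward the cleaning
#' water level and first-order memory carryover
#' `obs_i = (1 - lambda) * x_i + lambda * obs_{i-1}` along the physical
#' measurement sequence of the session. The additive session drift `d_w` is
#' a random walk over sessions starting at 0; the gain `g_w = 1 +
#' gain_step * w` drifts multiplicatively.
#'
#' @param sensors channel names (default: the seven standard channels)
#' @param classes class labels
#' @param fingerprints class-by-sensor matrix of mean responses (units)
#' @param sessions number of sessions (weeks), default 6
#' @param rounds rounds (complete sample-set passes) per session, default 18
#' @param noise_sd measurement noise standard deviation per sensor (units),
#'   default 1
#' @param drift_step expected Euclidean norm of the per-session additive
#'   drift increment (units); the walk starts at 0 in session 0. Default 5.
#' @param gain_step relative multiplicative drift per session (default 0.01)
#' @param beta per-sensor temperature sensitivity (units per deg C); default
#'   norm 50
#' @param temp_ref reference temperature (deg C) at which no temperature
#'   term applies, default 25
#' @param class_temperature named vector of per-class sample temperatures;
#'   default: all at `temp_ref`
#' @param session_temp_offset per-session temperature offset (deg C),
#'   default 0 (length `sessions`)
#' @param carryover memory carryover fraction lambda in \[0, 1)
#' @param dilution_rate per-round cross-contamination dilution fraction in
#'   \[0, 1), applied in `contaminated_sessions`
#' @param contaminated_sessions sessions whose cleaning fluids are not
#'   replaced (dilution and pH track active)
#' @param water_level per-sensor reading of the cleaning water toward which
#'   contaminated readings are pulled; default: the shared fingerprint base
#'   (column means of `fingerprints`)
#' @param ph0 initial sample pH (default 3.8, an apple-juice-like value)
#' @param ph_increment pH increase per dip/round under contamination
#'   (default 0.1)
#' @param class_order measurement order of the classes within a round:
#'   a character vector, or a list of one such vector per session; default:
#'   `classes` order
#' @param seed RNG seed (same config + seed gives identical output)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(sensors = default_sensors(),
                              classes = default_classes(),
                              fingerprints = default_fingerprints(sensors, classes),
                              sessions = 6L, rounds = 18L,
                              noise_sd = 1, drift_step = 5, gain_step = 0.01,
                              beta = rep(50 / sqrt(length(sensors)),
                                         length(sensors)),
                              temp_ref = 25,
                              class_temperature = NULL,
                              session_temp_offset = rep(0, sessions),
                              carryover = 0, dilution_rate = 0,
                              contaminated_sessions = integer(0),
                              water_level = NULL,
                              ph0 = 3.8, ph_increment = 0.1,
                              class_order = NULL, seed = 1L) {
  fingerprints <- as.matrix(fingerprints)
  if (is.null(class_temperature)) {
    class_temperature <- stats::setNames(rep(temp_ref, length(classes)),
                                         classes)
  }
  if (is.null(water_level)) water_level <- colMeans(fingerprints)
  if (is.null(class_order)) class_order <- classes
  if (!is.list(class_order)) {
    class_order <- rep(list(as.character(class_order)), sessions)
  }
  cfg <- structure(
    list(sensors = as.character(sensors), classes = as.character(classes),
         fingerprints = fingerprints, sessions = as.integer(sessions),
         rounds = as.integer(rounds), noise_sd = noise_sd,
         drift_step = drift_step, gain_step = gain_step, beta = beta,
         temp_ref = temp_ref, class_temperature = class_temperature,
         session_temp_offset = session_temp_offset, carryover = carryover,
         dilution_rate = dilution_rate,
         contaminated_sessions = as.integer(contaminated_sessions),
         water_level = water_level, ph0 = ph0, ph_increment = ph_increment,
         class_order = class_order, seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (sessions < 1L || rounds < 1L) stop("sessions and rounds must be >= 1")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (carryover < 0 || carryover >= 1) stop("carryover must be in [0, 1)")
    if (dilution_rate < 0 || dilution_rate >= 1) {
      stop("dilution_rate must be in [0, 1)")
    }
    if (drift_step < 0 || gain_step < -1) stop("invalid drift parameters")
    if (nrow(fingerprints) != length(classes) ||
        ncol(fingerprints) != length(sensors)) {
      stop("fingerprints must be a classes x sensors matrix")
    }
    if (length(beta) != length(sensors)) {
      stop("beta must have one entry per sensor")
    }
    if (length(water_level) != length(sensors)) {
      stop("water_level must have one entry per sensor")
    }
    if (length(session_temp_offset) != sessions) {
      stop("session_temp_offset must have one entry per session")
    }
    if (!all(classes %in% names(class_temperature))) {
      stop("class_temperature must cover every class")
    }
    if (length(class_order) != sessions ||
        !all(vapply(class_order, function(o) setequal(o, classes) &&
                      length(o) == length(classes), logical(1)))) {
      stop("class_order must list every class exactly once per session")
    }
    if (any(contaminated_sessions < 0 | contaminated_sessions >= sessions)) {
      stop("contaminated_sessions out of range")
    }
    invisible(NULL)
  })
  invisible(cfg)
}

#' Simulate a multi-session sensor-array experiment
#'
#' Draws one experiment from the generative model of [simulation_config()].
#' The returned object carries the observed measurements, the drift-free
#' ground truth (fingerprint plus the same noise draws, with no drift, gain,
#' temperature, contamination or carryover terms), the pre-carryover signal,
#' the pH track of the cleaning-contamination process, and the realized
#' parameters, so that every disturbance is exactly reconstructible.
#'
#' @param config simulation_config
#' @return object of class `simulated_experiment` with elements
#'   `measurements`, `truth` (both measurement_set), `signal` (pre-carryover
#'   matrix), `ph` (data.frame session, round, ph) and `params`
#' @export
simulate_experiment <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  p <- length(config$sensors)
  S <- config$sessions
  R <- config$rounds
  K <- length(config$classes)
  drift <- matrix(0, S, p, dimnames = list(NULL, config$sensors))
  if (S > 1L) {
    for (w in 2:S) {
      drift[w, ] <- drift[w - 1L, ] +
        stats::rnorm(p, 0, config$drift_step / sqrt(p))
    }
  }
  gain <- 1 + config$gain_step * (0:(S - 1L))

  n <- S * R * K
  meta <- data.frame(
    session = integer(n), round = integer(n),
    sample_id = character(n), class = character(n),
    temperature = numeric(n), seq_pos = integer(n),
    stringsAsFactors = FALSE
  )
  truth <- matrix(NA_real_, n, p, dimnames = list(NULL, config$sensors))
  signal <- truth
  observed <- truth
  ph <- data.frame(session = integer(S * R), round = integer(S * R),
                   ph = numeric(S * R))
  i <- 0L
  bi <- 0L
  for (w in seq_len(S) - 1L) {
    order_w <- config$class_order[[w + 1L]]
    contaminated <- w %in% config$contaminated_sessions
    pos <- 0L
    prev <- NULL
    for (r in seq_len(R) - 1L) {
      bi <- bi + 1L
      ph$session[bi] <- w
      ph$round[bi] <- r
      ph$ph[bi] <- config$ph0 +
        if (contaminated) config$ph_increment * r else 0
      for (cl in order_w) {
        i <- i + 1L
        pos <- pos + 1L
        mu <- config$fingerprints[cl, ]
        temp <- config$class_temperature[[cl]] +
          config$session_temp_offset[w + 1L]
        eps <- stats::rnorm(p, 0, config$noise_sd)
        x <- gain[w + 1L] * mu + drift[w + 1L, ] +
          config$beta * (temp - config$temp_ref) + eps
        if (contaminated && config$dilution_rate > 0) {
          shrink <- (1 - config$dilution_rate)^r
          x <- config$water_level + (x - config$water_level) * shrink
        }
        obs <- if (is.null(prev)) x else
          (1 - config$carryover) * x + config$carryover * prev
        prev <- obs
        meta$session[i] <- w
        meta$round[i] <- r
        meta$sample_id[i] <- cl
        meta$class[i] <- cl
        meta$temperature[i] <- temp
        meta$seq_pos[i] <- pos
        truth[i, ] <- mu + eps
        signal[i, ] <- x
        observed[i, ] <- obs
      }
    }
  }
  structure(
    list(
      measurements = measurement_set(meta, observed, config$sensors),
      truth = measurement_set(meta, truth, config$sensors),
      signal = signal,
      ph = ph,
      params = list(drift = drift, gain = gain, beta = config$beta,
                    carryover = config$carryover, config = config)
    ),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cfg <- x$params$config
  cat(sprintf(
    "simulated_experiment: %d sessions x %d rounds x %d classes (seed %d)\n",
    cfg$sessions, cfg$rounds, length(cfg$classes), cfg$seed))
  invisible(x)
}

#' Named simulation scenarios
#'
#' Fully parameterized configurations reproducing the structure of the
#' standard disturbance experiments:
#'
#' * `baseline_drift` — six weekly sessions of the four default classes, 18
#'   usable rounds per session, additive random-walk session drift (expected
#'   step norm 5 units at noise 1), 1% per-session gain drift and mild
#'   carryover (lambda = 0.05); constant 25 deg C.
#' * `temperature_sweep` — apple-juice dilutions at 4 temperature levels (5,
#'   15, 25, 35 deg C) x 5 concentrations (80-100% in 5% steps), three
#'   replicate rounds, one session, no drift. Concentration shifts the
#'   fingerprint by 7 units per %.
#' * `memory_orders` — three sessions realizing the three class orderings
#'   (a) citric acid, NaCl, MSG, apple juice; (b) citric acid, apple juice,
#'   MSG, NaCl; (c) citric acid, NaCl, apple juice, MSG; strong carryover
#'   (lambda = 0.3), nine rounds, no drift.
#' * `contamination` — one session of apple juice only, nine rounds, per-round
#'   dilution 1% toward the cleaning-water level, pH track advancing 0.1 per
#'   round.
#' * `week5_shift` — `baseline_drift` plus unreplaced cleaning fluids in
#'   sessions 4-5 (dilution 0.5%/round) and an uncontrolled -2 deg C
#'   temperature offset in session 5.
#'
#' @param name scenario name
#' @param ... overrides passed on to [simulation_config()] (e.g. `seed`,
#'   `drift_step`)
#' @return simulation_config
#' @export
scenario <- function(name, ...) {
  known <- c("baseline_drift", "temperature_sweep", "memory_orders",
             "contamination", "week5_shift")
  if (length(name) != 1L || !name %in% known) {
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  }
  dots <- list(...)
  args <- switch(name,
    baseline_drift = list(carryover = 0.05),
    week5_shift = list(
      carryover = 0.05,
      contaminated_sessions = c(4L, 5L), dilution_rate = 0.005,
      session_temp_offset = c(0, 0, 0, 0, 0, -2)
    ),
    memory_orders = list(
      sessions = 3L, rounds = 9L, drift_step = 0, gain_step = 0,
      carryover = 0.3,
      class_order = list(
        c("citric_acid", "NaCl", "MSG", "apple_juice"),
        c("citric_acid", "apple_juice", "MSG", "NaCl"),
        c("citric_acid", "NaCl", "apple_juice", "MSG")
      ),
      session_temp_offset = rep(0, 3)
    ),
    contamination = {
      fp <- default_fingerprints()["apple_juice", , drop = FALSE]
      list(classes = "apple_juice", fingerprints = fp,
           sessions = 1L, rounds = 9L, drift_step = 0, gain_step = 0,
           dilution_rate = 0.01, contaminated_sessions = 0L,
           water_level = c(1520, 1180, 845, 1060, 930, 1100, 1310),
           session_temp_offset = 0)
    },
    temperature_sweep = {
      temps <- c(5, 15, 25, 35)
      concs <- c(80, 85, 90, 95, 100)
      combos <- expand.grid(conc = concs, temp = temps)
      labels <- sprintf("aj%d_t%d", combos$conc, combos$temp)
      aj <- default_fingerprints()["apple_juice", ]
      gamma_dir <- c(2, -1, 1, 2, -1, -1, 1)
      gamma <- 7 * gamma_dir / sqrt(sum(gamma_dir^2)) # 7 units per conc %
      fp <- t(vapply(seq_len(nrow(combos)),
                     function(i) aj + (combos$conc[i] - 90) * gamma,
                     numeric(7)))
      dimnames(fp) <- list(labels, default_sensors())
      list(classes = labels, fingerprints = fp,
           sessions = 1L, rounds = 3L, drift_step = 0, gain_step = 0,
           class_temperature = stats::setNames(combos$temp, labels),
           session_temp_offset = 0)
    }
  )
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

#' Recover generative parameters from a simulated experiment
#'
#' A test harness for the generator: estimates the additive session drift
#' from per-session mean shifts of observed minus drift-free truth, the
#' temperature-sensitivity norm from the slope of sensor-space centroid
#' distance versus temperature difference, and the memory carryover from a
#' through-origin lag-1 regression of the carryover residual
#' `obs_i - x_i` on `obs_{i-1} - x_i` (exact under the generative recursion).
#'
#' @param exp simulated_experiment
#' @return list with `drift` (session x sensor matrix of estimated offsets),
#'   `beta_norm` (estimated units/deg C; `NA` when the experiment has no
#'   temperature variation) and `carryover` (estimated lambda)
#' @export
recover_parameters <- function(exp) {
  stopifnot(inherits(exp, "simulated_experiment"))
  meta <- exp$measurements$meta
  obs <- exp$measurements$values
  tru <- exp$truth$values
  sessions <- sort(unique(meta$session))
  d_hat <- t(vapply(sessions, function(s) {
    rows <- meta$session == s
    colMeans(obs[rows, , drop = FALSE] - tru[rows, , drop = FALSE])
  }, numeric(ncol(obs))))
  dimnames(d_hat) <- list(sessions, exp$measurements$sensors)

  temps <- meta$temperature
  beta_norm <- NA_real_
  if (length(unique(temps)) >= 3L) {
    tref <- min(temps)
    dist <- centroid_distances_sensor_space(exp$measurements, temps, tref)
    dt <- as.numeric(names(dist)) - tref
    beta_norm <- fit_trend(dt, dist)$slope
  }

  num <- 0
  den <- 0
  for (s in sessions) {
    rows <- which(meta$session == s)
    rows <- rows[order(meta$seq_pos[rows])]
    if (length(rows) < 2L) {
      stop("insufficient observations per session for lag-1 regression")
    }
    u <- obs[rows[-1L], , drop = FALSE] - exp$signal[rows[-1L], , drop = FALSE]
    v <- obs[rows[-length(rows)], , drop = FALSE] -
      exp$signal[rows[-1L], , drop = FALSE]
    num <- num + sum(u * v)
    den <- den + sum(v * v)
  }
  lambda_hat <- if (den == 0) 0 else num / den
  list(drift = d_hat, beta_norm = beta_norm, carryover = lambda_hat)
}

#' Write a simulated experiment to CSV files
#'
#' The observed measurements go to `<stem>.csv`, the drift-free ground truth
#' to `<stem>_truth.csv`, and the configuration echo to `<stem>_config.json`.
#'
#' @param exp simulated_experiment
#' @param stem output path stem (no extension)
#' @param layout CSV layout, `"long"` or `"wide"`
#' @return character vector of the three paths written, invisibly
#' @export
write_experiment <- function(exp, stem, layout = "long") {
  paths <- c(
    measurements = paste0(stem, ".csv"),
    truth = paste0(stem, "_truth.csv"),
    config = paste0(stem, "_config.json")
  )
  write_measurements(exp$measurements, paths[["measurements"]], layout)
  write_measurements(exp$truth, paths[["truth"]], layout)
  cfg <- exp$params$config
  doc <- cfg
  doc$fingerprints <- unname(apply(cfg$fingerprints, 1L, as.list))
  doc$fingerprint_classes <- rownames(cfg$fingerprints)
  class(doc) <- NULL
  jsonlite::write_json(doc, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
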