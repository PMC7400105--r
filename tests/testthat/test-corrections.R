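make_block_ms <- function(values_by_class, sensors = paste0("s", seq_len(ncol(values_by_class[[1]])))) {
  # values_by_class: named list class -> matrix (rounds x sensors), 1 session
  rows <- list()
  for (cl in names(values_by_class)) {
    m <- values_by_class[[cl]]
    rows[[cl]] <- data.frame(session = 0L, round = seq_len(nrow(m)) - 1L,
                             sample_id = cl, class = cl)
  }
  meta <- do.call(rbind, rows)
  vals <- do.call(rbind, lapply(values_by_class, identity))
  measurement_set(meta, vals, sensors)
}

test_that("additive fitters compute per-block basis means", {
  ms <- make_block_ms(list(A = matrix(3, 1, 1), B = matrix(5, 1, 1)),
                      sensors = "s1")
  fit <- fit_additive_all(ms)
  expect_equal(unname(fit$offsets[1, 1]), 4)

  # already zero-mean block -> zero offsets
  ms0 <- make_block_ms(list(A = matrix(c(-1, 2), 1), B = matrix(c(1, -2), 1)),
                       sensors = c("s1", "s2"))
  expect_equal(unname(fit_additive_all(ms0)$offsets), matrix(0, 1, 2))

  # reference variant ignores non-references
  msr <- make_block_ms(list(A = matrix(1, 1, 1), B = matrix(3, 1, 1),
                            C = matrix(10, 1, 1)), sensors = "s1")
  fr <- fit_additive_reference(msr, c("A", "B"))
  expect_equal(unname(fr$offsets[1, 1]), 2)
  # with all classes as references it reduces to the all-samples fit
  expect_equal(fit_additive_reference(msr, c("A", "B", "C"))$offsets,
               fit_additive_all(msr)$offsets)

  # brute-force oracle on a random 4-class x 7-sensor experiment
  ms4 <- rand_ms(seed = 5, sessions = 2, rounds = 3,
                 classes = c("A", "B", "C", "D"),
                 sensors = paste0("s", 1:7))
  fit4 <- fit_additive_all(ms4)
  fitr <- fit_additive_reference(ms4, c("A", "C", "D"))
  for (i in seq_len(nrow(fit4$blocks))) {
    rows <- ms4$meta$session == fit4$blocks$session[i] &
      ms4$meta$round == fit4$blocks$round[i]
    for (j in 1:7) {
      expect_equal(unname(fit4$offsets[i, j]), mean(ms4$values[rows, j]))
      rrows <- rows & ms4$meta$class %in% c("A", "C", "D")
      expect_equal(unname(fitr$offsets[i, j]), mean(ms4$values[rrows, j]))
    }
  }
})

test_that("additive fit preconditions hold", {
  ms <- rand_ms(seed = 6, sessions = 1, rounds = 2)
  drop <- !(ms$meta$round == 1 & ms$meta$class == "B")
  broken <- measurement_set(ms$meta[drop, ], ms$values[drop, ], ms$sensors)
  expect_error(fit_additive_all(broken), "round=1.*incomplete.*B")
  expect_error(fit_additive_reference(broken, "B"), "lacks reference.*B")
  expect_error(fit_additive_reference(ms, "nope"), "absent")
})

test_that("apply_additive zero-centers, is idempotent, absorbs block shifts", {
  ms <- rand_ms(seed = 7, sessions = 3, rounds = 4,
                classes = c("A", "B", "C", "D"), sensors = paste0("s", 1:7))
  corr <- apply_additive(ms, fit_additive_all(ms))
  for (i in unique(paste(corr$meta$session, corr$meta$round))) {
    rows <- paste(corr$meta$session, corr$meta$round) == i
    expect_lt(max(abs(colMeans(corr$values[rows, ]))), 1e-10)
  }
  twice <- apply_additive(corr, fit_additive_all(corr))
  expect_equal(twice$values, corr$values, tolerance = 1e-12)

  shifted <- ms
  block <- shifted$meta$session == 1 & shifted$meta$round == 2
  shifted$values[block, ] <- shifted$values[block, ] + 17
  corr2 <- apply_additive(shifted, fit_additive_all(shifted))
  expect_equal(corr2$values, corr$values, tolerance = 1e-10)

  other <- rand_ms(seed = 8, sessions = 4, rounds = 4,
                   classes = c("A", "B", "C", "D"), sensors = paste0("s", 1:7))
  expect_error(apply_additive(other, fit_additive_all(ms)),
               "not covered")
})

test_that("linear map fit matches closed-form least squares", {
  # identical references -> identity map
  mu <- matrix(c(1, 5, 9, 2, 4, 8), 3, 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  mk <- function(shift = 0, scale = 1) {
    meta <- expand.grid(class = rownames(mu), round = 0:1, session = 0:1,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample_id <- meta$class
    vals <- mu[meta$class, ]
    later <- meta$session == 1
    vals[later, ] <- vals[later, ] * scale + shift
    measurement_set(meta, vals, colnames(mu))
  }
  fid <- fit_linear_map(mk(), c("A", "B", "C"))
  expect_equal(unname(fid$m), matrix(1, 2, 2))
  expect_equal(unname(fid$b), matrix(0, 2, 2))

  # pure offset drift of -10: y = x + 10
  foff <- fit_linear_map(mk(shift = -10), c("A", "B", "C"))
  expect_equal(unname(foff$m[2, ]), c(1, 1))
  expect_equal(unname(foff$b[2, ]), c(10, 10))

  # exact line y = 2x + 1: later centroids at (y - 1)/2
  mexact <- mk()
  later <- mexact$meta$session == 1
  mexact$values[later, ] <- (mexact$values[later, ] - 1) / 2
  fex <- fit_linear_map(mexact, c("A", "B", "C"))
  expect_equal(unname(fex$m[2, ]), c(2, 2), tolerance = 1e-12)
  expect_equal(unname(fex$b[2, ]), c(1, 1), tolerance = 1e-12)

  # noisy centroids against the normal-equations oracle
  ms <- rand_ms(seed = 9, sessions = 2, rounds = 6,
                classes = c("A", "B", "C", "D"), sensors = paste0("s", 1:3),
                drift = 2)
  fit <- fit_linear_map(ms, c("A", "B", "C"))
  for (j in 1:3) {
    x <- vapply(c("A", "B", "C"), function(cl) {
      mean(ms$values[ms$meta$session == 1 & ms$meta$class == cl, j])
    }, numeric(1))
    y <- vapply(c("A", "B", "C"), function(cl) {
      mean(ms$values[ms$meta$session == 0 & ms$meta$class == cl, j])
    }, numeric(1))
    o <- oracle_ols(x, y)
    expect_equal(fit$m[2, j], o$slope, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fit$b[2, j], o$intercept, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  expect_error(fit_linear_map(ms, "A"), "at least two reference classes")
  # constant sensor across reference centroids -> error naming the sensor
  flat <- mk()
  flat$values[flat$meta$session == 1, 2] <- 7
  expect_error(fit_linear_map(flat, c("A", "B", "C")), "s2.*zero variance|zero variance.*s2")
})

test_that("linear map application inverts affine drift exactly", {
  ms <- rand_ms(seed = 10, sessions = 1, rounds = 5,
                classes = c("A", "B", "C", "D"), sensors = paste0("s", 1:7))
  # replicate session 0 into sessions 1..3 under per-session affine drift
  m0 <- c(1.2, 0.8, 1.5, 0.9, 1.1, 0.7, 1.3)
  metas <- list(ms$meta)
  valss <- list(ms$values)
  for (w in 1:3) {
    mw <- ms$meta
    mw$session <- w
    metas[[w + 1]] <- mw
    valss[[w + 1]] <- sweep(sweep(ms$values, 2, w * 10, `+`), 2, m0^w, `*`)
  }
  big <- measurement_set(do.call(rbind, metas), do.call(rbind, valss),
                         ms$sensors)
  fit <- fit_linear_map(big, c("A", "B", "C"))
  corrected <- apply_linear_map(big, fit)
  for (w in 0:3) {
    expect_lt(max(abs(corrected$values[corrected$meta$session == w, ] -
                        ms$values)), 1e-9)
  }

  # identity map leaves data untouched; random map matches hand loop
  expect_equal(apply_linear_map(ms, fit_linear_map(
    measurement_set(rbind(ms$meta, transform(ms$meta, session = 1L)),
                    rbind(ms$values, ms$values), ms$sensors),
    c("A", "B")
  ))$values[seq_len(n_obs(ms)), ], ms$values)

  set.seed(13)
  model <- fit
  model$m[2, ] <- runif(7, 0.5, 2)
  model$b[2, ] <- rnorm(7, 0, 5)
  out <- apply_linear_map(big, model)
  rows <- which(big$meta$session == 1)
  for (i in rows[1:5]) {
    for (j in 1:7) {
      expect_equal(out$values[i, j],
                   model$m[2, j] * big$values[i, j] + model$b[2, j])
    }
  }
  expect_error(apply_linear_map(
    measurement_set(transform(ms$meta, session = 9L), ms$values, ms$sensors),
    fit), "session 9")
})

two_cluster_ms <- function(seed, shift, n = 12, noise = 0.1, p = 2) {
  set.seed(seed)
  sensors <- paste0("s", seq_len(p))
  meta <- data.frame(session = rep(c(0L, 1L), each = n),
                     round = rep(seq_len(n) - 1L, 2),
                     sample_id = "ref", class = "ref")
  vals <- matrix(rnorm(2 * n * p, sd = noise), ncol = p)
  vals[meta$session == 1, ] <- sweep(vals[meta$session == 1, , drop = FALSE],
                                     2, shift, `+`)
  measurement_set(meta, vals, sensors)
}

test_that("drift component estimation finds the drift direction", {
  # displacement along the first sensor axis only
  ms <- two_cluster_ms(14, shift = c(8, 0), noise = 0.05)
  fit <- fit_drift_component(ms, "ref", pairing = "first_last")
  p <- fit$components[[1]]$loading
  expect_gt(abs(p[1]), 0.999)
  expect_equal(fit$components[[1]]$center, colMeans(ms$values),
               ignore_attr = TRUE)
  # sign fixed by base -> later displacement
  expect_gt(p[1], 0)

  # eigen-decomposition oracle on the (4,4) toy
  ms2 <- two_cluster_ms(15, shift = c(4, 4), noise = 0.2)
  fit2 <- fit_drift_component(ms2, "ref", pairing = "first_last")
  p2 <- fit2$components[[1]]$loading
  expect_equal(abs(p2), rep(1 / sqrt(2), 2), tolerance = 0.05)
  centered <- sweep(ms2$values, 2, colMeans(ms2$values))
  ev <- eigen((t(centered) %*% centered) / (nrow(centered) - 1))$vectors[, 1]
  expect_equal(abs(p2), abs(ev), tolerance = 1e-8)

  # rank-0 pooled reference set
  ms0 <- two_cluster_ms(16, shift = c(0, 0), noise = 0.1)
  ms0$values[] <- 1
  expect_error(fit_drift_component(ms0, "ref", pairing = "first_last"),
               "zero variance")
  expect_error(fit_drift_component(ms, "nope", pairing = "first_last"),
               "not observed")
})

test_that("component correction removes / reflects the drift projection", {
  ms <- two_cluster_ms(17, shift = c(5, 3), noise = 0.2)
  fit <- fit_drift_component(ms, "ref", pairing = "first_last", multiplier = 1)
  corr <- apply_component_correction(ms, fit)
  p <- fit$components[[1]]$loading
  proj <- sweep(corr$values, 2, colMeans(corr$values)) %*% p
  expect_lt(stats::var(drop(proj)) / sum(diag(stats::cov(ms$values))), 1e-10)

  # modified CC under NOISELESS pure translation: the pooled reference pool
  # varies only along the drift direction, so the fitted loading is exact and
  # the later centroid is mapped onto the base one; base rows bit-identical
  delta <- 6
  msT <- two_cluster_ms(18, shift = c(0, 0), noise = 0.3)
  pdir <- c(3, 4) / 5
  later <- msT$meta$session == 1
  msT$values[!later, ] <- matrix(c(1, 2), sum(!later), 2, byrow = TRUE)
  msT$values[later, ] <- msT$values[!later, , drop = FALSE] +
    matrix(delta * pdir, sum(later), 2, byrow = TRUE)
  fitM <- fit_drift_component(msT, "ref", pairing = "each_week_to_week0",
                              multiplier = 2)
  corrM <- apply_component_correction(msT, fitM)
  expect_identical(corrM$values[!later, ], msT$values[!later, ])
  expect_lt(max(abs(colMeans(corrM$values[later, ]) -
                      colMeans(msT$values[!later, ]))), 1e-10)

  # sign flip of the loading leaves the correction bit-identical
  flipped <- fit
  flipped$components[[1]]$loading <- -flipped$components[[1]]$loading
  expect_identical(apply_component_correction(ms, flipped)$values,
                   corr$values)
})

test_that("correct() dispatch equals direct fit/apply pairs", {
  exp <- simulate_experiment(scenario("baseline_drift", seed = 1, rounds = 5))
  ms <- exp$measurements
  refs <- c("citric_acid", "NaCl", "MSG")

  expect_identical(correct(ms, "none")$corrected$values, ms$values)

  direct <- apply_additive(ms, fit_additive_all(ms))
  expect_equal(correct(ms, "additive_all")$corrected$values, direct$values)

  direct <- apply_additive(ms, fit_additive_reference(ms, refs))
  expect_equal(correct(ms, "additive_ref",
                       reference_classes = refs)$corrected$values,
               direct$values)

  direct <- apply_linear_map(ms, fit_linear_map(ms, refs))
  expect_equal(correct(ms, "linear_ref",
                       reference_classes = refs)$corrected$values,
               direct$values)

  direct <- apply_component_correction(
    ms, fit_drift_component(ms, "citric_acid", "first_last", multiplier = 1))
  expect_equal(correct(ms, "cc",
                       reference_class = "citric_acid")$corrected$values,
               direct$values)

  direct <- apply_component_correction(
    ms, fit_drift_component(ms, "citric_acid", "each_week_to_week0",
                            multiplier = 2))
  expect_equal(correct(ms, "cc_modified",
                       reference_class = "citric_acid")$corrected$values,
               direct$values)

  expect_error(correct(ms, "linear_ref"), "requires")
  expect_error(correct(ms, "cc"), "requires")

  # single-session additive_all yields zero-centered blocks
  one <- subset_sessions(ms, 0)
  z <- correct(one, "additive_all")$corrected
  for (r in unique(z$meta$round)) {
    expect_lt(max(abs(colMeans(z$values[z$meta$round == r, ]))), 1e-10)
  }
})

test_that("corrections are permutation-equivariant and shift-(in)variant", {
  exp <- simulate_experiment(scenario("baseline_drift", seed = 4, rounds = 4))
  ms <- exp$measurements
  refs <- c("citric_acid", "NaCl", "MSG")
  run <- function(m, method) {
    correct(m, method, reference_classes = refs,
            reference_class = "citric_acid")$corrected
  }
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  msp <- measurement_set(ms$meta, ms$values[, perm], ms$sensors[perm])
  shifted <- measurement_set(ms$meta, ms$values + 17, ms$sensors)
  for (method in c("additive_all", "additive_ref", "linear_ref",
                   "cc", "cc_modified")) {
    base <- run(ms, method)
    expect_equal(run(msp, method)$values, base$values[, perm],
                 tolerance = 1e-8, ignore_attr = TRUE)
    got <- run(shifted, method)$values
    if (startsWith(method, "additive")) {
      expect_equal(got, base$values, tolerance = 1e-8)  # shift removed
    } else {
      expect_equal(got, base$values + 17, tolerance = 1e-8)  # shift carried
    }
  }
})

test_that("fitted models serialize to JSON", {
  exp <- simulate_experiment(scenario("baseline_drift", seed = 2, rounds = 4))
  ms <- exp$measurements
  refs <- c("citric_acid", "NaCl", "MSG")
  cases <- list(
    none = correct(ms, "none")$model,
    additive_all = correct(ms, "additive_all")$model,
    linear_ref = correct(ms, "linear_ref", reference_classes = refs)$model,
    cc_modified = correct(ms, "cc_modified",
                          reference_class = "citric_acid")$model
  )
  for (nm in names(cases)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_correction_model(cases[[nm]], path)
    doc <- jsonlite::read_json(path)
    expect_identical(doc$method, nm)
    expect_true(!is.null(doc$software_version))
  }
})
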