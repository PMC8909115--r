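## Feature columns of the surrogate, in canonical order. Units: particle_size
## in micron; pipe_diameter and pipe_length in m; velocities in m/s.
SURROGATE_FEATURES <- c("particle_size", "particle_density", "pipe_diameter",
                        "pipe_length", "air_velocity",
                        "particle_vertical_velocity")

#' Studied input ranges of the collision-number surrogate
#'
#' The six inputs and the envelope over which the collision database is
#' sampled: particle size 10-600 micron, particle density 1410-7850 kg/m^3,
#' pipe diameter 0.002-0.006 m, pipe length 0.25-1.5 m, air velocity
#' 6.5-36 m/s, particle vertical (injection) velocity 0-1.2 m/s.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
table1_ranges <- function() {
  list(particle_size = c(10, 600),
       particle_density = c(1410, 7850),
       pipe_diameter = c(0.002, 0.006),
       pipe_length = c(0.25, 1.5),
       air_velocity = c(6.5, 36),
       particle_vertical_velocity = c(0, 1.2))
}

#' Sampling plan for the surrogate database
#'
#' Draws feature combinations over the studied ranges, by Latin-hypercube
#' sampling (default; space-filling with few points) or a full factorial
#' grid with `ceiling(n^(1/6))` levels per dimension truncated to `n` points.
#'
#' @param n Number of design points, default 197.
#' @param ranges Named ranges as from [table1_ranges()].
#' @param method `"lhs"` or `"grid"`.
#' @param seed Integer seed for the Latin hypercube.
#' @return A data frame with the six feature columns.
#' @export
sampling_plan <- function(n = 197, ranges = table1_ranges(),
                          method = c("lhs", "grid"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(identical(sort(names(ranges)), sort(SURROGATE_FEATURES)))
  if (n < 1) stop_invalid("n must be >= 1")
  if (method == "lhs") {
    set.seed(seed)
    u <- lhs::randomLHS(n, length(SURROGATE_FEATURES))
  } else {
    levels_per_dim <- ceiling(n^(1 / 6))
    g <- do.call(expand.grid,
                 rep(list(seq(0, 1, length.out = max(levels_per_dim, 2))), 6))
    u <- as.matrix(g[seq_len(min(n, nrow(g))), ])
  }
  out <- as.data.frame(u)
  names(out) <- SURROGATE_FEATURES
  for (nm in SURROGATE_FEATURES) {
    rng <- ranges[[nm]]
    out[[nm]] <- rng[1] + out[[nm]] * (rng[2] - rng[1])
  }
  out
}

## 70/15/15 split by the floor rule: train = floor(0.70 n); the remainder is
## halved, validation = floor(rest/2), test takes the odd point. 197 points
## therefore split 137/30/30.
split_counts <- function(n) {
  n_train <- floor(0.70 * n)
  rest <- n - n_train
  n_val <- floor(rest / 2)
  c(train = n_train, validation = n_val, test = rest - n_val)
}

#' Build the simulator-backed surrogate database
#'
#' Runs [simulate_particles()] at every point of the sampling plan and
#' records the mean collision number as the regression target, together
#' with its Monte-Carlo standard error. Points are seeded independently
#' (derived from `seed` + row index) and assigned to train/validation/test
#' splits at 70/15/15 by count (floor rule, random assignment under `seed`).
#' A point whose simulation fails is excluded and reported.
#'
#' @param plan Data frame from [sampling_plan()].
#' @param seed Master seed.
#' @param gas A [gas_properties()].
#' @param n_particles Particles per simulation, default 100.
#' @param regime Flow regime passed to [build_profile()]; default `"auto"`
#'   so low-Reynolds corner points run laminar.
#' @return An object of class `surrogate_dataset`: `data` (features +
#'   `target` + `sem` + `split`), `normalizer` (empty until
#'   [fit_normalizer()]), `seed`, `n_failed`.
#' @export
build_database <- function(plan, seed = 1L, gas = gas_properties(),
                           n_particles = 100, regime = "auto") {
  stopifnot(is.data.frame(plan), all(SURROGATE_FEATURES %in% names(plan)))
  n <- nrow(plan)
  target <- sem <- rep(NA_real_, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      geo <- pipe_geometry(plan$pipe_length[i], plan$pipe_diameter[i])
      fl <- suppressWarnings(
        build_profile(geo, gas, plan$air_velocity[i], regime = regime))
      spec <- particle_spec(plan$particle_size[i] * 1e-6,
                            plan$particle_density[i])
      cfg <- tracking_config(
        n_particles = n_particles, rng_seed = derive_seed(seed, i),
        initial_vertical_speed = plan$particle_vertical_velocity[i])
      suppressWarnings(simulate_particles(spec, fl, geo, gas, cfg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("point %d: %s", i, conditionMessage(res)))
    } else {
      target[i] <- res$mean_collision_number
      sem[i] <- sd(res$per_particle_counts) / sqrt(res$n_released)
    }
  }
  data <- cbind(plan[, SURROGATE_FEATURES, drop = FALSE],
                data.frame(target = target, sem = sem))
  data <- data[!is.na(target), , drop = FALSE]
  if (length(failed) > 0)
    warning(length(failed), " simulation(s) failed and were excluded",
            call. = FALSE)
  cnt <- split_counts(nrow(data))
  set.seed(seed)
  lab <- sample(rep(c("train", "validation", "test"), times = cnt))
  data$split <- lab
  rownames(data) <- NULL
  structure(list(data = data, normalizer = NULL, seed = as.integer(seed),
                 n_particles = n_particles, n_failed = length(failed),
                 failures = failed),
            class = "surrogate_dataset")
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  cnt <- table(x$data$split)
  cat(sprintf("<surrogate_dataset> %d points (train %d / val %d / test %d)%s\n",
              nrow(x$data), cnt[["train"]], cnt[["validation"]],
              cnt[["test"]],
              if (is.null(x$normalizer)) "" else ", normalized"))
  invisible(x)
}

#' Fit the min-max normalizer on the training split
#'
#' Computes per-feature (and target) minima and maxima over the training
#' split only and stores them in the dataset. Normalized values are
#' `(x - min)/(max - min)`, so training features map into `[0, 1]`; points
#' outside the training envelope map outside and trigger an extrapolation
#' warning when transformed.
#'
#' @param dataset A [build_database()] result.
#' @return The dataset with its `normalizer` state filled in.
#' @export
fit_normalizer <- function(dataset) {
  stopifnot(inherits(dataset, "surrogate_dataset"))
  tr <- dataset$data[dataset$data$split == "train", ]
  cols <- c(SURROGATE_FEATURES, "target")
  mins <- vapply(tr[cols], min, numeric(1))
  maxs <- vapply(tr[cols], max, numeric(1))
  bad <- setdiff(cols[maxs <= mins], "target")
  if (length(bad) > 0)
    stop("degenerate normalization: feature '", bad[1],
         "' is constant on the training split", call. = FALSE)
  ## a constant target is representable: map it to 0 with unit range
  if (maxs[["target"]] <= mins[["target"]])
    maxs[["target"]] <- mins[["target"]] + 1
  dataset$normalizer <- list(min = mins, max = maxs)
  dataset
}

#' Apply a fitted min-max normalizer
#'
#' @param state A normalizer state (`$normalizer` of a dataset or ensemble).
#' @param values A data frame whose columns are a subset of the fitted ones.
#' @param warn_extrapolation Warn when any value maps outside `[0, 1]`.
#' @return The data frame with each fitted column scaled.
#' @export
normalize_values <- function(state, values, warn_extrapolation = TRUE) {
  stopifnot(is.list(state), !is.null(state$min))
  out <- values
  outside <- FALSE
  for (nm in intersect(names(values), names(state$min))) {
    out[[nm]] <- (values[[nm]] - state$min[[nm]]) /
      (state$max[[nm]] - state$min[[nm]])
    if (any(out[[nm]] < 0 | out[[nm]] > 1, na.rm = TRUE)) outside <- TRUE
  }
  if (outside && warn_extrapolation)
    warning("values outside the training range: the surrogate is ",
            "extrapolating", call. = FALSE)
  out
}

#' Invert a fitted min-max normalizer
#'
#' Exact inverse of [normalize_values()] on the fitted columns.
#'
#' @inheritParams normalize_values
#' @param values A data frame of scaled values.
#' @return The data frame mapped back to physical units.
#' @export
denormalize_values <- function(state, values) {
  stopifnot(is.list(state), !is.null(state$min))
  out <- values
  for (nm in intersect(names(values), names(state$min)))
    out[[nm]] <- values[[nm]] * (state$max[[nm]] - state$min[[nm]]) +
      state$min[[nm]]
  out
}

## Forward pass of one 6-H-1 member: logistic hidden layer, linear output.
## wts layout follows nnet: per hidden unit (bias, 6 weights), then the
## output unit (bias, H weights).
member_forward <- function(wts, X, hidden) {
  p <- ncol(X)
  W1 <- matrix(0, hidden, p); b1 <- numeric(hidden)
  idx <- 1L
  for (h in seq_len(hidden)) {
    b1[h] <- wts[idx]
    W1[h, ] <- wts[idx + seq_len(p)]
    idx <- idx + p + 1L
  }
  b2 <- wts[idx]
  W2 <- wts[idx + seq_len(hidden)]
  A <- 1 / (1 + exp(-(X %*% t(W1) + matrix(b1, nrow(X), hidden, byrow = TRUE))))
  drop(A %*% W2 + b2)
}

train_member <- function(Xtr, ytr, hidden, seed, decay, maxit) {
  set.seed(seed)
  fit <- nnet::nnet(x = Xtr, y = ytr, size = hidden, linout = TRUE,
                    decay = decay, maxit = maxit, trace = FALSE)
  fit$wts
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Train the surrogate ensemble
#'
#' Fits `n_members` independently initialized feed-forward networks (six
#' inputs, one hidden layer of `hidden_neurons` logistic units, linear
#' output) on the min-max-normalized training split, with weight-decay
#' regularization. The ensemble prediction is the arithmetic mean of the
#' member outputs. Member test RMSEs are reported in collision-number units
#' (denormalized). Members whose fit is non-finite or whose validation RMSE
#' exceeds five times the member median are flagged as non-converged; the
#' ensemble proceeds if at least 80 percent converge, else errors.
#'
#' @param dataset A [build_database()] result (normalizer fitted on demand).
#' @param hidden_neurons Hidden-layer width, default 6.
#' @param n_members Ensemble size, default 30.
#' @param seed Master seed for member initializations.
#' @param decay Weight decay, default 1e-2.
#' @param maxit Optimizer iteration cap per member, default 2000.
#' @return An object of class `surrogate_ensemble`: `member_wts`,
#'   `member_rmse` (test split), `mean_rmse`, `converged`, `hidden`,
#'   `normalizer`, `features`.
#' @export
train_ensemble <- function(dataset, hidden_neurons = 6, n_members = 30,
                           seed = 1L, decay = 1e-2, maxit = 2000) {
  stopifnot(inherits(dataset, "surrogate_dataset"))
  if (is.null(dataset$normalizer)) dataset <- fit_normalizer(dataset)
  state <- dataset$normalizer
  d <- normalize_values(state, dataset$data, warn_extrapolation = FALSE)
  Xtr <- as.matrix(d[d$split == "train", SURROGATE_FEATURES])
  ytr <- d$target[d$split == "train"]
  Xval <- as.matrix(d[d$split == "validation", SURROGATE_FEATURES])
  yval_phys <- dataset$data$target[d$split == "validation"]
  Xte <- as.matrix(d[d$split == "test", SURROGATE_FEATURES])
  yte_phys <- dataset$data$target[d$split == "test"]
  t_min <- state$min[["target"]]; t_rng <- state$max[["target"]] - t_min

  member_wts <- vector("list", n_members)
  member_rmse <- val_rmse <- rep(NA_real_, n_members)
  for (m in seq_len(n_members)) {
    wts <- train_member(Xtr, ytr, hidden_neurons,
                        derive_seed(seed, 1000 + m), decay, maxit)
    member_wts[[m]] <- wts
    if (all(is.finite(wts))) {
      val_rmse[m] <- rmse(yval_phys,
                          member_forward(wts, Xval, hidden_neurons) * t_rng + t_min)
      member_rmse[m] <- rmse(yte_phys,
                             member_forward(wts, Xte, hidden_neurons) * t_rng + t_min)
    }
  }
  converged <- is.finite(val_rmse) &
    val_rmse <= 5 * stats::median(val_rmse, na.rm = TRUE)
  if (mean(converged) < 0.8)
    stop("fewer than 80% of ensemble members converged", call. = FALSE)

  structure(list(member_wts = member_wts[converged],
                 member_rmse = member_rmse[converged],
                 mean_rmse = mean(member_rmse[converged]),
                 converged = converged, hidden = hidden_neurons,
                 normalizer = state, features = SURROGATE_FEATURES),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> %d members, %d hidden neurons, mean test RMSE %.3g\n",
    length(x$member_wts), x$hidden, x$mean_rmse))
  invisible(x)
}

#' Predict mean collision numbers with the surrogate ensemble
#'
#' @param object A [train_ensemble()] result.
#' @param newdata Data frame with the six feature columns (physical units).
#' @param ... Unused.
#' @return Numeric vector of predicted mean collision numbers (arithmetic
#'   mean of the member outputs, denormalized).
#' @export
predict.surrogate_ensemble <- function(object, newdata, ...) {
  stopifnot(all(object$features %in% names(newdata)))
  d <- normalize_values(object$normalizer,
                        newdata[, object$features, drop = FALSE])
  X <- as.matrix(d)
  preds <- vapply(object$member_wts,
                  function(w) member_forward(w, X, object$hidden),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  t_min <- object$normalizer$min[["target"]]
  t_rng <- object$normalizer$max[["target"]] - t_min
  rowMeans(preds) * t_rng + t_min
}

#' Hidden-neuron sweep
#'
#' For each candidate hidden-layer width, trains `repeats` independently
#' seeded single networks and averages their test RMSE (collision-number
#' units), mirroring the usual width-selection study.
#'
#' @param dataset A [build_database()] result.
#' @param candidates Hidden widths to try, default 1:10.
#' @param repeats Networks per width, default 5.
#' @param seed Master seed.
#' @inheritParams train_ensemble
#' @return A data frame (`hidden`, `mean_rmse`) sorted by `hidden`, with
#'   the best width in `attr(, "best_hidden")`.
#' @export
neuron_sweep <- function(dataset, candidates = 1:10, repeats = 5, seed = 1L,
                         decay = 1e-2, maxit = 2000) {
  stopifnot(inherits(dataset, "surrogate_dataset"))
  if (is.null(dataset$normalizer)) dataset <- fit_normalizer(dataset)
  state <- dataset$normalizer
  d <- normalize_values(state, dataset$data, warn_extrapolation = FALSE)
  Xtr <- as.matrix(d[d$split == "train", SURROGATE_FEATURES])
  ytr <- d$target[d$split == "train"]
  Xte <- as.matrix(d[d$split == "test", SURROGATE_FEATURES])
  yte_phys <- dataset$data$target[d$split == "test"]
  t_min <- state$min[["target"]]; t_rng <- state$max[["target"]] - t_min

  res <- lapply(candidates, function(h) {
    errs <- vapply(seq_len(repeats), function(r) {
      wts <- train_member(Xtr, ytr, h, derive_seed(seed, h * 100 + r),
                          decay, maxit)
      rmse(yte_phys, member_forward(wts, Xte, h) * t_rng + t_min)
    }, numeric(1))
    mean(errs)
  })
  out <- data.frame(hidden = candidates, mean_rmse = unlist(res))
  out <- out[order(out$hidden), ]
  rownames(out) <- NULL
  attr(out, "best_hidden") <- out$hidden[which.min(out$mean_rmse)]
  out
}

#' Serialize a surrogate ensemble to JSON
#'
#' Stores the member weights, hidden width and normalizer state under a
#' schema version, so [load_surrogate()] reproduces predictions exactly.
#'
#' @param ensemble A [train_ensemble()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_surrogate <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  doc <- list(schema_version = 1L, hidden = ensemble$hidden,
              features = ensemble$features,
              normalizer = list(min = as.list(ensemble$normalizer$min),
                                max = as.list(ensemble$normalizer$max)),
              member_rmse = ensemble$member_rmse,
              mean_rmse = ensemble$mean_rmse,
              member_wts = ensemble$member_wts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a surrogate ensemble from JSON
#'
#' @param path File written by [save_surrogate()].
#' @return A `surrogate_ensemble`.
#' @export
load_surrogate <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported surrogate schema version", call. = FALSE)
  nm <- list(min = unlist(doc$normalizer$min), max = unlist(doc$normalizer$max))
  wts <- doc$member_wts
  if (is.matrix(wts)) wts <- lapply(seq_len(nrow(wts)), function(i) wts[i, ])
  structure(list(member_wts = wts, member_rmse = doc$member_rmse,
                 mean_rmse = doc$mean_rmse,
                 converged = rep(TRUE, length(wts)),
                 hidden = doc$hidden, normalizer = nm,
                 features = doc$features),
            class = "surrogate_ensemble")
}
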