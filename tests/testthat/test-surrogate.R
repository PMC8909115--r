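small_db <- function(n = 60, seed = 3, n_particles = 25) {
  plan <- sampling_plan(n, seed = seed)
  suppressWarnings(build_database(plan, seed = seed,
                                  n_particles = n_particles))
}

test_that("sampling plans cover the studied ranges", {
  plan <- sampling_plan(50, seed = 1)
  expect_identical(nrow(plan), 50L)
  for (nm in names(table1_ranges())) {
    rng <- table1_ranges()[[nm]]
    expect_true(all(plan[[nm]] >= rng[1] & plan[[nm]] <= rng[2]))
  }
  expect_identical(sampling_plan(50, seed = 1), plan) # seeded
  g <- sampling_plan(64, method = "grid")
  expect_identical(nrow(g), 64L)
})

test_that("a singleton plan reproduces a direct simulation", {
  plan <- sampling_plan(1, seed = 5)
  db <- build_database(plan, seed = 5, n_particles = 25)
  geo <- pipe_geometry(plan$pipe_length, plan$pipe_diameter)
  fl <- suppressWarnings(build_profile(geo, gas_properties(),
                                       plan$air_velocity))
  sm <- simulate_particles(
    particle_spec(plan$particle_size * 1e-6, plan$particle_density), fl,
    config = tracking_config(
      n_particles = 25, rng_seed = tribochar:::derive_seed(5, 1),
      initial_vertical_speed = plan$particle_vertical_velocity))
  expect_equal(db$data$target, sm$mean_collision_number)
})

test_that("database builds are reproducible and split disjointly", {
  db1 <- small_db()
  db2 <- small_db()
  expect_identical(db1$data, db2$data)
  expect_identical(sum(db1$data$split == "train"), 42L)  # floor(0.7 * 60)
  expect_setequal(unique(db1$data$split), c("train", "validation", "test"))
  expect_identical(length(db1$data$split), nrow(db1$data))
})

test_that("min-max normalization maps training data to [0,1] and inverts", {
  db <- fit_normalizer(small_db())
  tr <- db$data[db$data$split == "train", ]
  sc <- normalize_values(db$normalizer, tr, warn_extrapolation = FALSE)
  feats <- tribochar:::SURROGATE_FEATURES
  for (nm in feats) {
    expect_gte(min(sc[[nm]]), 0)
    expect_lte(max(sc[[nm]]), 1)
  }
  # endpoints hit 0 and 1 exactly
  expect_equal(min(sc$particle_size), 0)
  expect_equal(max(sc$particle_size), 1)
  back <- denormalize_values(db$normalizer, sc)
  for (nm in feats) expect_equal(back[[nm]], tr[[nm]], tolerance = 1e-12)
  # a point beyond the training envelope maps outside [0,1] and warns
  outside <- tr[1, ]
  outside$particle_size <- db$normalizer$max[["particle_size"]] * 2
  expect_warning(sc_out <- normalize_values(db$normalizer, outside),
                 "extrapolating")
  expect_gt(sc_out$particle_size, 1)
})

test_that("a constant feature triggers a degenerate-normalization error", {
  db <- small_db()
  db$data$pipe_diameter <- 4.76e-3
  expect_error(fit_normalizer(db), "pipe_diameter")
})

test_that("a constant-target dataset is learned to near-zero RMSE", {
  db <- small_db()
  db$data$target <- 7.5
  ens <- train_ensemble(db, n_members = 5, seed = 2)
  expect_true(all(ens$member_rmse <= 1e-3))
})

test_that("the ensemble prediction is the mean of its members", {
  db <- small_db()
  ens <- train_ensemble(db, n_members = 6, seed = 4)
  newdata <- db$data[sample(nrow(db$data), 5), ]
  pred <- suppressWarnings(predict(ens, newdata))
  X <- as.matrix(normalize_values(ens$normalizer, newdata,
                                  warn_extrapolation = FALSE)[, ens$features])
  t_min <- ens$normalizer$min[["target"]]
  t_rng <- ens$normalizer$max[["target"]] - t_min
  manual <- rowMeans(vapply(ens$member_wts, function(w)
    tribochar:::member_forward(w, X, ens$hidden), numeric(5))) * t_rng + t_min
  expect_equal(pred, manual, tolerance = 1e-12)
})

test_that("the manual forward pass agrees with nnet's own predictions", {
  set.seed(9)
  X <- matrix(runif(80 * 3), 80, 3)
  y <- X %*% c(1, -2, 0.5) + 0.05 * rnorm(80)
  fit <- nnet::nnet(x = X, y = y, size = 4, linout = TRUE, decay = 1e-3,
                    maxit = 500, trace = FALSE)
  expect_equal(drop(predict(fit, X)),
               tribochar:::member_forward(fit$wts, X, 4), tolerance = 1e-10)
})

test_that("training is reproducible and beats the train-mean baseline", {
  db <- small_db()
  ens1 <- train_ensemble(db, n_members = 8, seed = 6)
  ens2 <- train_ensemble(db, n_members = 8, seed = 6)
  expect_identical(ens1$member_wts, ens2$member_wts)
  te <- db$data$split == "test"
  baseline <- sqrt(mean((db$data$target[te] -
                           mean(db$data$target[db$data$split == "train"]))^2))
  expect_lte(ens1$mean_rmse, baseline)
})

test_that("the neuron sweep is seeded and covers all candidates", {
  db <- small_db()
  s1 <- neuron_sweep(db, candidates = 1:10, repeats = 1, seed = 8)
  s2 <- neuron_sweep(db, candidates = 1:10, repeats = 1, seed = 8)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 10L)
  expect_identical(s1$hidden, 1:10)
  expect_true(attr(s1, "best_hidden") %in% 1:10)
})

test_that("a serialized ensemble reloads with identical predictions", {
  db <- small_db()
  ens <- train_ensemble(db, n_members = 4, seed = 10)
  path <- tempfile(fileext = ".json")
  save_surrogate(ens, path)
  back <- load_surrogate(path)
  newdata <- db$data[1:7, ]
  expect_equal(suppressWarnings(predict(back, newdata)),
               suppressWarnings(predict(ens, newdata)), tolerance = 1e-10)
  unlink(path)
})
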