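test_that("packaged tables parse with the published values", {
  t3 <- load_fixture("table3")
  expect_identical(nrow(t3), 5L)
  expect_equal(t3$density_kg_m3[t3$material == "Glass beads"], 2420)
  expect_equal(t3$density_kg_m3[t3$material == "Flour"], 1440)
  expect_equal(t3$density_kg_m3[t3$material == "Steel"], 7850)

  t2 <- load_fixture("table2")
  expect_identical(nrow(t2), 7L)
  pan <- t2[t2$mesh_label == "Pan (<53 um)", ]
  expect_equal(pan$d43_um, 25.0)
  expect_equal(pan$protein_wt_pct, 14.2)
  expect_equal(pan$qm_nC_per_g, 138.2)
  m270 <- t2[t2$mesh_label == "No. 270", ]
  expect_equal(m270$d43_um, 61.7)
  expect_equal(m270$protein_wt_pct, 26.4)
  expect_equal(m270$qm_nC_per_g, 608.8)
  expect_equal(m270$qm_sd, 151.3)

  expect_identical(load_fixture("table2"), t2)
  expect_error(load_fixture("table9"), "available: table2, table3")
})

test_that("CSV round trips preserve fixture values exactly", {
  t2 <- load_fixture("table2")
  path <- tempfile(fileext = ".csv")
  write.csv(t2, path, row.names = FALSE)
  back <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expect_identical(back, t2)
  unlink(path)
})

test_that("size distributions sample seeded log-normal mixtures", {
  mono <- size_distribution(data.frame(median_um = 380, gsd = 1, weight = 1))
  expect_identical(mono$kind, "monomodal")
  s <- generate_size_distribution(mono, 100, seed = 1)
  expect_equal(s$d43_um, 380)
  expect_equal(s$diameters_um, rep(380, 100))

  bi <- size_distribution(data.frame(median_um = c(6, 30),
                                     gsd = c(1.5, 1.6),
                                     weight = c(0.3, 0.7)))
  expect_identical(bi$kind, "bimodal")
  a <- generate_size_distribution(bi, 500, seed = 9)
  b <- generate_size_distribution(bi, 500, seed = 9)
  expect_identical(a$diameters_um, b$diameters_um)

  expect_error(size_distribution(data.frame(median_um = 10, gsd = 1.4,
                                            weight = 0.7)), "sum to 1")
  expect_error(size_distribution(data.frame(median_um = 10, gsd = 0.9,
                                            weight = 1)), ">= 1")
})

test_that("D4,3 matches a large-sample Monte-Carlo reference", {
  spec <- size_distribution(data.frame(median_um = 380, gsd = 1.3,
                                       weight = 1))
  gen <- generate_size_distribution(spec, 1e5, seed = 2)
  # brute-force reference with a different seed
  set.seed(77)
  d <- rlnorm(1e6, log(380), log(1.3))
  ref <- sum(d^4) / sum(d^3)
  expect_equal(gen$d43_um, ref, tolerance = 0.02)
})

test_that("volume, Sauter and arithmetic means are correctly ordered", {
  set.seed(13)
  for (i in 1:10) {
    spec <- size_distribution(data.frame(median_um = runif(1, 10, 300),
                                         gsd = runif(1, 1.1, 2.5),
                                         weight = 1))
    s <- generate_size_distribution(spec, 2000, seed = i)
    expect_gte(s$d43_um, s$d32_um)
    expect_gte(s$d32_um, s$mean_um)
  }
})

test_that("run configurations parse from YAML and JSON", {
  cfg_yaml <- tempfile(fileext = ".yaml")
  writeLines(c("pipe: {length_m: 1.0, diameter_m: 0.00476}",
               "gas: {density: 1.2, viscosity: 1.81e-5}",
               "flow: {mean_velocity: 8.4, regime: turbulent}",
               "particle: {diameter_um: 61.7, density: 1440}",
               "tracking: {n_particles: 10, rng_seed: 4}"), cfg_yaml)
  cfg <- read_run_config(cfg_yaml)
  expect_s3_class(cfg$geometry, "pipe_geometry")
  expect_equal(cfg$geometry$inner_diameter, 4.76e-3)
  expect_equal(cfg$mean_velocity, 8.4)
  expect_equal(cfg$particle$diameter, 61.7e-6)
  expect_identical(cfg$tracking$n_particles, 10L)

  cfg_json <- tempfile(fileext = ".json")
  writeLines('{"pipe": {"length_m": 0.5, "diameter_m": 0.002}}', cfg_json)
  cfg2 <- read_run_config(cfg_json)
  expect_equal(cfg2$geometry$length, 0.5)
  expect_error(read_run_config("no/such/file.yaml"), "not found")
  unlink(c(cfg_yaml, cfg_json))
})

test_that("manifests record seed and a stable config digest", {
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_manifest(p1, 42, list(a = 1, b = "x"))
  write_manifest(p2, 42, list(a = 1, b = "x"))
  m1 <- jsonlite::read_json(p1)
  m2 <- jsonlite::read_json(p2)
  expect_identical(m1$master_seed, 42L)
  expect_identical(m1$config_digest, m2$config_digest)
  write_manifest(p2, 42, list(a = 2, b = "x"))
  expect_false(identical(jsonlite::read_json(p2)$config_digest,
                         m1$config_digest))
  unlink(c(p1, p2))
})

test_that("the CLI dispatcher runs subcommands end to end", {
  out <- tempfile(fileext = ".csv")
  tribochar_cli(c("fixtures", "--name", "table3", "--out", out))
  expect_identical(read.csv(out, check.names = FALSE), load_fixture("table3"))
  expect_true(file.exists(paste0(out, ".manifest.json")))

  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("pipe: {length_m: 1.0, diameter_m: 0.00476}",
               "flow: {mean_velocity: 8.4, regime: turbulent}",
               "particle: {diameter_um: 100, density: 1440}",
               "tracking: {n_particles: 10}"), cfg)
  out2 <- tempfile(fileext = ".csv")
  suppressMessages(tribochar_cli(c("simulate", "--config", cfg, "--seed", "3",
                                   "--out", out2)))
  row <- read.csv(out2)
  expect_gt(row$mean_collision_number, 0)
  expect_identical(row$n_exited + row$n_timed_out, 10L)
  expect_error(tribochar_cli(c("nope", "--out", "x")), "unknown subcommand")
  unlink(c(out, out2, cfg, paste0(c(out, out2), ".manifest.json")))
})
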