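# Synthetic fixture generators: geometry schema, determinism, activity
# profiles, virtual markers.

test_that("knee geometry has the full schema and clean reference clearances", {
  geo <- make_knee_geometry(coarse_params())
  tissue <- c("femoral_cartilage", "medial_tibial_cartilage",
              "lateral_tibial_cartilage", "medial_meniscus",
              "lateral_meniscus", "patellar_cartilage")
  bones <- c("femur", "tibia", "patella")
  expect_true(all(c(tissue, bones) %in% names(geo)))
  expect_equal(nrow(geo$attachments), 22)
  # bones are watertight, outward-oriented solids
  for (b in bones) expect_gt(mesh_volume(geo[[b]]), 0)
  # no initial penetration anywhere at the reference pose
  for (pr in build_default_pairs(geo))
    expect_equal(max(vertex_penetrations(pr)$depth), 0)
  # compartment tags present on both sides
  expect_true(all(c("medial", "lateral") %in% geo$femoral_cartilage$compartment))
  expect_error(make_knee_geometry(knee_fixture_params(cart_r = 30)),
               class = "knee_parameter_error")
})

test_that("requested condylar radius is recovered by a sphere fit", {
  geo <- make_knee_geometry(knee_fixture_params(medial_radius = 22,
                                                density = 0.8))
  med <- geo$femoral_cartilage
  keep <- unique(as.vector(med$faces[med$compartment == "medial", ]))
  fit <- fit_sphere(med$vertices[keep, ])
  expect_equal(fit$radius, 22, tolerance = 0.1 / 22)
  expect_equal(fit$center, c(0, 22, 0), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("geometry and STL export are deterministic", {
  p <- coarse_params()
  g1 <- make_knee_geometry(p)
  g2 <- make_knee_geometry(p)
  expect_identical(g1$femoral_cartilage$vertices, g2$femoral_cartilage$vertices)
  f1 <- withr::local_tempfile(fileext = ".stl")
  f2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(g1$medial_meniscus, f1)
  write_stl(g2$medial_meniscus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("activity trials have the stated shapes and are seed-deterministic", {
  for (act in c("walk", "stair_ascent", "stair_descent", "sit_to_stand",
                "stand_to_sit")) {
    tr <- make_activity_trial(act, n_frames = 51)
    fl <- tr$frames$flexion
    expect_true(all(tr$grf$fz >= 0))
    peak <- max(fl)
    if (act == "walk") expect_true(peak > 55 && peak < 70)
    if (act %in% c("stair_ascent", "stair_descent"))
      expect_true(peak > 85 && peak < 115)
    if (act == "sit_to_stand") {
      expect_true(all(diff(fl) < 0.5))  # monotone-ish 90 -> 0 sweep
      expect_gt(fl[1], 80)
      expect_lt(fl[51], 10)
    }
    if (act == "stand_to_sit") {
      expect_lt(fl[1], 10)
      expect_gt(fl[51], 80)
    }
  }
  expect_error(make_activity_trial("jump"), class = "knee_domain_error")
  t1 <- make_activity_trial("walk", seed = 9, n_frames = 21)
  t2 <- make_activity_trial("walk", seed = 9, n_frames = 21)
  t3 <- make_activity_trial("walk", seed = 10, n_frames = 21)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$markers$observed_tibia, t2$markers$observed_tibia)
  expect_false(identical(t1$markers$observed_tibia, t3$markers$observed_tibia))
})

test_that("two-feet vertical GRF impulse balances body weight", {
  for (act in c("walk", "stair_ascent", "sit_to_stand")) {
    tr <- make_activity_trial(act, n_frames = 21)
    g <- tr$grf
    dt <- diff(g$time)[1]
    # contralateral leg carries the half-cycle-shifted copy
    shift <- round(nrow(g) / 2)
    both <- g$fz + g$fz[((seq_len(nrow(g)) - 1 + shift) %% nrow(g)) + 1]
    impulse <- sum(both) * dt
    expect_equal(impulse, tr$bw * tr$duration, tolerance = 0.02)
  }
})

test_that("noiseless markers close the loop on the flexion profile", {
  tr <- make_activity_trial("walk", n_frames = 21, noise_sd = 0)
  rec <- flexion_from_markers(tr)
  expect_equal(rec, tr$frames$flexion, tolerance = 1e-6)
  # with 1 mm noise the profile is still recovered to a couple of degrees
  trn <- make_activity_trial("walk", n_frames = 21, noise_sd = 1)
  recn <- flexion_from_markers(trn)
  expect_lt(stats::median(abs(recn - trn$frames$flexion)), 2.5)
})

test_that("fixture files and the model config round trip", {
  dir <- withr::local_tempdir()
  generate_fixture_files(dir, activity = "walk", params = coarse_params(),
                         seed = 7)
  expect_true(file.exists(file.path(dir, "femoral_cartilage.stl")))
  expect_true(file.exists(file.path(dir, "grf.txt")))
  expect_true(file.exists(file.path(dir, "model.json")))
  model <- load_model_config(file.path(dir, "model.json"))
  expect_s3_class(model, "KneeModel")
  expect_length(model$ligaments, 22)
  expect_length(model$contacts, 5)
  # schema validation: dropping a bundle is rejected
  cfg <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg$ligaments <- cfg$ligaments[-1, ]
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(cfg, bad, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  expect_error(load_model_config(bad), class = "knee_config_error")
})
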