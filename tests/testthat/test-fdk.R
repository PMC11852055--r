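# FDK residual assembly, the per-frame equilibrium search, and trial-level
# bookkeeping on toy configurations (the full knee runs in the acceptance
# suite).

no_load <- list(flexion = 0, ext_force = c(0, 0, 0), ext_moment = c(0, 0, 0))

test_that("a relaxed spring gives zero residual; Hooke displacement scales it", {
  model <- make_spring_model(k = 100, L0 = 100)
  expect_equal(max(abs(fdk_residual(numeric(10), no_load, model))), 0)
  # axial displacement 0.2 mm -> 20 N restoring force on that coordinate
  a <- numeric(10); a[5] <- 0.2
  Q <- fdk_residual(a, no_load, model)
  expect_equal(abs(Q[5]), 20, tolerance = 1e-6)
  expect_equal(max(abs(Q[-5])), 0, tolerance = 1e-9)
})

test_that("1-DOF spring equilibrium matches the analytic solution", {
  model <- make_spring_model(k = 100, L0 = 100)
  frame <- list(flexion = 0, ext_force = c(0, 0, 50), ext_moment = c(0, 0, 0))
  st <- solve_fdk_frame(numeric(10), frame, model)
  expect_true(st$converged)
  expect_equal(st$alpha[5], 0.5, tolerance = 0.01)  # 50 N / (100 N/mm)
  expect_lt(st$max_residual, 1)
  # starting exactly at equilibrium stays there
  st2 <- solve_fdk_frame(st$alpha, frame, model)
  expect_true(st2$converged)
  expect_equal(st2$alpha, st$alpha, tolerance = 1e-9)
  expect_error(solve_fdk_frame(numeric(10), frame, model, threshold = 0),
               class = "knee_domain_error")
})

test_that("elastic-only residuals equal -dE/dalpha (energy-gradient oracle)", {
  model <- make_elastic_model()
  frame <- list(flexion = 12, ext_force = NULL, ext_moment = NULL)
  E <- function(a) elastic_energy(a, frame, model)
  set.seed(31)
  for (rep in 1:4) {
    alpha <- c(runif(2, -3, 3), runif(3, -2, 2), runif(2, -3, 3), runif(3, -4, 4))
    Q <- fdk_residual(alpha, frame, model)
    g <- -fd_gradient(E, alpha)
    # rotational coordinates are stated in degrees but conjugate forces are
    # per radian
    g[kneefdk:::ROT_COORDS] <- g[kneefdk:::ROT_COORDS] * 180 / pi
    big <- abs(g) > 1  # compare where the gradient is numerically resolvable
    expect_true(any(big))
    expect_equal(Q[big], g[big], tolerance = 1e-4)
  }
})

test_that("converged frames respect the threshold on all active coordinates", {
  model <- make_spring_model()
  frame <- list(flexion = 0, ext_force = c(0, 0, 37), ext_moment = c(0, 0, 0))
  for (thr in c(1, 0.05)) {
    st <- solve_fdk_frame(numeric(10), frame, model, threshold = thr)
    expect_true(st$converged)
    expect_lte(max(abs(kneefdk:::scale_residual(st$F_FDK, model)[model$active_dofs])),
               thr)
  }
})

test_that("sphere-on-plane equilibrium matches the elastic-foundation integral", {
  # F = PM pi R delta^2 is the small-delta/R limit of the foundation
  # integral (relative truncation ~ delta/(3R)), so probe it at a
  # penetration two orders below the sphere radius
  R <- 40
  mat <- material(5, 0.46, 2.2)
  PM <- pressure_module(mat, mat)
  plate <- make_plate(w = 36, h = 0.6, z = 0, up = TRUE, label = "plate")
  cap <- make_sphere_cap(R = R, center = c(18, 18, R + 0.05), nt = 48, np = 72)
  pr <- contact_pair(plate, cap, mat, mat, name = "toy", slave_body = "tibia")
  load <- 200
  model <- knee_model(contacts = list(pr), active_dofs = 5)
  frame <- list(flexion = 0, ext_force = c(0, 0, load), ext_moment = c(0, 0, 0))
  st <- solve_fdk_frame(numeric(10), frame, model)
  expect_true(st$converged)
  delta <- st$alpha[5] - 0.05        # initial 0.05 mm gap
  expect_equal(PM * pi * R * delta^2, load, tolerance = 0.02)
})

test_that("run_trial output is consistent frame by frame", {
  # small elastic model driven through a short flexion ramp: no contacts,
  # so TFCF stays zero while bookkeeping still runs
  model <- make_elastic_model()
  trial <- list(activity = "walk",
                frames = data.frame(time = seq(0, 0.1, length.out = 6),
                                    flexion = seq(0, 10, length.out = 6),
                                    fx = 0, fy = 0, fz = 0,
                                    mx = 0, my = 0, mz = 0))
  res <- run_trial(model, trial)
  expect_s3_class(res, "TrialResult")
  expect_equal(nrow(res$curves), 101)
  expect_true(all(res$converged))
  expect_true(all(res$curves$tfcf_total_bw == 0))
  # medial + lateral resultants equal the tibiofemoral total vector
  geoq <- build_knee_model(coarse_params())
  det <- fdk_residual(numeric(10), list(flexion = 0, ext_force = c(0, 0, 300),
                                        ext_moment = c(0, 0, 0)), geoq,
                      detail = TRUE)
  tf <- kneefdk:::tfcf_from_contacts(det$loads$contact_results, geoq)
  expect_equal(tf$medial_vec + tf$lateral_vec, tf$total_vec, tolerance = 1e-12)
})

test_that("warm starts from different initial points agree (local minimum check)", {
  model <- make_spring_model()
  frame <- list(flexion = 0, ext_force = c(0, 0, 80), ext_moment = c(0, 0, 0))
  a1 <- solve_fdk_frame(numeric(10), frame, model)$alpha
  start2 <- numeric(10); start2[5] <- 2.5
  a2 <- solve_fdk_frame(start2, frame, model)$alpha
  expect_equal(a1[5], a2[5], tolerance = 0.01)
})

test_that("curve files round-trip through delimited text", {
  model <- make_elastic_model()
  trial <- list(activity = "sit_to_stand",
                frames = data.frame(time = seq(0, 0.05, length.out = 4),
                                    flexion = c(0, 2, 4, 6),
                                    fx = 0, fy = 0, fz = 0, mx = 0, my = 0, mz = 0))
  res <- run_trial(model, trial)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curves(res, path)
  back <- read_curves(path)
  expect_equal(nrow(back), 101)
  expect_equal(back$tfcf_total_bw, res$curves$tfcf_total_bw, tolerance = 1e-9)
  expect_true(all(back$activity == "sit_to_stand"))
  cs <- withr::local_tempfile(fileext = ".tsv")
  write_contact_summary(res, cs)
  d <- read.table(cs, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 3 * length(res$frames))
  expect_true(all(c("medial", "lateral", "total") %in% d$compartment))
})
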