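# Cubic-criterion static optimization, muscle strength, moment arms and
# intersegmental loads.

test_that("maximum isometric force follows F0 = mu Vol0 / Lf0", {
  expect_equal(max_isometric_force(100, 10, 27), 270)
  expect_equal(max_isometric_force(100, 10), 270)  # default mu = 27 N/cm^2
  expect_error(max_isometric_force(0, 10), class = "knee_domain_error")
  expect_error(max_isometric_force(100, -2), class = "knee_domain_error")
  mu <- muscle_unit("m", 100, 10,
                    data.frame(body = c("femur", "tibia"),
                               x = c(0, 0), y = c(0, 0), z = c(50, -50)))
  expect_equal(mu$F0, 270)
  expect_equal(mu$N, mu$F0)
})

test_that("two identical muscles split a load 50/50; strengths bias the split", {
  p <- recruitment_problem(matrix(c(1, 1), 1), 100, c(TRUE, TRUE),
                           N = c(1, 1))
  s <- solve_recruitment(p)
  expect_equal(as.numeric(s$muscle_forces), c(50, 50), tolerance = 1e-6)
  # N1 = 2 N2: KKT gives f1 = 2 sqrt(2) f2
  p2 <- recruitment_problem(matrix(c(1, 1), 1), 100, c(TRUE, TRUE),
                            N = c(2, 1))
  s2 <- solve_recruitment(p2)
  f1 <- 100 * 2 * sqrt(2) / (1 + 2 * sqrt(2))
  expect_equal(as.numeric(s2$muscle_forces), c(f1, 100 - f1), tolerance = 1e-6)
  expect_lt(s2$constraint_residual, 1e-6 * 100)
})

test_that("random small problems match the grid-search oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(2:3, 1)
    C <- matrix(runif(n, 0.5, 2), 1)
    r <- runif(1, 50, 200)
    N <- runif(n, 100, 1500)
    V <- runif(n, 0.5, 2)
    sol <- solve_recruitment(recruitment_problem(C, r, rep(TRUE, n), N, V))
    oracle <- grid_search_recruitment(C, r, N, V)
    # objective at least as good as the best grid point, and the grid best
    # no better than the solver beyond grid resolution
    expect_lte(sol$objective, oracle$objective * (1 + 1e-6) + 1e-9)
    expect_equal(sol$objective, oracle$objective, tolerance = 0.05)
  }
})

test_that("scaling all volume factors leaves the minimizer unchanged", {
  C <- matrix(c(1.2, 0.7, 1.0), 1)
  N <- c(800, 1200, 400)
  s1 <- solve_recruitment(recruitment_problem(C, 150, rep(TRUE, 3), N,
                                              V = c(1, 2, 0.5)))
  s2 <- solve_recruitment(recruitment_problem(C, 150, rep(TRUE, 3), N,
                                              V = 7 * c(1, 2, 0.5)))
  expect_equal(as.numeric(s1$muscle_forces), as.numeric(s2$muscle_forces),
               tolerance = 1e-5)
  expect_equal(s2$objective, 7 * s1$objective, tolerance = 1e-6)
})

test_that("raising a muscle's strength never lowers its share", {
  C <- matrix(c(1, 1), 1)
  shares <- vapply(c(0.5, 1, 2, 4), function(n1) {
    s <- solve_recruitment(recruitment_problem(C, 100, c(TRUE, TRUE),
                                               N = c(n1, 1)))
    as.numeric(s$muscle_forces[1])
  }, 0)
  expect_true(all(diff(shares) > 0))
})

test_that("reactions are free, unweighted, and excluded from the objective", {
  # one muscle and one reaction on separate equations
  C <- rbind(c(1, 0), c(0, 1))
  p <- recruitment_problem(C, c(80, -500), c(TRUE, FALSE), N = 400)
  s <- solve_recruitment(p)
  expect_equal(as.numeric(s$muscle_forces), 80, tolerance = 1e-6)
  expect_equal(s$f[2], -500, tolerance = 1e-6)  # unbounded below zero
  expect_equal(s$objective, (80 / 400)^3, tolerance = 1e-6)
  # perturbing the reaction load leaves the objective unchanged
  s2 <- solve_recruitment(recruitment_problem(C, c(80, 900), c(TRUE, FALSE),
                                              N = 400))
  expect_equal(s2$objective, s$objective, tolerance = 1e-9)
})

test_that("infeasible demands are reported with the violated equation", {
  # all moment arms oppose the demanded torque
  p <- recruitment_problem(matrix(c(-1, -0.5), 1), 100, c(TRUE, TRUE),
                           N = c(1, 1))
  expect_error(solve_recruitment(p), class = "knee_infeasible_error")
  err <- tryCatch(solve_recruitment(p), error = function(e) conditionMessage(e))
  expect_match(err, "equation 1")
})

test_that("moment arms: line through the joint center and perpendicular levers", {
  expect_equal(geometric_moment_arm(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0),
                                    c(0, 1, 0)), 0)
  # unit force at 40 mm perpendicular distance -> 40 N mm per N
  expect_equal(geometric_moment_arm(c(40, 0, 0), c(0, 0, 1), c(0, 0, 0),
                                    c(0, 1, 0)),
               40 * sign(geometric_moment_arm(c(40, 0, 0), c(0, 0, 1),
                                              c(0, 0, 0), c(0, 1, 0))),
               tolerance = 1e-12)
  expect_equal(abs(geometric_moment_arm(c(40, 0, 0), c(0, 0, 1), c(0, 0, 0),
                                        c(0, 1, 0))), 40)
})

test_that("tendon-excursion arms equal geometric arms for straight muscles", {
  params <- coarse_params()
  model <- build_knee_model(params)
  st <- knee_state(20)
  ma <- moment_arm_matrix(model$muscles, st, model$joint)
  poses <- kneefdk:::body_poses(st, model$joint)
  for (i in which(vapply(model$muscles, function(m) all(m$path$body != "patella"), TRUE))) {
    mu <- model$muscles[[i]]
    pts <- kneefdk:::muscle_path_points(mu, poses)
    u <- (pts[1, ] - pts[2, ]) / sqrt(sum((pts[1, ] - pts[2, ])^2))
    geom <- geometric_moment_arm(pts[2, ], u, c(0, 0, 0), c(0, 1, 0))
    expect_equal(ma[1, i], geom, tolerance = 1e-3)
  }
  # quadriceps act as knee extensors through the patella, hamstrings and
  # gastrocnemius as flexors (opposite signs)
  expect_true(all(ma[1, 1:4] < 0))
  expect_true(all(ma[1, 5:8] > 0))
  bad <- muscle_unit("bad", 10, 5,
                     data.frame(body = c("femur", "femur"),
                                x = c(1, 1), y = c(2, 2), z = c(3, 3)))
  expect_error(moment_arm_matrix(list(bad), st, model$joint),
               class = "knee_geometry_error")
})

test_that("quasi-static intersegmental load reproduces the statics oracle", {
  bw <- 73.4 * 9.81
  m_ss <- 4.5
  kin <- data.frame(time = seq(0, 1, 0.1), kx = 0, ky = 0, kz = 0,
                    cx = 0, cy = 0, cz = -200)
  grf <- data.frame(time = seq(0, 1, 0.01), fx = 0, fy = 0, fz = 0.5 * bw,
                    px = 0, py = 0, pz = -450)
  out <- intersegmental_load(kin, grf, m_ss)
  expect_equal(sqrt(sum(out$force[1, ]^2)), 0.5 * bw - m_ss * 9.81,
               tolerance = 1e-9)
  expect_lt(out$force[1, 3], 0)  # femur pushes down on the tibia
  # zero GRF, zero gravity -> zero load
  z <- intersegmental_load(kin, transform(grf, fz = 0), m_ss, gravity = 0)
  expect_equal(max(abs(z$force)), 0)
  expect_equal(max(abs(z$moment)), 0)
  # 100 N vertical applied 50 mm anterior of the knee -> 5 N m sagittal
  grf2 <- data.frame(time = seq(0, 1, 0.01), fx = 0, fy = 0, fz = 100,
                     px = 50, py = 0, pz = -450)
  out2 <- intersegmental_load(kin, grf2, mass = 1e-9)
  expect_equal(abs(out2$moment[1, 2]), 5000, tolerance = 1e-3)
  expect_error(intersegmental_load(kin[0, ], grf, m_ss),
               class = "knee_alignment_error")
  expect_error(intersegmental_load(transform(kin, time = time + 5), grf, m_ss),
               class = "knee_alignment_error")
})
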