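# Elastic-foundation contact: pressure module, penetration queries, force
# law, compartment aggregation.

test_that("pressure module matches independent arithmetic and is symmetric", {
  g <- function(v) (1 + v) * (1 - 2 * v) / (1 - v)
  fem <- material(5, 0.46, 2.2)
  mt <- material(5, 0.46, 2.1)
  expected <- 1 / (g(0.46) * 2.2 / 5 + g(0.46) * 2.1 / 5)
  expect_equal(pressure_module(fem, mt), expected, tolerance = 1e-12)
  expect_equal(round(pressure_module(fem, mt), 3), 5.376)
  expect_identical(pressure_module(fem, mt), pressure_module(mt, fem))
  # homogeneity: doubling both moduli doubles PM
  expect_equal(pressure_module(material(10, 0.46, 2.2), material(10, 0.46, 2.1)),
               2 * pressure_module(fem, mt), tolerance = 1e-12)
  expect_error(material(5, 0.5, 2), class = "knee_material_error")
})

test_that("parallel plate penetration is uniform and separation gives zeros", {
  slave <- make_plate(w = 10, h = 0.5, z = 0, up = TRUE)
  master <- make_plate(w = 10, h = 0.5, z = -0.1, up = FALSE)
  pr <- contact_pair(slave, master, material(5, 0.46, 2.2), material(5, 0.46, 2.1))
  pen <- vertex_penetrations(pr)
  expect_true(all(abs(pen$depth - 0.1) < 1e-9))
  expect_equal(sum(pen$area), 100, tolerance = 1e-9)
  apart <- contact_pair(slave, make_plate(w = 10, h = 0.5, z = 1, up = FALSE),
                        material(5, 0.46, 2.2), material(5, 0.46, 2.1))
  expect_true(all(vertex_penetrations(apart)$depth == 0))
  expect_equal(contact_forces(apart)$force_on_slave, c(0, 0, 0))
})

test_that("sphere-on-plane penetration has the right pole depth and footprint", {
  R <- 20; delta <- 0.5
  slave <- make_plate(w = 30, h = 0.5, z = 0, up = TRUE)
  master <- make_sphere_cap(R = R, center = c(15, 15, R - delta))
  pr <- contact_pair(slave, master, material(5, 0.46, 2.2), material(5, 0.46, 2.2))
  pen <- vertex_penetrations(pr)
  r <- sqrt((slave$vertices[, 1] - 15)^2 + (slave$vertices[, 2] - 15)^2)
  # facet sag of the cap mesh bounds the depth error (~R(1-cos(dtheta)))
  expect_equal(max(pen$depth), delta, tolerance = 0.05)
  expect_equal(pen$depth[which.min(r)], delta, tolerance = 0.05)
  # depth decreases radially; footprint radius ~ sqrt(2 R delta)
  a_expect <- sqrt(2 * R * delta)
  contacting <- pen$depth > 0
  expect_lt(max(r[contacting]), a_expect + 1)
  expect_gt(max(r[contacting]), a_expect - 1)
  ord <- order(r)
  expect_true(all(diff(pen$depth[ord]) < 0.03))
})

test_that("flat plate force matches PM*A*d and is linear in depth", {
  PM <- pressure_module(material(5, 0.46, 2.2), material(5, 0.46, 2.1))
  slave <- make_plate(w = 10, h = 0.5, z = 0, up = TRUE)
  mk <- function(d) contact_pair(slave, make_plate(w = 10, h = 0.5, z = -d, up = FALSE),
                                 material(5, 0.46, 2.2), material(5, 0.46, 2.1))
  f1 <- contact_forces(mk(0.1))
  expect_equal(f1$force_on_slave[3], -PM * 100 * 0.1, tolerance = 0.01)
  expect_equal(f1$force_on_master, -f1$force_on_slave, tolerance = 1e-12)
  f2 <- contact_forces(mk(0.2))
  expect_equal(f2$force_on_slave[3] / f1$force_on_slave[3], 2, tolerance = 1e-9)
})

test_that("flat-plate discretization error shrinks under refinement", {
  PM <- pressure_module(material(5, 0.46, 2.2), material(5, 0.46, 2.1))
  errs <- vapply(c(1, 0.5, 0.25), function(h) {
    slave <- make_plate(w = 10, h = h, z = 0, up = TRUE)
    master <- make_plate(w = 10, h = h, z = -0.1, up = FALSE)
    pr <- contact_pair(slave, master, material(5, 0.46, 2.2), material(5, 0.46, 2.1))
    abs(abs(contact_forces(pr)$force_on_slave[3]) - PM * 100 * 0.1) / (PM * 10)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[1], 0.01)
})

test_that("contact respects Newton's third law and compression-only forces", {
  geo <- make_knee_geometry(coarse_params())
  pairs <- build_default_pairs(geo)
  # push the tibia up into the femur
  pose_t <- pose(diag(3), c(0, 0, 0.6))
  for (pr in pairs[1:4]) {
    cf <- contact_forces(pr, pose_t, pose_identity())
    expect_equal(cf$force_on_master, -cf$force_on_slave, tolerance = 1e-12)
    expect_true(all(cf$force_mag >= 0))
    # forces on the tibia point away from the femur (downward on average)
    if (cf$n_contacting > 0) expect_lt(cf$force_on_slave[3], 0)
  }
})

test_that("compartment totals add up to the pair total", {
  geo <- make_knee_geometry(coarse_params())
  fem <- geo$femoral_cartilage
  both <- kneefdk:::merge_meshes(geo$medial_tibial_cartilage,
                                 geo$lateral_tibial_cartilage,
                                 label = "tibial_cartilage")
  pr <- contact_pair(both, fem, material(5, 0.46, 2.1), material(5, 0.46, 2.2),
                     name = "tibiofemoral")
  cf <- contact_forces(pr, pose(diag(3), c(0, 0, 0.7)), pose_identity())
  expect_gt(cf$n_contacting, 0)
  expect_equal(cf$compartment$medial + cf$compartment$lateral +
                 cf$compartment$none,
               cf$force_on_slave, tolerance = 1e-9)
})

test_that("build_default_pairs binds the tabulated materials", {
  geo <- make_knee_geometry(coarse_params())
  pairs <- build_default_pairs(geo)
  expect_length(pairs, 5)
  nm <- vapply(pairs, `[[`, "", "name")
  mm <- pairs[[which(nm == "medial_meniscus")]]
  expect_equal(mm$slave_material$E, 59)
  expect_equal(mm$slave_material$v, 0.49)
  expect_equal(mm$slave_material$h, 3.5)
  lt <- pairs[[which(nm == "lateral_tibial")]]
  expect_equal(lt$slave_material$h, 2.6)
  expect_equal(pairs[[1]]$PM,
               pressure_module(material(5, 0.46, 2.1), material(5, 0.46, 2.2)))
  geo$femoral_cartilage <- NULL
  expect_error(build_default_pairs(geo), class = "knee_config_error")
})

test_that("projected signed depth agrees with ray depth on plates", {
  slave <- make_plate(w = 10, h = 0.5, z = 0, up = TRUE)
  master <- make_plate(w = 10, h = 0.5, z = -0.1, up = FALSE)
  pr <- contact_pair(slave, master, material(5, 0.46, 2.2), material(5, 0.46, 2.1),
                     method = "project")
  pen <- vertex_penetrations(pr)
  expect_true(all(abs(pen$depth - 0.1) < 1e-9))
})
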