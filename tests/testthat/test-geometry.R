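# Mesh container, STL I/O, affine scaling, RBF morphing, projection and
# length-mass-fat scale factors.

test_that("STL round trip preserves geometry (binary and ASCII)", {
  cube <- make_cube()
  for (ascii in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(cube, path, ascii = ascii)
    m <- read_stl(path)
    expect_equal(nrow(m$faces), 12)
    expect_equal(nrow(m$vertices), 8)  # welded back to 8 unique vertices
    expect_equal(mesh_area(m), mesh_area(cube), tolerance = 1e-4)
    expect_equal(mesh_volume(m), 1, tolerance = 1e-4)
  }
})

test_that("unreadable STL input raises a format error", {
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_stl(empty), class = "knee_format_error")
  trunc <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0, 90)), trunc)  # header claims facets that are absent
  expect_error(read_stl(trunc), class = "knee_format_error")
  expect_error(read_stl(file.path(tempdir(), "no_such.stl")),
               class = "knee_format_error")
})

test_that("degenerate faces are dropped at construction", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face is collinear
  m <- trimesh(v, f)
  expect_equal(nrow(m$faces), 1)
  expect_error(trimesh(v, rbind(c(1, 2, 5))), class = "knee_mesh_error")
})

test_that("affine_scale maps vertices and scales volume by |det|", {
  cube <- make_cube()
  expect_equal(affine_scale(cube)$vertices, cube$vertices)
  expect_equal(mesh_volume(affine_scale(cube, 2 * diag(3))), 8,
               tolerance = 1e-9)
  expect_equal(mesh_volume(affine_scale(cube, diag(c(1, 2, 3)))), 6,
               tolerance = 1e-9)
  expect_error(affine_scale(cube, matrix(0, 3, 3)),
               class = "knee_transform_error")
  # random invertible maps on a closed mesh, with translation
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
    out <- affine_scale(cube, A, t = rnorm(3, 0, 10))
    expect_equal(mesh_volume(out), abs(det(A)) * mesh_volume(cube),
                 tolerance = 1e-6)
  }
})

test_that("rbf_morph interpolates landmarks exactly and reproduces affine maps", {
  set.seed(11)
  cube <- make_cube(scale = 40)
  src <- landmark_set(paste0("L", 1:6),
                      rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, 0, 40),
                            c(40, 40, 40), c(20, 10, 30)))
  # identity
  same <- rbf_morph(cube, src, src)
  expect_lt(max(abs(same$vertices - cube$vertices)), 1e-9)
  # pure translation reproduced at every vertex
  dst <- landmark_set(src$names, sweep(src$positions, 2, -c(5, 0, 0)))
  tr <- rbf_morph(cube, src, dst)
  expect_lt(max(abs(tr$vertices - sweep(cube$vertices, 2, -c(5, 0, 0)))), 1e-6)
  # random affine maps reproduced at every vertex; landmarks exact
  for (i in 1:5) {
    A <- matrix(rnorm(9, sd = 0.3), 3, 3) + diag(3)
    b <- rnorm(3, 0, 10)
    dst <- landmark_set(src$names, sweep(src$positions %*% t(A), 2, -b))
    out <- rbf_morph(cube, src, dst)
    expect_lt(max(abs(out$vertices - sweep(cube$vertices %*% t(A), 2, -b))),
              1e-5)
  }
  # nonlinear target: landmarks still mapped exactly
  dst <- landmark_set(src$names, src$positions + matrix(rnorm(18, 0, 3), 6, 3))
  out <- rbf_morph(cube, src, dst)
  fit_back <- rbf_morph(trimesh(src$positions, matrix(integer(0), 0, 3)),
                        src, dst)
  expect_lt(max(abs(fit_back$vertices - dst$positions)), 1e-6)
  expect_identical(out$faces, cube$faces)
})

test_that("rbf_morph rejects ill-posed landmark configurations", {
  cube <- make_cube()
  flat <- landmark_set(paste0("L", 1:4),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_error(rbf_morph(cube, flat, flat), class = "knee_conditioning_error")
  dup <- landmark_set(paste0("L", 1:5),
                      rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0, 0, 1)))
  expect_error(rbf_morph(cube, dup, dup), class = "knee_conditioning_error")
  a <- landmark_set(paste0("A", 1:5), matrix(rnorm(15), 5, 3))
  b <- landmark_set(paste0("B", 1:5), matrix(rnorm(15), 5, 3))
  expect_error(rbf_morph(cube, a, b), class = "knee_pairing_error")
})

test_that("landmark sets survive a text round trip", {
  lm <- landmark_set(c("med_epi", "lat_epi", "tub"),
                     rbind(c(1.25, 44, 0.5), c(0, -44, 0), c(30, 0, -45)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_identical(back$names, lm$names)
  expect_equal(back$positions, lm$positions, ignore_attr = TRUE)
})

test_that("project_to_surface moves vertices onto the target and is idempotent", {
  plate <- make_plate(w = 20, h = 1)
  pts <- trimesh(rbind(c(0, 0, 1), c(5.3, 7.1, -2), c(19, 2, 0.4)),
                 matrix(integer(0), 0, 3))
  proj <- project_to_surface(pts, plate)
  expect_equal(proj$vertices[1, ], c(0, 0, 0))
  expect_lt(max(abs(proj$vertices[, 3])), 1e-9)
  expect_equal(proj$vertices[, 1:2], pts$vertices[, 1:2])
  again <- project_to_surface(proj, plate)
  expect_equal(again$vertices, proj$vertices)
  # self-projection is the identity
  cube <- make_cube()
  self <- project_to_surface(cube, cube)
  expect_lt(max(abs(self$vertices - cube$vertices)), 1e-9)
  expect_error(project_to_surface(cube, trimesh(matrix(0, 1, 3),
                                                matrix(integer(0), 0, 3))),
               class = "knee_mesh_error")
})

test_that("length-mass-fat factors follow the fat-free-mass convention", {
  g <- list(mass = 75, length = 0.4, fat = 0.2)
  expect_equal(unclass(length_mass_fat_factors(g, g)),
               list(longitudinal = 1, radial = 1, strength = 1))
  s <- list(mass = 150, length = 0.4, fat = 0.2)
  f <- length_mass_fat_factors(s, g)
  expect_equal(f$radial, sqrt(2))
  expect_equal(f$strength, 2)
  s2 <- list(mass = 75, length = 0.44, fat = 0.2)
  f2 <- length_mass_fat_factors(s2, g)
  expect_equal(f2$longitudinal, 1.1)
  expect_equal(f2$radial, 1 / sqrt(1.1))
  expect_error(length_mass_fat_factors(list(mass = -1, length = 0.4, fat = 0), g),
               class = "knee_domain_error")
})
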