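# Shared builders for small programmatic fixtures. Everything is generated
# in code; no binary fixtures exist anywhere in the package.

# a unit cube as 12 outward-oriented triangles
make_cube <- function(scale = 1) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * scale
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f, "cube")
}

# square plate z = const on [0, w]^2, triangulated at spacing h, normals
# +z if up else -z
make_plate <- function(w = 10, h = 0.5, z = 0, up = TRUE, label = "plate",
                       compartment = "none") {
  g <- expand.grid(x = seq(0, w, h), y = seq(0, w, h))
  nx <- length(seq(0, w, h))
  ff <- NULL
  for (i in 1:(nx - 1)) for (j in 1:(nx - 1)) {
    a <- (j - 1) * nx + i; b <- a + 1; cc <- a + nx; d <- cc + 1
    ff <- rbind(ff, c(a, b, d), c(a, d, cc))
  }
  m <- trimesh(cbind(g$x, g$y, z), ff, label, compartment)
  fn <- kneefdk:::face_normals(m)
  bad <- if (up) fn[, 3] < 0 else fn[, 3] > 0
  m$faces[bad, 2:3] <- m$faces[bad, 3:2, drop = FALSE]
  m
}

# downward-facing spherical cap (lower part of a sphere), outward normals
make_sphere_cap <- function(R = 20, center = c(5, 5, 20), half_angle = pi / 3,
                            nt = 24, np = 36, label = "sphere") {
  kneefdk:::sphere_cap_mesh(center, R, c(0, 0, -1), half_angle, nt, np, label)
}

# 1-DOF toy: a single linear spring along z between femur and tibia;
# only the axial tibiofemoral translation (alpha 5) is active
make_spring_model <- function(k = 100, L0 = 100) {
  knee_model(springs = list(list(body_a = "femur", point_a = c(0, 0, L0 / 2),
                                 body_b = "tibia", point_b = c(0, 0, -L0 / 2),
                                 k = k, L0 = L0)),
             active_dofs = 5)
}

# elastic-only model with a few ligaments and springs in general position
make_elastic_model <- function(seed = 42) {
  set.seed(seed)
  att <- data.frame(
    bundle = c("aACL", "pACL", "aPCL"),
    origin_body = "femur",
    ox = runif(3, -20, 20), oy = runif(3, -20, 20), oz = runif(3, 10, 40),
    insertion_body = c("tibia", "tibia", "patella"),
    ix = runif(3, -20, 20), iy = runif(3, -20, 20), iz = runif(3, -45, -15),
    stringsAsFactors = FALSE)
  tab <- default_bundle_table()[1:3, ]
  tab$eps_r <- c(0.04, -0.05, 0.02)  # mix of taut and slack at reference
  ligs <- build_ligament_bundles(tab, att)
  sprs <- list(list(body_a = "femur", point_a = c(10, 5, 30),
                    body_b = "tibia", point_b = c(-5, 8, -30), k = 15, L0 = 55),
               list(body_a = "tibia", point_a = c(0, -10, -20),
                    body_b = "patella", point_b = c(25, 0, 5), k = 8, L0 = 40))
  knee_model(ligaments = ligs, springs = sprs)
}

# central finite difference of a scalar function of the alpha vector
fd_gradient <- function(fun, alpha, h = 1e-4) {
  vapply(seq_along(alpha), function(j) {
    ap <- alpha; ap[j] <- ap[j] + h
    am <- alpha; am[j] <- am[j] - h
    (fun(ap) - fun(am)) / (2 * h)
  }, 0)
}

# brute-force grid search oracle for <=3-muscle recruitment problems with a
# single equality constraint row eliminated by substitution
grid_search_recruitment <- function(C, r, N, V, n_grid = 120) {
  n <- ncol(C)
  stopifnot(nrow(C) == 1, n <= 3)
  obj <- function(f) sum(V * (f / N)^3)
  best <- NULL
  ub <- 3 * abs(r) / pmax(abs(C), 1e-12)
  if (n == 2) {
    f1 <- seq(0, ub[1], length.out = n_grid)
    f2 <- (r - C[1] * f1) / C[2]
    ok <- f2 >= 0
    if (!any(ok)) return(NULL)
    vals <- obj(rbind(f1, f2))
    vals <- V[1] * (f1 / N[1])^3 + V[2] * (f2 / N[2])^3
    vals[!ok] <- Inf
    i <- which.min(vals)
    best <- list(f = c(f1[i], f2[i]), objective = vals[i])
  } else {
    f1 <- seq(0, ub[1], length.out = n_grid)
    f2 <- seq(0, ub[2], length.out = n_grid)
    gg <- expand.grid(f1 = f1, f2 = f2)
    f3 <- (r - C[1] * gg$f1 - C[2] * gg$f2) / C[3]
    ok <- f3 >= 0
    vals <- V[1] * (gg$f1 / N[1])^3 + V[2] * (gg$f2 / N[2])^3 +
      V[3] * (pmax(f3, 0) / N[3])^3
    vals[!ok] <- Inf
    i <- which.min(vals)
    best <- list(f = c(gg$f1[i], gg$f2[i], f3[i]), objective = vals[i])
  }
  best
}

coarse_params <- function(...) knee_fixture_params(density = 0.7, ...)
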