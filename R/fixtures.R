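# Seeded synthetic fixtures: parametric knee geometry with ligament and
# muscle attachments, five daily-activity motion/ground-reaction profiles,
# virtual marker trajectories, and pseudo-reference curves for metric
# testing. These stand in for the MRI-derived geometry and the motion-lab
# recordings of a real study, which are not deposited anywhere; they are a
# stated world, not a fit to any subject.
#
# Frame convention (reference pose = full knee extension): knee center at
# the origin, x anterior, y medial, z superior; femur above, tibia below;
# all body frames coincide with this frame at reference. The femoral
# condyles are spheres centered on the transepicondylar (y) axis, so
# flexion about that axis leaves the tibiofemoral contact geometry
# invariant -- a deliberately benign, controllable geometry.

#' Knee fixture parameters
#'
#' Defaults describe an average adult knee: condylar radii 22/21 mm
#' (medial/lateral), condyle centers 22 mm off the midline, a 35 mm dish
#' radius for the tibial plateau, and the study-cohort mean subject
#' (73.4 kg, 1.78 m).
#'
#' @param medial_radius,lateral_radius condylar sphere radii (mm).
#' @param condyle_offset condyle center distance from midline (mm).
#' @param dish_radius tibial plateau dish curvature radius (mm).
#' @param plateau_gap initial cartilage clearance at reference (mm).
#' @param meniscus_gap meniscus clearance below the condyle (mm).
#' @param patella_gap patellar cartilage clearance (mm).
#' @param cart_r tibial cartilage patch radius (mm).
#' @param mass,height subject mass (kg) and height (m).
#' @param seed integer seed fixing all fixture randomness.
#' @param density mesh density multiplier (1 = default).
#' @return a `KneeFixtureParams` list.
#' @export
knee_fixture_params <- function(medial_radius = 22, lateral_radius = 21,
                                condyle_offset = 22, dish_radius = 35,
                                plateau_gap = 0.2, meniscus_gap = 0.3,
                                patella_gap = 0.3, cart_r = 16,
                                mass = 73.4, height = 1.78,
                                seed = 1, density = 1) {
  p <- list(medial_radius = medial_radius, lateral_radius = lateral_radius,
            condyle_offset = condyle_offset, dish_radius = dish_radius,
            plateau_gap = plateau_gap, meniscus_gap = meniscus_gap,
            patella_gap = patella_gap, cart_r = cart_r,
            mass = mass, height = height, seed = seed, density = density)
  if (any(unlist(p[1:8]) <= 0) || mass <= 0 || height <= 0)
    knee_stop("fixture geometric parameters must be positive", "knee_parameter_error")
  if (cart_r >= min(medial_radius, lateral_radius))
    knee_stop("cartilage patch radius must be below the condylar radius",
              "knee_parameter_error")
  class(p) <- "KneeFixtureParams"
  p
}

# ---- primitive surface builders -------------------------------------------

# polar disc z = zfun(r, phi), normals +z
disc_mesh <- function(cx, cy, r_out, nr, na, zfun, label, compartment) {
  ang <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  verts <- matrix(c(cx, cy, zfun(0, 0)), 1, 3)
  for (i in seq_len(nr)) {
    r <- r_out * i / nr
    verts <- rbind(verts, cbind(cx + r * cos(ang), cy + r * sin(ang),
                                zfun(r, ang)))
  }
  idx <- function(i, j) 1 + (i - 1) * na + ((j - 1) %% na) + 1  # ring i, seg j
  faces <- NULL
  for (j in seq_len(na)) faces <- rbind(faces, c(1, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(nr - 1)) for (j in seq_len(na)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    faces <- rbind(faces, c(a, cc, d), c(a, d, b))
  }
  trimesh(verts, faces, label = label, compartment = compartment)
}

# annulus r_in..r_out, z = zfun(r, phi), normals +z
annulus_mesh <- function(cx, cy, r_in, r_out, nr, na, zfun, label, compartment) {
  ang <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  verts <- NULL
  for (i in 0:nr) {
    r <- r_in + (r_out - r_in) * i / nr
    verts <- rbind(verts, cbind(cx + r * cos(ang), cy + r * sin(ang),
                                zfun(r, ang)))
  }
  idx <- function(i, j) i * na + ((j - 1) %% na) + 1
  faces <- NULL
  for (i in 0:(nr - 1)) for (j in seq_len(na)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    faces <- rbind(faces, c(a, cc, d), c(a, d, b))
  }
  trimesh(verts, faces, label = label, compartment = compartment)
}

# spherical patch of radius R about `center`, covering polar angle
# [0, half_angle] around unit `axis`; normals outward (away from center)
# unless inward = TRUE.
sphere_cap_mesh <- function(center, R, axis, half_angle, nt, np, label,
                            compartment = "none", inward = FALSE) {
  axis <- axis / sqrt(sum(axis^2))
  seed <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- seed - sum(seed * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  th <- half_angle * seq_len(nt) / nt
  ph <- seq(0, 2 * pi, length.out = np + 1)[-(np + 1)]
  verts <- matrix(center + R * axis, 1, 3, byrow = TRUE)
  for (t in th) {
    d <- outer(rep(cos(t), np), axis) +
      sin(t) * (outer(cos(ph), e1) + outer(sin(ph), e2))
    verts <- rbind(verts, sweep(R * d, 2, -center))
  }
  idx <- function(i, j) 1 + (i - 1) * np + ((j - 1) %% np) + 1
  faces <- NULL
  for (j in seq_len(np)) faces <- rbind(faces, c(1, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(nt - 1)) for (j in seq_len(np)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    faces <- rbind(faces, c(a, cc, d), c(a, d, b))
  }
  m <- trimesh(verts, faces, label = label, compartment = compartment)
  # orient per face: outward = normal away from the sphere center
  fn <- face_normals(m)
  cent <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
           m$vertices[m$faces[, 3], ]) / 3
  radial <- rowSums(fn * sweep(cent, 2, center))
  bad <- if (inward) radial > 0 else radial < 0
  m$faces[bad, 2:3] <- m$faces[bad, 3:2, drop = FALSE]
  m
}

# closed capped cylinder along z, outward normals (watertight)
cylinder_mesh <- function(cx, cy, radius, z0, z1, na, label) {
  ang <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  ring0 <- cbind(cx + radius * cos(ang), cy + radius * sin(ang), z0)
  ring1 <- cbind(cx + radius * cos(ang), cy + radius * sin(ang), z1)
  verts <- rbind(c(cx, cy, z0), ring0, ring1, c(cx, cy, z1))
  b <- function(j) 1 + ((j - 1) %% na) + 1
  t_ <- function(j) 1 + na + ((j - 1) %% na) + 1
  top <- 2 * na + 2
  faces <- NULL
  for (j in seq_len(na)) {
    faces <- rbind(faces,
                   c(1, b(j + 1), b(j)),                 # bottom cap (down)
                   c(b(j), b(j + 1), t_(j)), c(t_(j), b(j + 1), t_(j + 1)),
                   c(top, t_(j), t_(j + 1)))             # top cap (up)
  }
  trimesh(verts, faces, label = label)
}

# ---- knee geometry ---------------------------------------------------------

#' Generate the parametric knee geometry
#'
#' Builds nine surfaces -- femur/tibia/patella bone, femoral cartilage,
#' medial/lateral tibial cartilage, medial/lateral meniscus, patellar
#' cartilage -- plus the ligament attachment table, muscle table and joint
#' definition, all mutually consistent at the reference (full extension)
#' pose with the configured clearances (no initial penetration).
#'
#' @param params a [knee_fixture_params()] list.
#' @return a named list of `TriMesh` surfaces plus `attachments`,
#'   `muscle_table`, `joint`, and `params`.
#' @export
make_knee_geometry <- function(params = knee_fixture_params()) {
  Rm <- params$medial_radius; Rl <- params$lateral_radius
  oy <- params$condyle_offset; Rd <- params$dish_radius
  dz <- params$density
  cm <- c(0, oy, 0); cl <- c(0, -oy, 0)

  # femoral cartilage: two spherical patches around a down-forward axis so
  # both the tibiofemoral (inferior) and patellofemoral (anterior) sectors
  # are covered
  # near-complete condylar spheres (170 deg half-angle): the tibiofemoral
  # contact direction sweeps 40 deg (extension) to ~130 deg (deep flexion)
  # off the cap axis, and the meniscus rim adds ~30 deg more; any slave ray
  # landing outside the master surface would make the contact force jump at
  # the cap edge, so the master must cover the whole articulating range
  cap_axis <- c(sin(deg2rad(40)), 0, -cos(deg2rad(40)))
  nt <- max(18, round(26 * dz)); np <- max(16, round(26 * dz))
  fem_med <- sphere_cap_mesh(cm, Rm, cap_axis, deg2rad(170), nt, np,
                             "femoral_cartilage", "medial")
  fem_lat <- sphere_cap_mesh(cl, Rl, cap_axis, deg2rad(170), nt, np,
                             "femoral_cartilage", "lateral")
  fem_cart <- merge_meshes(fem_med, fem_lat, label = "femoral_cartilage")

  # tibial cartilage dishes: lowest point sits plateau_gap below each sphere
  zm <- -Rm - params$plateau_gap
  zl <- -Rl - params$plateau_gap
  nr <- max(5, round(7 * dz)); na <- max(14, round(22 * dz))
  dish <- function(z0) function(r, phi) z0 + r^2 / (2 * Rd)
  tib_med <- disc_mesh(0, oy, params$cart_r, nr, na, dish(zm),
                       "medial_tibial_cartilage", "medial")
  tib_lat <- disc_mesh(0, -oy, params$cart_r, nr, na, dish(zl),
                       "lateral_tibial_cartilage", "lateral")

  # menisci: annular bands whose top surface tracks the condylar sphere at
  # a clearance, fixed to the tibia
  # conformal to the condylar sphere up to r_t, then flat: the outer band
  # falls away from the sphere so no slave normal ever meets the master at
  # grazing incidence (which would make ray-cast depth discontinuous)
  men_top <- function(R) {
    force(R)
    r_t <- 12
    function(r, phi) -sqrt(pmax(R^2 - pmin(r, r_t)^2, 1)) - params$meniscus_gap
  }
  men_med <- annulus_mesh(0, oy, 9, params$cart_r + 0.5, max(3, round(4 * dz)),
                          na, men_top(Rm), "medial_meniscus", "medial")
  men_lat <- annulus_mesh(0, -oy, 9, params$cart_r + 0.5, max(3, round(4 * dz)),
                          na, men_top(Rl), "lateral_meniscus", "lateral")

  # patellar cartilage: two concave patches facing the condylar flanks
  pat_med <- sphere_cap_mesh(cm, Rm + params$patella_gap, cap_axis_pat(),
                             deg2rad(20), max(5, round(6 * dz)),
                             max(10, round(14 * dz)),
                             "patellar_cartilage", "medial", inward = TRUE)
  pat_lat <- sphere_cap_mesh(cl, Rl + params$patella_gap, cap_axis_pat(),
                             deg2rad(20), max(5, round(6 * dz)),
                             max(10, round(14 * dz)),
                             "patellar_cartilage", "lateral", inward = TRUE)
  pat_cart <- merge_meshes(pat_med, pat_lat, label = "patellar_cartilage")

  femur_bone <- cylinder_mesh(5, 0, 16, 10, 140, max(12, round(16 * dz)), "femur")
  tibia_bone <- cylinder_mesh(-2, 0, 16, -160, -26, max(12, round(16 * dz)), "tibia")
  patella_bone <- cylinder_mesh(0, 0, 12, 24.5, 32, max(10, round(12 * dz)), "patella")

  att <- default_ligament_attachments(params)
  mt <- default_muscle_table()
  joint <- knee_joint_definition(
    knee_center = c(0, 0, 0),
    pt_insertion_tibia = c(30, 0, -45),
    pt_origin_patella = patellar_pole(params, "inferior"))
  list(femur = femur_bone, tibia = tibia_bone, patella = patella_bone,
       femoral_cartilage = fem_cart,
       medial_tibial_cartilage = tib_med, lateral_tibial_cartilage = tib_lat,
       medial_meniscus = men_med, lateral_meniscus = men_lat,
       patellar_cartilage = pat_cart,
       attachments = att, muscle_table = mt, joint = joint, params = params)
}

cap_axis_pat <- function() {
  b <- deg2rad(20)  # anterior, slightly superior: where the patella rides
  c(cos(b), 0, sin(b))
}

patellar_center <- function(params) {
  a <- cap_axis_pat()
  (max(params$medial_radius, params$lateral_radius) + 6) * a
}

patellar_pole <- function(params, which = "inferior") {
  pc <- patellar_center(params)
  pc + switch(which,
              inferior = c(2, 0, -14), superior = c(0, 0, 14),
              medial = c(0, 12, 0), lateral = c(0, -12, 0))
}

merge_meshes <- function(a, b, label = a$label) {
  off <- nrow(a$vertices)
  trimesh(rbind(a$vertices, b$vertices), rbind(a$faces, b$faces + off),
          label = label, compartment = c(a$compartment, b$compartment))
}

#' Default ligament attachment table for the fixture knee
#'
#' Plausible anatomical positions on the parametric surfaces (body-local
#' mm, bodies' frames = reference global frame). These are fixture data,
#' not a reproduction of any cadaveric digitization.
#'
#' @param params a [knee_fixture_params()] list.
#' @return data.frame: `bundle`, `origin_body`, `ox,oy,oz`,
#'   `insertion_body`, `ix,iy,iz`.
#' @export
default_ligament_attachments <- function(params = knee_fixture_params()) {
  ye <- params$condyle_offset + max(params$medial_radius, params$lateral_radius)  # epicondyle
  pcm <- patellar_pole(params, "medial")
  pcl_ <- patellar_pole(params, "lateral")
  A <- function(bundle, ob, o, ib, i)
    data.frame(bundle = bundle, origin_body = ob,
               ox = o[1], oy = o[2], oz = o[3],
               insertion_body = ib, ix = i[1], iy = i[2], iz = i[3],
               stringsAsFactors = FALSE)
  rbind(
    A("aACL", "femur", c(-6, -8, 4), "tibia", c(10, 2, -23)),
    A("pACL", "femur", c(-9, -8, 7), "tibia", c(5, 4, -23)),
    A("aPCL", "femur", c(-4, 8, 2), "tibia", c(-26, 2, -30)),
    A("pPCL", "femur", c(-7, 6, 6), "tibia", c(-24, -2, -33)),
    A("aLCL", "femur", c(3, -ye, 2), "tibia", c(-4, -40, -52)),
    A("mLCL", "femur", c(0, -ye, 0), "tibia", c(-7, -40, -52)),
    A("pLCL", "femur", c(-4, -ye, 2), "tibia", c(-10, -40, -52)),
    A("aMCL", "femur", c(4, ye, 2), "tibia", c(8, 38, -62)),
    A("mMCL", "femur", c(0, ye, 0), "tibia", c(2, 39, -64)),
    A("pMCL", "femur", c(-4, ye, 2), "tibia", c(-5, 38, -62)),
    A("aDMCL", "femur", c(2, ye - 2, -2), "tibia", c(4, 40, -28)),
    A("pDMCL", "femur", c(-3, ye - 2, -2), "tibia", c(-5, 40, -28)),
    # patellofemoral ligament femoral attachments sit on the epicondyles,
    # i.e. essentially on the transepicondylar (flexion) axis, which makes
    # them near-isometric through the flexion range
    A("sMPFL", "femur", c(0, ye, 1), "patella", pcm + c(0, 0, 6)),
    A("mMPFL", "femur", c(0, ye, 0), "patella", pcm),
    A("iMPFL", "femur", c(0, ye, -1), "patella", pcm + c(0, 0, -6)),
    A("sLPFL", "femur", c(0, -ye, 1), "patella", pcl_ + c(0, 0, 6)),
    A("mLPFL", "femur", c(0, -ye, 0), "patella", pcl_),
    A("iLPFL", "femur", c(0, -ye, -1), "patella", pcl_ + c(0, 0, -6)),
    A("PMC", "femur", c(-12, ye - 4, -2), "tibia", c(-20, 32, -24)),
    A("POL", "femur", c(-14, ye - 4, 0), "tibia", c(-24, 28, -26)),
    A("ALL", "femur", c(-2, -ye, -3), "tibia", c(6, -38, -26)),
    A("PFL", "femur", c(-6, -ye + 2, -4), "tibia", c(-14, -38, -54))
  )
}

#' Default reduced lower-limb muscle table
#'
#' Eight knee-spanning muscle-tendon units: four quadriceps heads acting on
#' the patella (and hence on the tibia through the rigid patellar tendon),
#' two hamstrings and the two gastrocnemius heads. Volumes (cm^3) and
#' optimum fiber lengths (cm) are literature-plausible adult values; this
#' is a deliberate reduction of a full-body muscle system and proximal
#' (pelvis) origins are fixed to the femur frame.
#'
#' @return data.frame: `name`, `Vol0`, `Lf0`, `V`, plus path point columns.
#' @export
default_muscle_table <- function() {
  data.frame(
    name = c("rectus_femoris", "vastus_lateralis", "vastus_medialis",
             "vastus_intermedius", "semimembranosus", "biceps_femoris",
             "gastrocnemius_med", "gastrocnemius_lat"),
    Vol0 = c(270, 830, 430, 270, 480, 270, 310, 140),
    Lf0  = c(7.6, 9.9, 9.7, 9.9, 8.0, 9.8, 5.1, 5.7),
    V    = 1,
    o_body = c("femur", "femur", "femur", "femur", "femur", "femur", "femur", "femur"),
    ox = c(18, 14, 14, 16, -26, -26, -22, -22),
    oy = c(0, -16, 16, 0, 16, -20, 12, -12),
    oz = c(120, 90, 85, 95, 95, 95, -2, -2),
    i_body = c("patella", "patella", "patella", "patella", "tibia", "tibia",
               "tibia", "tibia"),
    ix = c(0, 0, 0, 0, -22, -18, -28, -28),
    iy = c(0, -9, 9, 0, 20, -26, 8, -8),
    iz = c(14, 12, 12, 14, -56, -52, -200, -200),
    stringsAsFactors = FALSE)
}

build_muscles <- function(params, table = default_muscle_table()) {
  pc <- patellar_center(params)
  lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    ins <- c(r$ix, r$iy, r$iz)
    # patellar insertions in the table are offsets from the patellar center
    if (r$i_body == "patella") ins <- pc + ins
    muscle_unit(r$name, r$Vol0, r$Lf0,
                data.frame(body = c(r$o_body, r$i_body),
                           x = c(r$ox, ins[1]), y = c(r$oy, ins[2]),
                           z = c(r$oz, ins[3])),
                V = r$V)
  })
}

#' Assemble the complete default knee model
#'
#' Geometry, 22 calibrated ligament bundles, 8 muscles, 5 contact pairs and
#' the joint definition in one call.
#'
#' @param params a [knee_fixture_params()] list.
#' @param eps_l linear strain limit for all bundles.
#' @return a `KneeModel`.
#' @export
build_knee_model <- function(params = knee_fixture_params(), eps_l = 0.03) {
  geo <- make_knee_geometry(params)
  ligs <- build_ligament_bundles(default_bundle_table(eps_l), geo$attachments)
  muscles <- build_muscles(params)
  contacts <- build_default_pairs(geo)
  knee_model(geometry = geo, joint = geo$joint, ligaments = ligs,
             muscles = muscles, contacts = contacts,
             subject = list(mass = params$mass, height = params$height))
}

# ---- activity profiles -----------------------------------------------------

ACTIVITIES <- c("walk", "stair_ascent", "stair_descent", "sit_to_stand",
                "stand_to_sit")

# periodic gaussian bump on p in [0,1)
pbump <- function(p, c0, w) {
  exp(-((p - c0)^2) / (2 * w^2)) + exp(-((p - c0 - 1)^2) / (2 * w^2)) +
    exp(-((p - c0 + 1)^2) / (2 * w^2))
}

sigm <- function(x) 1 / (1 + exp(-x))

# Each activity states flexion (deg), shank inclination (deg, positive =
# ankle anterior of the knee, as at heel strike), a single-leg vertical GRF
# shape (rescaled to a half-body-weight cycle mean downstream), and the
# ground-reaction lever waveforms about the knee: levy (mm, sagittal;
# negative = external flexion moment demanding knee extensors) and levx
# (mm, frontal; negative = external adduction moment loading the medial
# compartment). The center of pressure is then placed by inverting the
# moment balance, so the stated levers are what the inverse-dynamics stage
# reproduces -- knee moment patterns are the standard gait descriptor.
activity_waveforms <- function(activity, p) {
  switch(activity,
    walk = list(
      flexion = 4 + 16 * pbump(p, 0.14, 0.09) + 58 * pbump(p, 0.72, 0.10),
      shank = 18 * cos(2 * pi * p + 0.55) - 4,
      grf_shape = ifelse(p <= 0.60,
                         1.15 * pbump(p, 0.15, 0.065) + 1.10 * pbump(p, 0.45, 0.065) +
                           0.40 * pbump(p, 0.30, 0.10), 0) *
        sigm((p + 0.005) / 0.012) * sigm((0.60 - p) / 0.012),
      levy = -(42 * pbump(p, 0.16, 0.075) + 12 * pbump(p, 0.30, 0.10) +
               36 * pbump(p, 0.455, 0.07)) + 18 * pbump(p, 0.57, 0.045),
      levx = -16, stance_end = 0.60),
    stair_ascent = list(
      flexion = 10 + 85 * pbump(p, 1.0, 0.18),
      shank = -5 - 2 * cos(2 * pi * p),
      grf_shape = ifelse(p <= 0.64,
                         1.10 * pbump(p, 0.16, 0.08) + 1.05 * pbump(p, 0.48, 0.08) +
                           0.60 * pbump(p, 0.32, 0.11), 0) *
        sigm((p + 0.005) / 0.015) * sigm((0.64 - p) / 0.015),
      levy = -(62 * pbump(p, 0.17, 0.10) + 22 * pbump(p, 0.48, 0.10)),
      levx = -16, stance_end = 0.64),
    stair_descent = list(
      flexion = 10 + 30 * pbump(p, 0.30, 0.12) + 88 * pbump(p, 0.78, 0.11),
      shank = 10 * cos(2 * pi * p) - 6,
      grf_shape = ifelse(p <= 0.62,
                         1.05 * pbump(p, 0.12, 0.07) + 1.25 * pbump(p, 0.50, 0.07) +
                           0.55 * pbump(p, 0.30, 0.11), 0) *
        sigm((p + 0.005) / 0.015) * sigm((0.62 - p) / 0.015),
      levy = -(26 * pbump(p, 0.12, 0.08) + 68 * pbump(p, 0.50, 0.08)),
      levx = -17, stance_end = 0.62),
    sit_to_stand = list(
      flexion = 88 - 86 * sigm((p - 0.48) / 0.14),
      shank = -16 + 11 * p,
      grf_shape = 1 + 0.35 * pbump(p, 0.35, 0.12) - 0.20 * pbump(p, 0.70, 0.10),
      levy = -(30 + 65 * pbump(p, 0.33, 0.16)), levx = -13, stance_end = 1),
    stand_to_sit = list(
      flexion = 2 + 86 * sigm((p - 0.52) / 0.14),
      shank = -5 - 11 * p,
      grf_shape = 1 + 0.30 * pbump(p, 0.60, 0.12) - 0.15 * pbump(p, 0.25, 0.10),
      levy = -(30 + 60 * pbump(p, 0.68, 0.16)), levx = -13, stance_end = 1),
    knee_stop(paste("unknown activity:", activity), "knee_domain_error"))
}

activity_duration <- function(activity) {
  c(walk = 1.10, stair_ascent = 1.40, stair_descent = 1.30,
    sit_to_stand = 1.80, stand_to_sit = 1.90)[[activity]]
}

#' Generate a synthetic activity trial
#'
#' Produces the ground-truth flexion profile, a two-feet-consistent ground
#' reaction force record (vertical impulse over the cycle equals body
#' weight x duration), the intersegmental knee load expressed in the
#' knee-construct frame, and noisy virtual marker trajectories for the
#' femur and tibia clusters.
#'
#' The single-leg vertical GRF shape is rescaled so its cycle mean is
#' exactly half body weight (walking and stairs; the contralateral leg
#' carries the mirrored half-cycle) or uses the seat/two-leg split for the
#' transfers.
#'
#' @param activity one of `"walk"`, `"stair_ascent"`, `"stair_descent"`,
#'   `"sit_to_stand"`, `"stand_to_sit"`.
#' @param params a [knee_fixture_params()] list.
#' @param seed integer seed (markers' noise).
#' @param n_frames number of simulation frames over the cycle.
#' @param noise_sd marker noise (mm, isotropic Gaussian).
#' @param quasi_static drop inertial terms in the intersegmental load.
#' @return a trial list: `activity`, `frames` (time, flexion, fx..mz),
#'   `grf` (1000 Hz table), `markers`, `duration`, `seed`.
#' @export
make_activity_trial <- function(activity, params = knee_fixture_params(),
                                seed = params$seed, n_frames = 101,
                                noise_sd = 1, quasi_static = TRUE) {
  if (!activity %in% ACTIVITIES)
    knee_stop(paste("unknown activity:", activity), "knee_domain_error")
  dur <- activity_duration(activity)
  bw <- params$mass * 9.81
  leg <- 0.245 * params$height * 1000       # thigh length (mm)
  shank <- 0.246 * params$height * 1000
  hip <- c(0, 0, 0)                          # lab frame anchored at the hip

  kin_at <- function(tt) {
    p <- tt / dur
    wf <- activity_waveforms(activity, p)
    fl <- wf$flexion
    sh <- deg2rad(wf$shank)
    th <- sh + deg2rad(fl)                 # thigh = shank + knee flexion
    knee <- cbind(hip[1] + leg * sin(th), hip[2], hip[3] - leg * cos(th))
    ankle <- cbind(knee[, 1] + shank * sin(sh), knee[, 2], knee[, 3] - shank * cos(sh))
    list(p = p, wf = wf, flexion = fl, knee = knee, ankle = ankle,
         shank_angle = sh)
  }

  # GRF at 1000 Hz, scaled to the impulse-consistent level
  tg <- seq(0, dur, by = 0.001)
  kg <- kin_at(tg)
  shape <- kg$wf$grf_shape
  two_leg <- activity %in% c("sit_to_stand", "stand_to_sit")
  target_mean <- 0.5  # one leg carries half the body weight on cycle average
  fz <- pmax(shape, 0) * (target_mean / mean(pmax(shape, 0))) * bw
  fx <- (0.03 * (pbump(kg$p, 0.45, 0.07) - pbump(kg$p, 0.12, 0.06))) * bw *
    ifelse(shape > 0.02, 1, 0) * (!two_leg)
  # place the COP so that the moment balance reproduces the stated levers:
  # target knee moments m* = lev * fz, inverted for the COP offsets
  cop_z <- kg$ankle[, 3] - 0.039 * params$height * 1000
  m_ss0 <- 0.061 * params$mass
  com_g <- kg$knee + 0.6 * (kg$ankle - kg$knee)
  Gx <- (com_g[, 2] - kg$knee[, 2]) * (-m_ss0 * 9.81)   # (com-knee) x W, x comp
  Gy <- -(com_g[, 1] - kg$knee[, 1]) * (-m_ss0 * 9.81)
  rz <- cop_z - kg$knee[, 3]
  denom <- pmax(fz, 40)
  my_t <- kg$wf$levy * fz
  mx_t <- kg$wf$levx * fz
  cop_x <- kg$knee[, 1] + pmin(pmax((my_t + rz * fx + Gy) / denom, -250), 250)
  cop_y <- kg$knee[, 2] + pmin(pmax((-mx_t - Gx) / denom, -250), 250)
  grf <- data.frame(time = tg, fx = fx, fy = 0, fz = fz,
                    px = cop_x, py = cop_y, pz = cop_z)

  # intersegmental load at the simulation frames
  tf <- seq(0, dur, length.out = n_frames)
  kf <- kin_at(tf)
  com <- kf$knee + 0.6 * (kf$ankle - kf$knee)
  kin <- data.frame(time = tf, kx = kf$knee[, 1], ky = kf$knee[, 2],
                    kz = kf$knee[, 3], cx = com[, 1], cy = com[, 2],
                    cz = com[, 3])
  m_ss <- 0.061 * params$mass               # shank + foot
  load <- intersegmental_load(kin, grf, m_ss, quasi_static = quasi_static)
  # rotate the lab-frame load into the knee-construct frame: the construct
  # tibia axis is the lab shank axis, the construct y axis the flexion axis
  frames <- data.frame(time = tf, flexion = kf$flexion,
                       fx = 0, fy = 0, fz = 0, mx = 0, my = 0, mz = 0)
  for (i in seq_len(n_frames)) {
    sh <- kf$shank_angle[i]
    # lab -> shank frame (planar): shank z up along shank, x anterior
    Rl <- matrix(c(cos(sh), 0, -sin(sh), 0, 1, 0, sin(sh), 0, cos(sh)), 3, 3)
    f_local <- as.numeric(t(Rl) %*% load$force[i, ])
    m_local <- as.numeric(t(Rl) %*% load$moment[i, ])
    Rc <- rot_y(kf$flexion[i])               # construct tibia orientation
    frames[i, c("fx", "fy", "fz")] <- as.numeric(Rc %*% f_local)
    frames[i, c("mx", "my", "mz")] <- as.numeric(Rc %*% m_local)
  }

  # virtual markers in the construct frame: femur cluster fixed, tibia
  # cluster follows the ground-truth flexion (alpha = 0)
  fem_local <- rbind(c(20, 45, 60), c(-25, 40, 90), c(10, -48, 70), c(-15, -42, 110))
  tib_local <- rbind(c(25, 38, -60), c(-20, 42, -90), c(15, -40, -75), c(-22, -35, -110))
  mm_fem <- marker_model(paste0("FEM", 1:4), fem_local)
  mm_tib <- marker_model(paste0("TIB", 1:4), tib_local)
  set.seed(seed %% .Machine$integer.max)
  obs_tib <- array(0, c(n_frames, 4, 3))
  obs_fem <- array(0, c(n_frames, 4, 3))
  for (i in seq_len(n_frames)) {
    st <- knee_state(kf$flexion[i])
    pt <- knee_pose_from_dofs(st)$femur_tibia
    obs_tib[i, , ] <- pose_apply(pt, tib_local) +
      matrix(rnorm(12, 0, noise_sd), 4, 3)
    obs_fem[i, , ] <- fem_local + matrix(rnorm(12, 0, noise_sd), 4, 3)
  }
  list(activity = activity, frames = frames, grf = grf, duration = dur,
       markers = list(model_femur = mm_fem, model_tibia = mm_tib,
                      observed_femur = obs_fem, observed_tibia = obs_tib,
                      noise_sd = noise_sd),
       seed = seed, quasi_static = quasi_static, bw = bw)
}

#' Recover the flexion profile from the trial's virtual markers
#'
#' The marker-tracking closed loop: fits femur and tibia poses per frame by
#' least squares and reads the flexion angle off the relative pose.
#'
#' @param trial a trial from [make_activity_trial()].
#' @return numeric flexion profile (deg), one value per frame.
#' @export
flexion_from_markers <- function(trial) {
  mk <- trial$markers
  n <- dim(mk$observed_tibia)[1]
  out <- numeric(n)
  for (i in seq_len(n)) {
    of <- mk$observed_femur[i, , ]
    rownames(of) <- mk$model_femur$names
    ot <- mk$observed_tibia[i, , ]
    rownames(ot) <- mk$model_tibia$names
    pf <- pose_from_markers(mk$model_femur, of)$pose
    pt <- pose_from_markers(mk$model_tibia, ot)$pose
    rel <- pose_compose(pose_inverse(pf), pt)
    st <- dofs_from_knee_pose(list(femur_tibia = rel,
                                   tibia_patella = pose_identity()))
    out[i] <- st$tf_flexion
  }
  out
}

#' Distorted pseudo-reference curve for metric testing
#'
#' Builds a stand-in for an external measured curve by distorting a
#' predicted curve: the reference is the curve divided by `(1 + amplitude)`,
#' circularly shifted by `shift` percent of the cycle, plus Gaussian noise.
#' With zero noise the Sprague-Geers magnitude error of
#' (predicted, reference) is exactly `amplitude`, and for sinusoidal
#' content the phase error is the shift expressed as a fraction of pi.
#'
#' @param curve a `Curve` or numeric length-101 vector (the prediction).
#' @param amplitude fractional amplitude distortion `a`.
#' @param shift phase shift in percent of cycle.
#' @param noise_sd additive noise SD (curve units).
#' @param seed integer seed for the noise.
#' @return a `Curve`.
#' @export
make_pseudo_reference <- function(curve, amplitude = 0, shift = 0,
                                  noise_sd = 0, seed = 1) {
  v <- curve_values(curve)
  n <- length(v)
  pc <- seq(0, 100, length.out = n)
  if (shift != 0) {
    # circular shift by interpolation on the periodic extension
    src <- (pc - shift) %% 100
    v <- approx(c(pc, 100 + pc[-1]), c(v, v[-1]), pmin(src, 100), rule = 2)$y
  }
  v <- v / (1 + amplitude)
  if (noise_sd > 0) {
    set.seed(seed %% .Machine$integer.max)
    v <- v + rnorm(n, 0, noise_sd)
  }
  structure(list(percent = pc, value = v, activity = "pseudo_reference"),
            class = "Curve")
}

#' Least-squares sphere fit (algebraic)
#' @param pts n x 3 matrix of surface points.
#' @return list with `center` and `radius`.
#' @export
fit_sphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  x <- qr.coef(qr(A), b)
  center <- x[1:3]
  list(center = center, radius = sqrt(x[4] + sum(center^2)))
}

#' Write fixture files (STL, marker/GRF text, model config JSON)
#'
#' @param dir output directory (created).
#' @param activity activity label.
#' @param params fixture parameters.
#' @param seed seed for trial noise.
#' @return invisibly, the directory.
#' @export
generate_fixture_files <- function(dir, activity = "walk",
                                   params = knee_fixture_params(), seed = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geo <- make_knee_geometry(params)
  for (nm in c("femur", "tibia", "patella", "femoral_cartilage",
               "medial_tibial_cartilage", "lateral_tibial_cartilage",
               "medial_meniscus", "lateral_meniscus", "patellar_cartilage"))
    write_stl(geo[[nm]], file.path(dir, paste0(nm, ".stl")))
  trial <- make_activity_trial(activity, params, seed = seed)
  write.table(trial$grf, file.path(dir, "grf.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(trial$frames, file.path(dir, "frames.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- list(params = unclass(params), activity = activity, seed = seed,
              ligaments = default_bundle_table(),
              attachments = default_ligament_attachments(params),
              muscles = default_muscle_table(),
              materials = lapply(default_material_table(), unclass))
  jsonlite::write_json(cfg, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Load a model config JSON and validate the ligament schema
#'
#' @param path path to a `model.json` written by
#'   [generate_fixture_files()].
#' @return a `KneeModel`.
#' @export
load_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- default_bundle_table()
  lig <- cfg$ligaments
  if (!setequal(lig$bundle, ref$bundle) || nrow(lig) != 22)
    knee_stop("ligament table must contain exactly the 22 default bundles",
              "knee_config_error")
  params <- do.call(knee_fixture_params, cfg$params[names(cfg$params) %in%
    names(formals(knee_fixture_params))])
  geo <- make_knee_geometry(params)
  ligs <- build_ligament_bundles(lig, cfg$attachments)
  knee_model(geometry = geo, joint = geo$joint, ligaments = ligs,
             muscles = build_muscles(params, cfg$muscles),
             contacts = build_default_pairs(geo),
             subject = list(mass = params$mass, height = params$height))
}
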