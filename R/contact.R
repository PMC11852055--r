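# Elastic-foundation contact between triangulated tissue surfaces.
#
# The cartilage/meniscus layer pair is treated as a bed of independent
# springs. For slave vertex i with tributary area A_i penetrating the
# master surface to depth d_i, the compressive force is
#   F_i = PM * A_i * d_i          (linear force-penetration-volume law)
# directed along the slave vertex normal, where the pressure module PM
# combines both layers:
#   PM = [ g(v1) h1 / E1 + g(v2) h2 / E2 ]^-1,  g(v) = (1+v)(1-2v)/(1-v).
#
# Penetration is detected by casting a ray from each slave vertex along the
# inward (-normal) direction against the master triangulation; a hit on a
# facing triangle at distance t means the vertex sits t beyond the master
# surface. Friction is not modeled; forces are normal and compressive only.

#' Elastic layer material
#' @param E elasticity modulus (MPa), > 0.
#' @param v Poisson's ratio in `[0, 0.5)`.
#' @param h average elastic layer thickness (mm), > 0.
#' @return a `Material`.
#' @export
material <- function(E, v, h) {
  if (E <= 0 || h <= 0 || v < 0 || v >= 0.5)
    knee_stop("need E > 0, h > 0, 0 <= v < 0.5 (v = 0.5 is incompressible)",
              "knee_material_error")
  structure(list(E = E, v = v, h = h), class = "Material")
}

#' Default contact material table
#'
#' Linear-elastic layer properties for the six articulating tissues:
#' Poisson's ratio, elasticity modulus (MPa) and average layer thickness
#' (mm).
#'
#' @return named list of `Material` objects.
#' @export
default_material_table <- function() {
  list(
    femoral_cartilage        = material(E = 5,  v = 0.46, h = 2.2),
    medial_tibial_cartilage  = material(E = 5,  v = 0.46, h = 2.1),
    lateral_tibial_cartilage = material(E = 5,  v = 0.46, h = 2.6),
    medial_meniscus          = material(E = 59, v = 0.49, h = 3.5),
    lateral_meniscus         = material(E = 59, v = 0.49, h = 3.2),
    patellar_cartilage       = material(E = 5,  v = 0.46, h = 3.3)
  )
}

#' Pressure module of a contacting layer pair
#'
#' Composite series stiffness per unit thickness of the two elastic layers;
#' symmetric in its arguments and homogeneous of degree one in the moduli.
#'
#' @param m1,m2 `Material` objects.
#' @return pressure module (MPa/mm).
#' @export
pressure_module <- function(m1, m2) {
  g <- function(m) (1 + m$v) * (1 - 2 * m$v) / (1 - m$v)
  1 / (g(m1) * m1$h / m1$E + g(m2) * m2$h / m2$E)
}

#' Contact pair
#'
#' The slave surface (tibial, meniscal or patellar side) carries the
#' vertices at which penetration and force are evaluated; the master
#' surface (femoral side, which participates in all five knee pairs) is the
#' ray-cast target.
#'
#' @param slave,master `TriMesh` surfaces.
#' @param slave_material,master_material `Material` objects.
#' @param name pair label.
#' @param slave_body,master_body body names the surfaces are attached to.
#' @param max_depth depth cutoff (mm): penetrations deeper than this are
#'   non-physical (ray hits are ignored beyond it; projected depths
#'   saturate at it).
#' @param method `"ray"` (default: ray cast along the inward slave vertex
#'   normal) or `"project"` (signed closest-point distance; continuous at
#'   grazing incidence, used for steep surfaces such as the meniscal rims).
#' @return a `ContactPair` with the pressure module bound.
#' @export
contact_pair <- function(slave, master, slave_material, master_material,
                         name = "pair", slave_body = "tibia",
                         master_body = "femur", max_depth = 6,
                         method = c("ray", "project")) {
  method <- match.arg(method)
  vert_comp <- rep("none", nrow(slave$vertices))
  for (comp in c("medial", "lateral")) {
    idx <- unique(as.vector(slave$faces[slave$compartment == comp, ]))
    vert_comp[idx] <- comp
  }
  structure(list(
    slave = slave, master = master,
    slave_material = slave_material, master_material = master_material,
    PM = pressure_module(slave_material, master_material),
    name = name, slave_body = slave_body, master_body = master_body,
    max_depth = max_depth, method = method,
    slave_areas = vertex_areas(slave),
    slave_normals = vertex_normals(slave),
    vert_comp = vert_comp), class = "ContactPair")
}

#' Per-vertex penetration depths and tributary areas
#'
#' @param pair a `ContactPair`.
#' @param pose_slave,pose_master body -> global `Pose`s of the two surfaces.
#' @return list with `depth` (mm, 0 where not in contact) and `area` (mm^2)
#'   per slave vertex.
#' @export
vertex_penetrations <- function(pair, pose_slave = pose_identity(),
                                pose_master = pose_identity()) {
  rel <- pose_compose(pose_inverse(pose_master), pose_slave)
  pts <- pose_apply(rel, pair$slave$vertices)
  d <- if (identical(pair$method, "project")) {
    cpp_signed_depths(pts, pair$master$vertices, pair$master$faces,
                      pair$max_depth)
  } else {
    dirs <- -(pair$slave_normals %*% t(rel$R))
    cpp_ray_depths(pts, dirs, pair$master$vertices, pair$master$faces,
                   pair$max_depth)
  }
  list(depth = as.numeric(d), area = pair$slave_areas)
}

#' Elastic-foundation contact forces for a pair
#'
#' @inheritParams vertex_penetrations
#' @return a `ContactResult`: per-vertex magnitudes, depths, areas and
#'   normals (global frame), resultant force on each body, and per-
#'   compartment resultants on the slave body.
#' @export
contact_forces <- function(pair, pose_slave = pose_identity(),
                           pose_master = pose_identity()) {
  pen <- vertex_penetrations(pair, pose_slave, pose_master)
  Fmag <- pair$PM * pen$area * pen$depth
  n_global <- pair$slave_normals %*% t(pose_slave$R)
  # compression pushes the slave body away from the master (against its
  # outward normal)
  f_slave <- -n_global * Fmag
  pts_global <- pose_apply(pose_slave, pair$slave$vertices)
  total_slave <- colSums(f_slave)
  by_comp <- lapply(c(medial = "medial", lateral = "lateral", none = "none"),
                    function(cc) {
                      sel <- pair$vert_comp == cc
                      colSums(f_slave[sel, , drop = FALSE])
                    })
  structure(list(
    name = pair$name,
    force_mag = Fmag, depth = pen$depth, area = pen$area,
    normal = n_global, points = pts_global,
    force_on_slave = total_slave,
    force_on_master = -total_slave,
    compartment = by_comp,
    n_contacting = sum(pen$depth > 0)), class = "ContactResult")
}

#' Build the five default knee contact pairs
#'
#' Medial/lateral tibial cartilage vs femoral cartilage, medial/lateral
#' meniscus vs femoral cartilage, patellar cartilage vs femoral cartilage.
#' Meniscus surfaces are fixed to the tibia (meniscal motion is neglected),
#' so all four tibial-side pairs load the tibia.
#'
#' @param geometry a knee geometry list as produced by
#'   [make_knee_geometry()] (elements `femoral_cartilage`,
#'   `medial_tibial_cartilage`, `lateral_tibial_cartilage`,
#'   `medial_meniscus`, `lateral_meniscus`, `patellar_cartilage`).
#' @param materials named list as [default_material_table()].
#' @return list of 5 `ContactPair` objects.
#' @export
build_default_pairs <- function(geometry, materials = default_material_table()) {
  need <- c("femoral_cartilage", "medial_tibial_cartilage",
            "lateral_tibial_cartilage", "medial_meniscus", "lateral_meniscus",
            "patellar_cartilage")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    knee_stop(paste("missing surfaces:", paste(miss, collapse = ", ")),
              "knee_config_error")
  fem <- geometry$femoral_cartilage
  fm <- materials$femoral_cartilage
  list(
    contact_pair(geometry$medial_tibial_cartilage, fem,
                 materials$medial_tibial_cartilage, fm,
                 name = "medial_tibial", slave_body = "tibia"),
    contact_pair(geometry$lateral_tibial_cartilage, fem,
                 materials$lateral_tibial_cartilage, fm,
                 name = "lateral_tibial", slave_body = "tibia"),
    contact_pair(geometry$medial_meniscus, fem,
                 materials$medial_meniscus, fm,
                 name = "medial_meniscus", slave_body = "tibia"),
    contact_pair(geometry$lateral_meniscus, fem,
                 materials$lateral_meniscus, fm,
                 name = "lateral_meniscus", slave_body = "tibia"),
    contact_pair(geometry$patellar_cartilage, fem,
                 materials$patellar_cartilage, fm,
                 name = "patellofemoral", slave_body = "patella")
  )
}
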