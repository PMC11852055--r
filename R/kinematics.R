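# Rigid-pose algebra, the 11-DOF knee parameterization and least-squares
# marker pose fitting (the marker-tracking stage of the pipeline).
#
# Conventions (documented, configurable through the joint definition):
#   x anterior, y medial, z superior; angles in degrees, right-handed.
#   Flexion is a positive rotation about the joint's +y (transepicondylar)
#   axis; rotation order is flexion -> ab/adduction -> internal rotation,
#   i.e. R = Ry(flex) %*% Rx(abad) %*% Rz(intext).
#   All body frames coincide with the global frame at the reference pose
#   (full extension), with the knee center at the origin.

#' Rigid pose
#' @param R proper orthogonal 3 x 3 rotation.
#' @param t length-3 translation (mm).
#' @return a `Pose`.
#' @export
pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    knee_stop("R must be proper orthogonal", "knee_pose_error")
  structure(list(R = R, t = as.numeric(t)), class = "Pose")
}

#' @rdname pose
#' @export
pose_identity <- function() pose()

#' Compose two poses: `(a %o% b)(x) = a(b(x))`
#' @param a,b `Pose` objects.
#' @return the composed `Pose`.
#' @export
pose_compose <- function(a, b) pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' Invert a pose
#' @param p a `Pose`.
#' @return the inverse `Pose`.
#' @export
pose_inverse <- function(p) pose(t(p$R), as.numeric(-t(p$R) %*% p$t))

#' Apply a pose to points
#' @param p a `Pose`.
#' @param pts n x 3 matrix or length-3 vector.
#' @return transformed points, same shape.
#' @export
pose_apply <- function(p, pts) {
  if (is.null(dim(pts))) return(as.numeric(p$R %*% pts) + p$t)
  sweep(pts %*% t(p$R), 2, -p$t)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Elementary rotations (angle in degrees)
#' @param deg angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(axis, rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(rad) * K + (1 - cos(rad)) * K %*% K
}

# ---- marker models and Kabsch fitting --------------------------------------

#' Rigid-body marker model
#' @param names marker names.
#' @param local n x 3 body-local marker positions (mm).
#' @param weights per-marker positive weights.
#' @return a `MarkerModel`.
#' @export
marker_model <- function(names, local, weights = rep(1, length(names))) {
  local <- as.matrix(local)
  if (length(names) < 3) knee_stop("need >= 3 markers", "knee_underdetermined_error")
  structure(list(names = as.character(names), local = local,
                 weights = as.numeric(weights)), class = "MarkerModel")
}

#' Least-squares rigid pose from observed markers
#'
#' Weighted orthogonal Procrustes (Kabsch) fit of the body pose minimizing
#' the weighted sum of squared distances between transformed model markers
#' and their observations.
#'
#' @param model a `MarkerModel`.
#' @param observed n x 3 matrix of global marker positions with rownames, or
#'   a named list; matched to the model by name. NA rows are dropped.
#' @return list with `pose` (body -> global) and `rms` (mm).
#' @export
pose_from_markers <- function(model, observed) {
  obs <- as.matrix(observed)
  nm <- rownames(obs) %||% model$names
  keep <- stats::complete.cases(obs)
  obs <- obs[keep, , drop = FALSE]
  nm <- nm[keep]
  idx <- match(nm, model$names)
  if (anyNA(idx)) knee_stop("observed marker names not in model", "knee_pairing_error")
  X <- model$local[idx, , drop = FALSE]
  w <- model$weights[idx]
  if (nrow(X) < 3) knee_stop("fewer than 3 observed markers", "knee_underdetermined_error")
  xb <- colSums(X * w) / sum(w)
  yb <- colSums(obs * w) / sum(w)
  Xc <- sweep(X, 2, xb)
  Yc <- sweep(obs, 2, yb)
  if (svd(Xc)$d[2] < 1e-9 * max(1, svd(Xc)$d[1]))
    knee_stop("markers are collinear: pose underdetermined", "knee_underdetermined_error")
  H <- t(Xc * w) %*% Yc
  s <- svd(H)
  D <- diag(c(1, 1, det(s$v %*% t(s$u))))
  R <- s$v %*% D %*% t(s$u)
  tt <- yb - as.numeric(R %*% xb)
  res <- sweep(X %*% t(R), 2, -tt) - obs
  rms <- sqrt(sum(w * rowSums(res^2)) / sum(w))
  list(pose = pose(R, tt), rms = rms)
}

# ---- knee DOF state --------------------------------------------------------

#' Knee degree-of-freedom state
#'
#' One driven coordinate (tibiofemoral flexion) plus 10 secondary
#' coordinates resolved by FDK: 5 tibiofemoral (ab/adduction deg, internal
#' rotation deg, and 3 translations mm) and 5 patellofemoral. The
#' patellofemoral coordinates parameterize the patella *through the rigid
#' patellar tendon*: two tangential displacements (mm) of the tendon
#' direction about its tibial insertion and 3 patellar rotations (deg), so
#' tendon length is constant by construction.
#'
#' @param tf_flexion driven flexion (deg).
#' @param tf_secondary length-5: `c(abad_deg, intext_deg, tx, ty, tz)` (mm).
#' @param pf_secondary length-5: `c(u_mm, v_mm, rx_deg, ry_deg, rz_deg)`.
#' @return a `KneeDofState`.
#' @export
knee_state <- function(tf_flexion = 0, tf_secondary = numeric(5),
                       pf_secondary = numeric(5)) {
  stopifnot(length(tf_secondary) == 5, length(pf_secondary) == 5)
  structure(list(tf_flexion = tf_flexion,
                 tf_secondary = as.numeric(tf_secondary),
                 pf_secondary = as.numeric(pf_secondary)),
            class = "KneeDofState")
}

#' @rdname knee_state
#' @param state a `KneeDofState`.
#' @return `state_to_alpha`: the 10 secondary coordinates as a vector.
#' @export
state_to_alpha <- function(state) c(state$tf_secondary, state$pf_secondary)

#' @rdname knee_state
#' @param alpha length-10 secondary coordinate vector.
#' @param flexion driven flexion (deg).
#' @export
alpha_to_state <- function(alpha, flexion) {
  knee_state(flexion, alpha[1:5], alpha[6:10])
}

#' Joint frame definition
#'
#' Fixes the axes and the patellar-tendon parameterization. Defaults place
#' the knee center at the origin with the flexion axis along +y
#' (transepicondylar line of the fixture geometry).
#'
#' @param knee_center reference knee center (global, mm).
#' @param pt_insertion_tibia patellar tendon insertion (tibia frame, mm).
#' @param pt_origin_patella tendon origin on the patella (patella frame, mm).
#' @param pt_length reference (rigid) tendon length (mm).
#' @param pt_direction unit tendon direction insertion -> patella at
#'   reference (tibia frame).
#' @param patellar_tracking fraction of the flexion angle by which the
#'   patella is expected to rotate back relative to the tibia while it
#'   tracks the femoral trochlea. Used only to seed the FDK search (see
#'   [tracked_patellar_alpha()]); the coordinates themselves stay
#'   tibia-relative so the quadriceps keep their full extensor moment arm
#'   in the recruitment equation. With the default concentric trochlea the
#'   rigid tendon nearly locks the patellar attitude to the tibia, so the
#'   default is 0 (plain warm starts).
#' @return a `KneeJointDef`.
#' @export
knee_joint_definition <- function(knee_center = c(0, 0, 0),
                                  pt_insertion_tibia = c(35, 0, -45),
                                  pt_origin_patella = c(0, 0, -18),
                                  pt_length = NULL,
                                  pt_direction = NULL,
                                  patellar_tracking = 0) {
  if (is.null(pt_direction)) {
    # reference patellar attachment = origin point mapped by identity pose
    d <- pt_origin_patella - pt_insertion_tibia
    pt_direction <- d / sqrt(sum(d^2))
    if (is.null(pt_length)) pt_length <- sqrt(sum(d^2))
  }
  if (is.null(pt_length) || pt_length <= 0)
    knee_stop("tendon reference length must be positive", "knee_domain_error")
  u0 <- pt_direction / sqrt(sum(pt_direction^2))
  # tangent basis for the two tendon-swing coordinates
  seed <- if (abs(u0[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  t1 <- seed - sum(seed * u0) * u0
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u0[2] * t1[3] - u0[3] * t1[2],
          u0[3] * t1[1] - u0[1] * t1[3],
          u0[1] * t1[2] - u0[2] * t1[1])
  structure(list(knee_center = knee_center,
                 pt_insertion_tibia = pt_insertion_tibia,
                 pt_origin_patella = pt_origin_patella,
                 pt_length = pt_length, u0 = u0, t1 = t1, t2 = t2,
                 patellar_tracking = patellar_tracking),
            class = "KneeJointDef")
}

#' Body poses from a knee DOF state
#'
#' Maps the 11 coordinates to rigid poses. The zero state reproduces the
#' reference alignment (identity poses). Tibiofemoral rotation order is
#' flexion (y) -> ab/adduction (x) -> internal rotation (z).
#'
#' @param state a `KneeDofState`.
#' @param joint a `KneeJointDef`.
#' @return list with `femur_tibia` and `femur_patella` poses and
#'   `tibia_patella` (the pose actually parameterized).
#' @export
knee_pose_from_dofs <- function(state, joint = knee_joint_definition()) {
  s <- state$tf_secondary
  R_tf <- rot_y(state$tf_flexion) %*% rot_x(s[1]) %*% rot_z(s[2])
  c0 <- joint$knee_center
  # rotate about the knee center, then translate
  p_ft <- pose(R_tf, c0 - as.numeric(R_tf %*% c0) + s[3:5])
  p <- state$pf_secondary
  dir <- rot_axis(joint$t2, p[2] / joint$pt_length) %*%
    rot_axis(joint$t1, p[1] / joint$pt_length) %*% joint$u0
  q <- joint$pt_insertion_tibia + joint$pt_length * as.numeric(dir)
  R_p <- rot_y(p[4]) %*% rot_x(p[3]) %*% rot_z(p[5])
  t_p <- q - as.numeric(R_p %*% joint$pt_origin_patella)
  p_tp <- pose(R_p, t_p)
  list(femur_tibia = p_ft, tibia_patella = p_tp,
       femur_patella = pose_compose(p_ft, p_tp))
}

#' Recover the DOF state from body poses (inverse parameterization)
#'
#' @param poses as returned by [knee_pose_from_dofs()].
#' @param joint a `KneeJointDef`.
#' @return a `KneeDofState` (exact away from gimbal configurations).
#' @export
dofs_from_knee_pose <- function(poses, joint = knee_joint_definition()) {
  dec_yxz <- function(R) {
    b <- asin(max(-1, min(1, -R[2, 3])))
    a <- atan2(R[1, 3], R[3, 3])
    cc <- atan2(R[2, 1], R[2, 2])
    rad2deg(c(a, b, cc))  # (y, x, z) angles
  }
  R <- poses$femur_tibia$R
  ang <- dec_yxz(R)
  c0 <- joint$knee_center
  trans <- poses$femur_tibia$t - (c0 - as.numeric(R %*% c0))
  Rp <- poses$tibia_patella$R
  angp <- dec_yxz(Rp)
  q <- as.numeric(Rp %*% joint$pt_origin_patella) + poses$tibia_patella$t
  dir <- (q - joint$pt_insertion_tibia) / joint$pt_length
  B <- cbind(joint$t1, joint$t2, joint$u0)
  dl <- as.numeric(t(B) %*% dir)
  # dir = Rt2(v/L) Rt1(u/L) u0; in the (t1,t2,u0) basis this is
  # Ry(v)Rx(u)e3 = (sin v cos u, -sin u, cos v cos u)
  u <- asin(max(-1, min(1, -dl[2])))
  v <- atan2(dl[1], dl[3])
  knee_state(ang[1], c(ang[2], ang[3], trans),
             c(u * joint$pt_length, v * joint$pt_length, angp[2], angp[1], angp[3]))
}

#' Patellar-tracking warm start for the FDK search
#'
#' Secondary-coordinate vector whose patellofemoral entries place the
#' patella on its expected trochlear track at a given flexion angle: the
#' patella rotated back relative to the tibia by `patellar_tracking x
#' flexion` about the flexion axis, with the tendon swung accordingly. The
#' tibiofemoral entries are zero. Purely an initial guess; the FDK solve
#' moves on from it.
#'
#' @param flexion driven flexion (deg).
#' @param joint a `KneeJointDef`.
#' @return length-10 secondary coordinate vector.
#' @export
tracked_patellar_alpha <- function(flexion, joint = knee_joint_definition()) {
  B <- rot_y(-joint$patellar_tracking * flexion)
  q <- joint$pt_insertion_tibia + joint$pt_length * as.numeric(B %*% joint$u0)
  p_tp <- pose(B, q - as.numeric(B %*% joint$pt_origin_patella))
  c0 <- joint$knee_center
  Rf <- rot_y(flexion)
  p_ft <- pose(Rf, c0 - as.numeric(Rf %*% c0))
  st <- dofs_from_knee_pose(list(femur_tibia = p_ft, tibia_patella = p_tp), joint)
  state_to_alpha(st)
}

#' Patellar tendon length residual
#'
#' Current tendon length minus the rigid reference length. With the
#' tendon-based patellar parameterization used by the FDK solver this is
#' zero by construction; the function checks arbitrary poses.
#'
#' @param tibia_patella a `Pose` (tibia -> patella frame).
#' @param origin_patella tendon origin in the patella frame (mm).
#' @param insertion_tibia tendon insertion in the tibia frame (mm).
#' @param reference_length rigid tendon length (mm), > 0.
#' @return signed length residual (mm).
#' @export
patellar_tendon_residual <- function(tibia_patella, origin_patella,
                                     insertion_tibia, reference_length) {
  if (reference_length <= 0)
    knee_stop("reference length must be positive", "knee_domain_error")
  q <- pose_apply(tibia_patella, origin_patella)
  sqrt(sum((q - insertion_tibia)^2)) - reference_length
}
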