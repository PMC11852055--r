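# Static-optimization muscle recruitment with the cubic polynomial
# criterion, plus the intersegmental (inverse-dynamics) load computation
# that supplies its right-hand side.
#
# The recruitment problem at each frame is
#   minimize  G(f) = sum_i V_i (f_i^M / N_i)^3
#   s.t.      C f = r,   f_i^M >= 0
# over the unknown vector f = (muscle forces, free reaction/residual
# forces). Reactions carry no objective weight and are unbounded. Ligament
# and contact forces are position-dependent applied loads and enter r, not
# f. Solved by a primal log-barrier interior-point method with
# infeasible-start Newton steps on the KKT system; the objective gradient
# 3 V f^2 / N^3 is continuous at f = 0, so no smoothing is needed.

#' Maximum isometric muscle force from morphology
#'
#' `F0 = mu * PCSA = mu * Vol0 / Lf0`, with the PCSA factor `mu` defaulting
#' to 27 N/cm^2.
#'
#' @param Vol0 muscle volume (cm^3), > 0.
#' @param Lf0 optimum fiber length (cm), > 0.
#' @param mu PCSA factor (N/cm^2), > 0.
#' @return maximum isometric force (N).
#' @export
max_isometric_force <- function(Vol0, Lf0, mu = 27) {
  if (any(Vol0 <= 0) || any(Lf0 <= 0) || any(mu <= 0))
    knee_stop("Vol0, Lf0 and mu must be positive", "knee_domain_error")
  mu * Vol0 / Lf0
}

#' Recruitment problem container
#'
#' @param C m x n coefficient matrix (generalized force per unit actuator
#'   force on each equilibrium equation).
#' @param r length-m load vector (external + inertial generalized forces).
#' @param is_muscle length-n logical: TRUE for bounded muscle columns with
#'   objective weight, FALSE for free reaction/residual columns.
#' @param N instantaneous strengths (N), one per muscle column.
#' @param V volume weight factors, one per muscle column.
#' @param names optional column names.
#' @return a `RecruitmentProblem`.
#' @export
recruitment_problem <- function(C, r, is_muscle, N, V = rep(1, sum(is_muscle)),
                                names = NULL) {
  C <- rbind(C)
  if (length(r) != nrow(C)) knee_stop("length(r) != nrow(C)", "knee_config_error")
  if (length(is_muscle) != ncol(C))
    knee_stop("is_muscle length != ncol(C)", "knee_config_error")
  if (length(N) != sum(is_muscle) || any(N <= 0))
    knee_stop("need one positive strength per muscle", "knee_config_error")
  if (length(V) != sum(is_muscle) || any(V <= 0))
    knee_stop("need one positive volume factor per muscle", "knee_config_error")
  structure(list(C = C, r = as.numeric(r), is_muscle = as.logical(is_muscle),
                 N = as.numeric(N), V = as.numeric(V),
                 names = names %||% paste0("u", seq_len(ncol(C)))),
            class = "RecruitmentProblem")
}

#' Solve the cubic recruitment problem
#'
#' @param problem a `RecruitmentProblem`.
#' @param tol KKT/constraint tolerance (relative to `max(1, ||r||)`).
#' @param max_outer barrier continuation steps.
#' @return a `RecruitmentSolution`: `f` (full vector), `muscle_forces`,
#'   `objective`, `constraint_residual`, `status`.
#' @export
solve_recruitment <- function(problem, tol = 1e-8, max_outer = 40) {
  C <- problem$C
  r <- problem$r
  im <- problem$is_muscle
  m <- nrow(C); n <- ncol(C); nM <- sum(im)
  N3 <- problem$N^3
  V <- problem$V
  scale_r <- max(1, sqrt(sum(r^2)))

  # scale muscle variables by strength for conditioning
  f <- numeric(n)
  f[im] <- pmax(problem$N * 0.05, 1e-3)
  if (any(!im)) {
    # least-squares start for free reactions
    CR <- C[, !im, drop = FALSE]
    rhs <- r - C[, im, drop = FALSE] %*% f[im]
    f[!im] <- tryCatch(qr.coef(qr(CR), rhs), error = function(e) rep(0, sum(!im)))
    f[!im][is.na(f[!im])] <- 0
  }

  tbar <- 1 / max(1e-6, sum(V * (f[im] / problem$N)^3) / nM)
  status <- "max_iterations"
  for (outer in seq_len(max_outer)) {
    # Newton iterations at fixed barrier parameter
    for (it in 1:60) {
      fM <- f[im]
      g <- numeric(n)
      g[im] <- tbar * 3 * V * fM^2 / N3 - 1 / fM
      h <- numeric(n)
      h[im] <- tbar * 6 * V * fM / N3 + 1 / fM^2
      h[!im] <- 1e-12
      K <- rbind(cbind(diag(h, n), t(C)), cbind(C, matrix(0, m, m)))
      rhs <- c(-g, r - as.numeric(C %*% f))
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) { status <- "kkt_singular"; break }
      df <- sol[1:n]
      # fraction-to-boundary step for the positivity bound
      alpha <- 1
      neg <- im & (df < 0)
      if (any(neg)) alpha <- min(1, 0.99 * min(-f[neg] / df[neg]))
      f <- f + alpha * df
      if (max(abs(df)) * alpha < 1e-12 * max(1, max(abs(f))) &&
          sqrt(sum((r - C %*% f)^2)) < tol * scale_r) break
    }
    if (status == "kkt_singular") break
    gap <- nM / tbar
    feas <- sqrt(sum((r - C %*% f)^2))
    if (gap < tol * max(1, abs(sum(V * (f[im] / problem$N)^3))) + 1e-12 &&
        feas < tol * scale_r) { status <- "optimal"; break }
    tbar <- tbar * 10
  }

  feas <- sqrt(sum((r - as.numeric(C %*% f))^2))
  if (feas > 1e-6 * scale_r) {
    # diagnose: bounded least squares to find the violated equation
    obj <- function(x) { z <- as.numeric(C %*% x) - r; sum(z^2) }
    grd <- function(x) as.numeric(2 * t(C) %*% (as.numeric(C %*% x) - r))
    lo <- ifelse(im, 0, -Inf)
    bs <- optim(pmax(f, ifelse(im, 0, f)), obj, grd, method = "L-BFGS-B",
                lower = lo, control = list(maxit = 500))
    resid <- abs(as.numeric(C %*% bs$par) - r)
    worst <- which.max(resid)
    knee_stop(sprintf("recruitment infeasible: equation %d violated by %.3g",
                      worst, resid[worst]), "knee_infeasible_error")
  }
  if (status == "kkt_singular")
    knee_stop("KKT system singular: rank-deficient constraints or redundant free columns",
              "knee_rank_error")
  fM <- pmax(f[im], 0)
  f[im] <- fM
  structure(list(f = f, muscle_forces = stats::setNames(fM, problem$names[im]),
                 objective = sum(V * (fM / problem$N)^3),
                 constraint_residual = feas, status = status),
            class = "RecruitmentSolution")
}

# ---- muscle paths and moment arms ------------------------------------------

#' Muscle unit
#'
#' @param name muscle name.
#' @param Vol0 volume (cm^3). @param Lf0 optimum fiber length (cm).
#' @param mu PCSA factor (N/cm^2).
#' @param V volume weight factor for the recruitment objective.
#' @param path data.frame with columns `body` (one of `"femur"`, `"tibia"`,
#'   `"patella"`) and `x`, `y`, `z` (body-local mm), ordered origin -> via
#'   -> insertion.
#' @return a `MuscleUnit` with `F0` (and strength `N = F0`) bound.
#' @export
muscle_unit <- function(name, Vol0, Lf0, path, mu = 27, V = 1) {
  F0 <- max_isometric_force(Vol0, Lf0, mu)
  if (nrow(path) < 2) knee_stop("muscle path needs >= 2 points", "knee_geometry_error")
  structure(list(name = name, Vol0 = Vol0, Lf0 = Lf0, mu = mu, F0 = F0,
                 N = F0, V = V, path = path), class = "MuscleUnit")
}

muscle_path_points <- function(muscle, poses) {
  pts <- as.matrix(muscle$path[, c("x", "y", "z")])
  out <- pts
  for (b in unique(muscle$path$body)) {
    sel <- muscle$path$body == b
    p <- poses[[b]]
    if (!is.null(p)) out[sel, ] <- pose_apply(p, pts[sel, , drop = FALSE])
  }
  out
}

muscle_length <- function(muscle, poses) {
  p <- muscle_path_points(muscle, poses)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Moment-arm (coefficient) matrix by tendon excursion
#'
#' Generalized force of each muscle per unit tension on each requested
#' coordinate, computed as minus the tendon-excursion derivative
#' `-dL/dq` by central differences of the joint kinematic map. For a
#' straight line of action this equals the classic geometric moment arm
#' (perpendicular-distance lever) on rotational coordinates.
#'
#' @param muscles list of `MuscleUnit`.
#' @param state a `KneeDofState` at which to linearize.
#' @param joint a `KneeJointDef`.
#' @param coords character vector of coordinates: `"flexion"` or
#'   `"alpha1"`..`"alpha10"` (secondary coordinates).
#' @param step finite-difference step (deg or mm).
#' @return length(coords) x length(muscles) matrix.
#' @export
moment_arm_matrix <- function(muscles, state, joint = knee_joint_definition(),
                              coords = "flexion", step = 1e-3) {
  for (mu in muscles) {
    p <- as.matrix(mu$path[, c("x", "y", "z")])
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(seg < 1e-9))
      knee_stop(sprintf("muscle '%s' has a zero-length path segment", mu$name),
                "knee_geometry_error")
  }
  poses_at <- function(st) {
    kp <- knee_pose_from_dofs(st, joint)
    list(femur = pose_identity(), tibia = kp$femur_tibia,
         patella = kp$femur_patella)
  }
  perturb <- function(st, coord, h) {
    if (coord == "flexion") { st$tf_flexion <- st$tf_flexion + h; return(st) }
    k <- as.integer(sub("alpha", "", coord))
    a <- state_to_alpha(st); a[k] <- a[k] + h
    alpha_to_state(a, st$tf_flexion)
  }
  out <- matrix(0, length(coords), length(muscles),
                dimnames = list(coords, vapply(muscles, `[[`, "", "name")))
  for (ci in seq_along(coords)) {
    pp <- poses_at(perturb(state, coords[ci], step))
    pm <- poses_at(perturb(state, coords[ci], -step))
    for (mi in seq_along(muscles)) {
      dL <- (muscle_length(muscles[[mi]], pp) - muscle_length(muscles[[mi]], pm)) /
        (2 * step)
      out[ci, mi] <- -dL
    }
  }
  # rotational coordinates are in degrees; convert lever to per-radian
  rot <- coords %in% c("flexion", "alpha1", "alpha2", "alpha8", "alpha9", "alpha10")
  out[rot, ] <- out[rot, , drop = FALSE] * 180 / pi
  out
}

#' Geometric moment arm of a straight line of action
#'
#' Lever of a unit force along `direction` applied at `point` about an axis
#' through `center` along `axis` (all mm / unit vectors).
#'
#' @param point application point (mm). @param direction unit force
#'   direction. @param center axis point (mm). @param axis unit axis.
#' @return signed moment arm (mm per unit force).
#' @export
geometric_moment_arm <- function(point, direction, center, axis) {
  r <- point - center
  m <- c(r[2] * direction[3] - r[3] * direction[2],
         r[3] * direction[1] - r[1] * direction[3],
         r[1] * direction[2] - r[2] * direction[1])
  sum(m * axis / sqrt(sum(axis^2)))
}

# ---- intersegmental loads --------------------------------------------------

#' Intersegmental knee load from GRF and shank+foot kinematics
#'
#' Newton-Euler balance of the foot+shank subsystem. Returns the force and
#' moment the femur must transmit to the tibia at the knee center, in the
#' global frame (N, N mm). GRF (typically 1000 Hz) is linearly interpolated
#' to the kinematic timestamps (100 Hz nominal). In quasi-static mode
#' accelerations are off; in dynamic mode the linear inertia of the
#' subsystem center of mass is included (central differences; rotational
#' inertia of the shank is neglected at desk scale).
#'
#' @param kin data.frame: `time` (s), knee center `kx,ky,kz` and subsystem
#'   center of mass `cx,cy,cz` (global mm).
#' @param grf data.frame: `time` (s), force `fx,fy,fz` (N), center of
#'   pressure `px,py,pz` (global mm).
#' @param mass shank+foot mass (kg).
#' @param gravity gravitational acceleration (m/s^2), acting along -z.
#' @param quasi_static drop acceleration terms.
#' @return list of matrices `force` (n x 3, N) and `moment` (n x 3, N mm)
#'   plus `time`.
#' @export
intersegmental_load <- function(kin, grf, mass, gravity = 9.81,
                                quasi_static = TRUE) {
  if (nrow(kin) < 1 || nrow(grf) < 1)
    knee_stop("empty input series", "knee_alignment_error")
  if (min(kin$time) < min(grf$time) - 1e-9 || max(kin$time) > max(grf$time) + 1e-9)
    knee_stop("kinematics and GRF time ranges not aligned", "knee_alignment_error")
  gi <- function(col) approx(grf$time, grf[[col]], kin$time, rule = 2)$y
  Fg <- cbind(gi("fx"), gi("fy"), gi("fz"))
  cop <- cbind(gi("px"), gi("py"), gi("pz"))
  W <- matrix(rep(c(0, 0, -mass * gravity), each = nrow(kin)), ncol = 3)
  acc <- matrix(0, nrow(kin), 3)
  if (!quasi_static && nrow(kin) >= 3) {
    com_m <- as.matrix(kin[, c("cx", "cy", "cz")]) / 1000  # mm -> m
    t <- kin$time
    for (j in 1:3) {
      v <- diff(com_m[, j]) / diff(t)
      a <- diff(v) / (0.5 * (diff(t)[-1] + diff(t)[-(length(t) - 1)]))
      acc[, j] <- c(a[1], a, a[length(a)])
    }
  }
  Fk <- mass * acc - Fg - W
  knee <- as.matrix(kin[, c("kx", "ky", "kz")])
  com <- as.matrix(kin[, c("cx", "cy", "cz")])
  crossm <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  Mk <- -crossm(cop - knee, Fg) - crossm(com - knee, W)
  list(time = kin$time, force = Fk, moment = Mk)
}
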