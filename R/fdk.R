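# Force-dependent kinematics (FDK) driver.
#
# Per simulation frame the driven coordinate (tibiofemoral flexion) is
# prescribed and the 10 secondary coordinates alpha are searched until the
# generalized forces conjugate to them vanish: max |F_FDK| <= threshold
# (default 1 N for force coordinates; moment coordinates are compared
# against threshold x a characteristic lever, default 10 mm). Muscle forces
# are re-solved by the cubic recruitment criterion inside every residual
# evaluation, so the secondary positions are genuinely force-dependent.
#
# Generalized forces are assembled by virtual work: all loads on the tibia
# and patella are reduced to wrenches, then dotted with the body twists
# d(pose)/d(alpha_j) obtained by central differences of the kinematic map.
# Rotational coordinates are stated in degrees but their conjugate forces
# are expressed per radian (i.e. as physical moments in N mm).

ROT_COORDS <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)

#' Assemble a knee model
#'
#' @param geometry named list of `TriMesh` surfaces (see
#'   [make_knee_geometry()]); may be NULL for toy models without contact.
#' @param joint a `KneeJointDef`.
#' @param ligaments list of `LigamentBundle` ([build_ligament_bundles()]).
#' @param muscles list of `MuscleUnit`.
#' @param springs optional list of linear springs for toy configurations:
#'   each `list(body_a, point_a, body_b, point_b, k, L0)` with `k` in N/mm
#'   (bilinear, acts in tension and compression).
#' @param contacts list of `ContactPair` ([build_default_pairs()]).
#' @param subject list with `mass` (kg) and `height` (m).
#' @param threshold FDK convergence threshold (N).
#' @param moment_lever characteristic lever (mm) converting the force
#'   threshold to a moment threshold for rotational coordinates.
#' @param active_dofs indices (1..10) of secondary coordinates actually
#'   solved; the rest stay at their initial values (toy configurations).
#' @param gravity gravitational acceleration (m/s^2) used only for body
#'   weight normalization.
#' @return a `KneeModel`.
#' @export
knee_model <- function(geometry = NULL, joint = knee_joint_definition(),
                       ligaments = list(), muscles = list(), springs = list(),
                       contacts = list(), subject = list(mass = 73.4, height = 1.78),
                       threshold = 1, moment_lever = 10, active_dofs = 1:10,
                       gravity = 9.81) {
  structure(list(geometry = geometry, joint = joint, ligaments = ligaments,
                 muscles = muscles, springs = springs, contacts = contacts,
                 subject = subject, threshold = threshold,
                 moment_lever = moment_lever, active_dofs = active_dofs,
                 gravity = gravity,
                 bw = subject$mass * gravity), class = "KneeModel")
}

body_poses <- function(state, joint) {
  kp <- knee_pose_from_dofs(state, joint)
  list(femur = pose_identity(), tibia = kp$femur_tibia,
       patella = kp$femur_patella, tibia_patella = kp$tibia_patella)
}

# twists d(pose)/d(coordinate) for tibia and patella, central differences.
# Returns for each of the 10 secondary coordinates and each moving body:
# omega (per rad for rotational coords, per mm otherwise) and v at the body
# translation point.
body_twists <- function(state, joint, coords = 1:10, step = 1e-3) {
  out <- vector("list", length(coords))
  a0 <- state_to_alpha(state)
  p0 <- body_poses(state, joint)
  for (i in seq_along(coords)) {
    j <- coords[i]
    ap <- a0; ap[j] <- ap[j] + step
    am <- a0; am[j] <- am[j] - step
    pp <- body_poses(alpha_to_state(ap, state$tf_flexion), joint)
    pm <- body_poses(alpha_to_state(am, state$tf_flexion), joint)
    tw <- list()
    for (b in c("tibia", "patella")) {
      dR <- (pp[[b]]$R - pm[[b]]$R) / (2 * step)
      W <- dR %*% t(p0[[b]]$R)
      omega <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
      v <- (pp[[b]]$t - pm[[b]]$t) / (2 * step)
      if (ROT_COORDS[j]) { omega <- omega * 180 / pi; v <- v * 180 / pi }
      tw[[b]] <- list(omega = omega, v = v)
    }
    out[[i]] <- tw
  }
  out
}

# driven-flexion twist (per radian)
flexion_twist <- function(state, joint, step = 1e-3) {
  p0 <- body_poses(state, joint)
  sp <- state; sp$tf_flexion <- sp$tf_flexion + step
  sm <- state; sm$tf_flexion <- sm$tf_flexion - step
  pp <- body_poses(sp, joint)
  pm <- body_poses(sm, joint)
  tw <- list()
  for (b in c("tibia", "patella")) {
    dR <- (pp[[b]]$R - pm[[b]]$R) / (2 * step)
    W <- dR %*% t(p0[[b]]$R)
    omega <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
    tw[[b]] <- list(omega = omega * 180 / pi, v = (pp[[b]]$t - pm[[b]]$t) / (2 * step) * 180 / pi)
  }
  tw
}

new_wrench <- function() list(tibia = list(F = c(0, 0, 0), M = c(0, 0, 0)),
                              patella = list(F = c(0, 0, 0), M = c(0, 0, 0)))

add_force <- function(wr, body, F, at, poses) {
  if (!body %in% c("tibia", "patella")) return(wr)  # femur/ground fixed
  r <- at - poses[[body]]$t
  wr[[body]]$F <- wr[[body]]$F + F
  wr[[body]]$M <- wr[[body]]$M +
    c(r[2] * F[3] - r[3] * F[2], r[3] * F[1] - r[1] * F[3], r[1] * F[2] - r[2] * F[1])
  wr
}

# passive + external wrenches and the contact results at a given state
assemble_loads <- function(state, model, frame) {
  poses <- body_poses(state, model$joint)
  wr <- new_wrench()
  lig_forces <- numeric(length(model$ligaments))
  for (i in seq_along(model$ligaments)) {
    lg <- model$ligaments[[i]]
    o <- pose_apply(poses[[lg$origin_body]], lg$origin)
    ins <- pose_apply(poses[[lg$insertion_body]], lg$insertion)
    L <- sqrt(sum((o - ins)^2))
    Tn <- bundle_force(bundle_strain(L, lg$L0), lg$k, lg$eps_l)
    lig_forces[i] <- Tn
    if (Tn > 0) {
      u <- (o - ins) / L
      wr <- add_force(wr, lg$insertion_body, Tn * u, ins, poses)
      wr <- add_force(wr, lg$origin_body, -Tn * u, o, poses)
    }
  }
  for (sp in model$springs) {
    a <- pose_apply(poses[[sp$body_a]], sp$point_a)
    b <- pose_apply(poses[[sp$body_b]], sp$point_b)
    L <- sqrt(sum((a - b)^2))
    Tn <- sp$k * (L - sp$L0)
    if (abs(Tn) > 0 && L > 1e-12) {
      u <- (a - b) / L
      wr <- add_force(wr, sp$body_b, Tn * u, b, poses)
      wr <- add_force(wr, sp$body_a, -Tn * u, a, poses)
    }
  }
  contact_results <- vector("list", length(model$contacts))
  for (i in seq_along(model$contacts)) {
    cp <- model$contacts[[i]]
    cr <- contact_forces(cp, poses[[cp$slave_body]], poses[[cp$master_body]])
    contact_results[[i]] <- cr
    sel <- cr$depth > 0
    if (any(sel)) {
      f <- -cr$normal[sel, , drop = FALSE] * cr$force_mag[sel]
      pts <- cr$points[sel, , drop = FALSE]
      bt <- poses[[cp$slave_body]]$t
      wr[[cp$slave_body]]$F <- wr[[cp$slave_body]]$F + colSums(f)
      r <- sweep(pts, 2, bt)
      wr[[cp$slave_body]]$M <- wr[[cp$slave_body]]$M +
        colSums(cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
                      r[, 3] * f[, 1] - r[, 1] * f[, 3],
                      r[, 1] * f[, 2] - r[, 2] * f[, 1]))
    }
  }
  if (!is.null(frame$ext_force)) {
    at <- pose_apply(poses$tibia, model$joint$knee_center)
    wr <- add_force(wr, "tibia", frame$ext_force, at, poses)
  }
  if (!is.null(frame$ext_moment))
    wr$tibia$M <- wr$tibia$M + frame$ext_moment
  list(poses = poses, wrench = wr, contact_results = contact_results,
       lig_forces = lig_forces)
}

# unit-tension wrenches of every muscle (list per muscle of body wrenches)
muscle_unit_wrenches <- function(model, poses) {
  lapply(model$muscles, function(mu) {
    pts <- muscle_path_points(mu, poses)
    wr <- new_wrench()
    np <- nrow(pts)
    for (k in seq_len(np)) {
      F <- c(0, 0, 0)
      if (k > 1) {
        d <- pts[k - 1, ] - pts[k, ]
        F <- F + d / sqrt(sum(d^2))
      }
      if (k < np) {
        d <- pts[k + 1, ] - pts[k, ]
        F <- F + d / sqrt(sum(d^2))
      }
      wr <- add_force(wr, mu$path$body[k], F, pts[k, ], poses)
    }
    wr
  })
}

dot_wrench_twist <- function(wr, tw) {
  sum(wr$tibia$F * tw$tibia$v) + sum(wr$tibia$M * tw$tibia$omega) +
    sum(wr$patella$F * tw$patella$v) + sum(wr$patella$M * tw$patella$omega)
}

#' FDK residual: generalized forces on the 10 secondary coordinates
#'
#' Component j is the total generalized force (ligament + contact + muscle +
#' external) conjugate to secondary coordinate j, with muscle forces from
#' the cubic recruitment solution at the current pose. Rotational components
#' are moments in N mm (per radian); translational components are in N.
#'
#' @param alpha length-10 secondary coordinate vector.
#' @param frame list with `flexion` (deg) and optional `ext_force` (N,
#'   global, at the tibial knee center) and `ext_moment` (N mm).
#' @param model a `KneeModel`.
#' @param detail return loads and recruitment with the residual.
#' @return length-10 numeric residual (or a list when `detail = TRUE`).
#' @export
fdk_residual <- function(alpha, frame, model, detail = FALSE) {
  state <- alpha_to_state(alpha, frame$flexion)
  loads <- assemble_loads(state, model, frame)
  tw <- body_twists(state, model$joint)
  recruit <- NULL
  muscle_wr <- NULL
  fM <- numeric(0)
  if (length(model$muscles) > 0) {
    ftw <- flexion_twist(state, model$joint)
    q_pass_flex <- dot_wrench_twist(loads$wrench, ftw)
    muscle_wr <- muscle_unit_wrenches(model, loads$poses)
    Cflex <- vapply(muscle_wr, dot_wrench_twist, 0, tw = ftw)
    prob <- recruitment_problem(
      matrix(Cflex, nrow = 1), r = -q_pass_flex,
      is_muscle = rep(TRUE, length(model$muscles)),
      N = vapply(model$muscles, `[[`, 0, "N"),
      V = vapply(model$muscles, `[[`, 0, "V"),
      names = vapply(model$muscles, `[[`, "", "name"))
    recruit <- tryCatch(solve_recruitment(prob), knee_infeasible_error = function(e)
      knee_stop(sprintf("recruitment infeasible at flexion %.1f deg, alpha [%s]: %s",
                        frame$flexion, paste(sprintf("%.2f", alpha), collapse = ", "),
                        conditionMessage(e)), "knee_infeasible_error"))
    fM <- recruit$muscle_forces
  }
  Q <- vapply(seq_len(10), function(i) {
    q <- dot_wrench_twist(loads$wrench, tw[[i]])
    if (length(fM))
      q <- q + sum(fM * vapply(muscle_wr, dot_wrench_twist, 0, tw = tw[[i]]))
    q
  }, 0)
  if (!detail) return(Q)
  list(Q = Q, loads = loads, recruitment = recruit, state = state)
}

# Total elastic potential energy (ligaments, springs, contact foundation)
# at a secondary-coordinate vector. Independent code path from the
# force/virtual-work residual; used as the oracle in energy-gradient checks.
#' @rdname fdk_residual
#' @export
elastic_energy <- function(alpha, frame, model) {
  state <- alpha_to_state(alpha, frame$flexion)
  poses <- body_poses(state, model$joint)
  E <- 0
  for (lg in model$ligaments) {
    o <- pose_apply(poses[[lg$origin_body]], lg$origin)
    ins <- pose_apply(poses[[lg$insertion_body]], lg$insertion)
    L <- sqrt(sum((o - ins)^2))
    E <- E + bundle_energy(bundle_strain(L, lg$L0), lg$k, lg$eps_l, lg$L0)
  }
  for (sp in model$springs) {
    a <- pose_apply(poses[[sp$body_a]], sp$point_a)
    b <- pose_apply(poses[[sp$body_b]], sp$point_b)
    L <- sqrt(sum((a - b)^2))
    E <- E + 0.5 * sp$k * (L - sp$L0)^2
  }
  for (cp in model$contacts) {
    pen <- vertex_penetrations(cp, poses[[cp$slave_body]], poses[[cp$master_body]])
    E <- E + 0.5 * cp$PM * sum(pen$area * pen$depth^2)
  }
  E
}

scale_residual <- function(Q, model) {
  s <- Q
  s[ROT_COORDS] <- s[ROT_COORDS] / model$moment_lever
  s
}

#' Solve one FDK frame
#'
#' Damped Newton search on the scaled residual with a central
#' finite-difference Jacobian and a line-searched fallback, warm-started
#' from `alpha0`.
#'
#' @param alpha0 initial secondary coordinates (e.g. the previous frame's
#'   solution).
#' @param frame frame inputs (see [fdk_residual()]).
#' @param model a `KneeModel`.
#' @param threshold convergence threshold (N), by default the model's.
#' @param max_iter iteration cap.
#' @param fd_step Jacobian finite-difference step (mm / deg).
#' @return an `FdkState`: `alpha`, `F_FDK` (raw residual), `converged`,
#'   `iterations`, `max_residual` (scaled, N).
#' @export
solve_fdk_frame <- function(alpha0, frame, model, threshold = model$threshold,
                            max_iter = 200, fd_step = 1e-3) {
  if (threshold <= 0) knee_stop("threshold must be positive", "knee_domain_error")
  act <- model$active_dofs
  alpha <- as.numeric(alpha0)
  Q <- tryCatch(fdk_residual(alpha, frame, model),
                knee_infeasible_error = function(e) NULL,
                knee_rank_error = function(e) NULL)
  if (is.null(Q)) {
    # pathological warm start: retry from the zero state
    alpha <- numeric(length(alpha))
    Q <- fdk_residual(alpha, frame, model)
  }
  s <- scale_residual(Q, model)
  best <- max(abs(s[act]))
  it <- 0
  # per-coordinate trust bound per iteration (deg / mm); patellar entries
  # are allowed longer steps since the patella travels with flexion
  max_step <- c(3, 3, 1.5, 1.5, 1.5, 4, 4, 6, 6, 6)
  h <- fd_step
  safe_res <- function(a) {
    tryCatch(fdk_residual(a, frame, model),
             knee_infeasible_error = function(e) NULL,
             knee_rank_error = function(e) NULL)
  }
  while (best > threshold && it < max_iter) {
    it <- it + 1
    J <- matrix(0, length(act), length(act))
    bad_jac <- FALSE
    for (k in seq_along(act)) {
      j <- act[k]
      ap <- alpha; ap[j] <- ap[j] + h
      am <- alpha; am[j] <- am[j] - h
      qp <- safe_res(ap); qm <- safe_res(am)
      if (is.null(qp) || is.null(qm)) { bad_jac <- TRUE; break }
      J[, k] <- (scale_residual(qp, model)[act] -
                 scale_residual(qm, model)[act]) / (2 * h)
    }
    try_dir <- function(step) {
      ov <- max(abs(step) / max_step[act])
      if (ov > 1) step <- step / ov
      lam <- 1
      for (ls in 1:9) {
        cand <- alpha
        cand[act] <- cand[act] + lam * step
        Qc <- safe_res(cand)
        if (!is.null(Qc)) {
          sc <- scale_residual(Qc, model)
          if (max(abs(sc[act])) < best * (1 - 1e-4) ||
              max(abs(sc[act])) <= threshold)
            return(list(alpha = cand, Q = Qc, s = sc))
        }
        lam <- lam / 2
      }
      NULL
    }
    res <- NULL
    if (!bad_jac) {
      step <- tryCatch(-solve(J, s[act]), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) res <- try_dir(step)
      if (is.null(res)) {
        # fall back to a line-searched Cauchy (steepest-descent) step on
        # 0.5||s||^2: step length minimizes the linearized objective
        g <- as.numeric(t(J) %*% s[act])
        denom <- sum((J %*% g)^2)
        if (denom > 0) res <- try_dir(-g * sum(g^2) / denom)
      }
    }
    if (is.null(res) && h < 0.05) {
      # the residual is only piecewise-smooth across mesh facets: retry the
      # Jacobian with a coarser difference step before giving up
      h <- h * 10
      next
    }
    if (is.null(res)) break
    alpha <- res$alpha; Q <- res$Q; s <- res$s
    best <- max(abs(s[act]))
    h <- fd_step
  }
  structure(list(alpha = alpha, F_FDK = Q, converged = best <= threshold,
                 iterations = it, max_residual = best), class = "FdkState")
}

# medial/lateral/total tibiofemoral resultants from contact results
tfcf_from_contacts <- function(contact_results, model) {
  med <- c(0, 0, 0); lat <- c(0, 0, 0); pf <- c(0, 0, 0)
  for (cr in contact_results) {
    if (cr$name %in% c("medial_tibial", "medial_meniscus")) {
      med <- med + cr$force_on_slave
    } else if (cr$name %in% c("lateral_tibial", "lateral_meniscus")) {
      lat <- lat + cr$force_on_slave
    } else if (cr$name == "patellofemoral") {
      pf <- pf + cr$force_on_slave
    } else {
      # generic pairs: split by compartment tags
      med <- med + cr$compartment$medial
      lat <- lat + cr$compartment$lateral + cr$compartment$none
    }
  }
  list(medial_vec = med, lateral_vec = lat, total_vec = med + lat,
       total = sqrt(sum((med + lat)^2)), medial = sqrt(sum(med^2)),
       lateral = sqrt(sum(lat^2)), pf = sqrt(sum(pf^2)))
}

#' Run a full activity trial
#'
#' Per-frame pipeline: prescribe flexion (from the trial's ground-truth
#' profile or a marker fit), apply the intersegmental knee load, solve the
#' FDK equilibrium (recruitment + contact + ligaments inside), extract
#' total/medial/lateral tibiofemoral contact force, then resample the
#' cycle onto 101 points and normalize by body weight.
#'
#' @param model a `KneeModel`.
#' @param trial list with `activity` and a data.frame `frames` holding
#'   `time`, `flexion` (deg), `fx,fy,fz` (N) and `mx,my,mz` (N mm): the
#'   intersegmental load transmitted femur -> tibia, applied to the tibia
#'   with reversed sign (action of the distal segment).
#' @param alpha0 initial secondary coordinates.
#' @param verbose print per-frame convergence.
#' @return a `TrialResult`: per-frame records, convergence flags and
#'   101-point BW-normalized curves.
#' @export
run_trial <- function(model, trial, alpha0 = numeric(10), verbose = FALSE) {
  fr <- trial$frames
  n <- nrow(fr)
  recs <- vector("list", n)
  alpha <- alpha0 + tracked_patellar_alpha(fr$flexion[1], model$joint)
  for (i in seq_len(n)) {
    if (i > 1)  # transport the warm start along the patellar track
      alpha <- alpha + tracked_patellar_alpha(fr$flexion[i], model$joint) -
        tracked_patellar_alpha(fr$flexion[i - 1], model$joint)
    frame <- list(flexion = fr$flexion[i],
                  ext_force = -c(fr$fx[i], fr$fy[i], fr$fz[i]),
                  ext_moment = -c(fr$mx[i], fr$my[i], fr$mz[i]))
    st <- solve_fdk_frame(alpha, frame, model)
    alpha <- st$alpha
    det <- fdk_residual(alpha, frame, model, detail = TRUE)
    tf <- tfcf_from_contacts(det$loads$contact_results, model)
    recs[[i]] <- list(time = fr$time[i], flexion = fr$flexion[i], fdk = st,
                      tfcf = tf, recruitment = det$recruitment,
                      lig_forces = det$loads$lig_forces)
    if (verbose)
      message(sprintf("frame %3d flex %6.1f iters %3d res %8.3f N TFCF %6.1f N",
                      i, fr$flexion[i], st$iterations, st$max_residual, tf$total))
  }
  conv <- vapply(recs, function(r) r$fdk$converged, TRUE)
  bw <- model$bw
  tot <- vapply(recs, function(r) r$tfcf$total, 0) / bw
  med <- vapply(recs, function(r) r$tfcf$medial, 0) / bw
  lat <- vapply(recs, function(r) r$tfcf$lateral, 0) / bw
  curves <- data.frame(
    percent_cycle = seq(0, 100, length.out = 101),
    tfcf_total_bw = normalize_cycle(fr$time, tot)$value,
    tfcf_medial_bw = normalize_cycle(fr$time, med)$value,
    tfcf_lateral_bw = normalize_cycle(fr$time, lat)$value)
  structure(list(activity = trial$activity, frames = recs, converged = conv,
                 curves = curves, bw = bw,
                 nonconverged_frames = which(!conv)), class = "TrialResult")
}

#' Write / read trial curve files (delimited text)
#' @param result a `TrialResult`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_curves <- function(result, path) {
  d <- cbind(activity = result$activity, result$curves)
  write.table(format(d, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write per-frame contact summaries as delimited text
#'
#' One row per frame and compartment: resultant force components,
#' magnitude and number of contacting vertices.
#'
#' @param result a `TrialResult`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_contact_summary <- function(result, path) {
  rows <- do.call(rbind, lapply(seq_along(result$frames), function(i) {
    fr <- result$frames[[i]]
    tf <- fr$tfcf
    data.frame(frame = i, time = fr$time,
               compartment = c("medial", "lateral", "total"),
               fx = c(tf$medial_vec[1], tf$lateral_vec[1], tf$total_vec[1]),
               fy = c(tf$medial_vec[2], tf$lateral_vec[2], tf$total_vec[2]),
               fz = c(tf$medial_vec[3], tf$lateral_vec[3], tf$total_vec[3]),
               f = c(tf$medial, tf$lateral, tf$total))
  }))
  write.table(format(rows, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (cc in setdiff(names(d), "activity")) d[[cc]] <- as.numeric(d[[cc]])
  d
}
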