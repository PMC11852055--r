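# Piecewise quadratic/linear ligament bundle mechanics.
#
# Each bundle is a tension-only straight-line element between an origin and
# an insertion. The force-strain law has a quadratic toe region up to twice
# the linear strain limit eps_l, then a linear region with stiffness k
# (N/strain):
#   f(e) = 0                      e < 0
#        = (1/4) k e^2 / eps_l    0 <= e <= 2 eps_l
#        = k (e - eps_l)          e > 2 eps_l
# The two branches meet at e = 2 eps_l with value k*eps_l and slope k (C1).
# Slack length L0 is calibrated from the bundle length at full knee
# extension and the reference strain eps_r tabulated per bundle.

#' Default 22-bundle ligament parameter table
#'
#' Ten ligaments, 22 bundles: cruciates (ACL, PCL), collaterals (LCL, MCL),
#' patellofemoral ligaments (MPFL, LPFL), posteromedial complex, posterior
#' oblique, anterolateral and popliteofibular ligaments. Columns: bundle
#' name, ligament group, stiffness `k` (N/strain) and reference strain
#' `eps_r` at full extension. The linear strain limit `eps_l` defaults to
#' 0.03 for every bundle (the customary value for this piecewise law; the
#' source tabulations give none) and is configurable per bundle.
#'
#' @param eps_l linear strain limit applied to all bundles.
#' @return data.frame with columns `bundle`, `ligament`, `k`, `eps_r`,
#'   `eps_l`.
#' @export
default_bundle_table <- function(eps_l = 0.03) {
  tab <- data.frame(
    bundle = c("aACL", "pACL",
               "aPCL", "pPCL",
               "aLCL", "mLCL", "pLCL",
               "aMCL", "mMCL", "pMCL", "aDMCL", "pDMCL",
               "sMPFL", "mMPFL", "iMPFL",
               "sLPFL", "mLPFL", "iLPFL",
               "PMC", "POL", "ALL", "PFL"),
    ligament = c("ACL", "ACL",
                 "PCL", "PCL",
                 "LCL", "LCL", "LCL",
                 "MCL", "MCL", "MCL", "MCL", "MCL",
                 "MPFL", "MPFL", "MPFL",
                 "LPFL", "LPFL", "LPFL",
                 "PMC", "POL", "ALL", "PFL"),
    k = c(5000, 5000,
          9000, 9000,
          2000, 2000, 2000,
          2500, 3000, 2500, 1000, 1000,
          2000, 2000, 2000,
          2000, 2000, 2000,
          2000, 1500, 2000, 2000),
    eps_r = c(0.06, 0.10,
              -0.24, -0.03,
              0.03, -0.05, 0.08,
              0.04, 0.04, 0.04, -0.18, -0.04,
              0.08, 0.08, 0.08,
              0.06, 0.06, 0.06,
              -0.04, -0.18, 0.05, 0.05),
    stringsAsFactors = FALSE)
  tab$eps_l <- eps_l
  tab
}

#' Slack length from the full-extension reference strain
#'
#' `L0 = L_ext / (1 + eps_r)`: bundles with negative reference strain are
#' slack at full extension (L0 larger than the extended length).
#'
#' @param length_at_full_extension bundle length at full extension (mm), > 0.
#' @param eps_r reference strain, > -1.
#' @return slack length L0 (mm).
#' @export
slack_length_from_reference <- function(length_at_full_extension, eps_r) {
  if (any(length_at_full_extension <= 0))
    knee_stop("length must be positive", "knee_domain_error")
  if (any(eps_r <= -1))
    knee_stop("reference strain must exceed -1", "knee_domain_error")
  length_at_full_extension / (1 + eps_r)
}

#' Engineering strain of a bundle
#' @param length current origin-insertion distance (mm).
#' @param L0 slack length (mm), > 0.
#' @return strain (dimensionless).
#' @export
bundle_strain <- function(length, L0) {
  if (any(L0 <= 0)) knee_stop("slack length must be positive", "knee_domain_error")
  (length - L0) / L0
}

#' Tension of a bundle from its strain
#'
#' Vectorized over `eps` (and over `k`, `eps_l` of matching length).
#'
#' @param eps strain.
#' @param k stiffness (N/strain), >= 0.
#' @param eps_l linear strain limit, > 0.
#' @return tensile force (N), zero when slack.
#' @export
bundle_force <- function(eps, k, eps_l = 0.03) {
  if (any(eps_l <= 0)) knee_stop("eps_l must be positive", "knee_domain_error")
  toe <- 0.25 * k * eps^2 / eps_l
  lin <- k * (eps - eps_l)
  ifelse(eps < 0, 0, ifelse(eps <= 2 * eps_l, toe, lin))
}

# Elastic energy stored in a bundle at engineering strain eps, for a slack
# length L0 (integral of force over length, dL = L0 de). Used by the
# energy-gradient checks of the FDK residual.
bundle_energy <- function(eps, k, eps_l, L0) {
  e2 <- pmin(pmax(eps, 0), 2 * eps_l)
  toe <- k / (12 * eps_l) * e2^3
  lin <- ifelse(eps > 2 * eps_l,
                0.5 * k * (eps - eps_l)^2 - 0.5 * k * eps_l^2, 0)
  L0 * (toe + lin)
}

#' Assemble ligament bundles from a parameter table and attachment sets
#'
#' Joins the mechanical table with per-bundle attachment points (body-local,
#' mm) and calibrates slack lengths so each bundle attains its reference
#' strain at the full-extension reference pose (identity poses).
#'
#' @param table as [default_bundle_table()].
#' @param attachments data.frame: `bundle`, `origin_body`, `ox`,`oy`,`oz`,
#'   `insertion_body`, `ix`,`iy`,`iz`.
#' @return list of `LigamentBundle` records.
#' @export
build_ligament_bundles <- function(table = default_bundle_table(), attachments) {
  idx <- match(table$bundle, attachments$bundle)
  if (anyNA(idx))
    knee_stop(paste("missing attachments for:",
                    paste(table$bundle[is.na(idx)], collapse = ", ")),
              "knee_config_error")
  at <- attachments[idx, ]
  lapply(seq_len(nrow(table)), function(i) {
    o <- as.numeric(at[i, c("ox", "oy", "oz")])
    ins <- as.numeric(at[i, c("ix", "iy", "iz")])
    L_ext <- sqrt(sum((o - ins)^2))
    structure(list(
      name = table$bundle[i], ligament = table$ligament[i],
      origin_body = at$origin_body[i], origin = o,
      insertion_body = at$insertion_body[i], insertion = ins,
      k = table$k[i], eps_r = table$eps_r[i], eps_l = table$eps_l[i],
      L0 = slack_length_from_reference(L_ext, table$eps_r[i])),
      class = "LigamentBundle")
  })
}
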