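# Outer posture search: CMA-ES over fingertip contact positions.
#
# Each candidate is a set of in-plane (u, v) coordinates, one pair per
# grasping finger, on that finger's assigned contact surface. A candidate is
# scored by (1) solving the penalized inverse kinematics for the fingertip
# targets, (2) building the soft-contact pairs, grasp matrix, friction
# pyramids (with the planner's halved friction coefficient) and contact
# Jacobian at the converged posture, and (3) solving the effort QP. If the
# fingertips cannot reach the targets or no activation pattern satisfies the
# grasp constraints, the candidate receives the infeasibility penalty, which
# ranks infeasible postures by their deviation from the natural posture.

#' Carpal starting pose aligning the natural pinch with the grasp axis
#'
#' Places the hand so that, in its natural posture, the thumb-to-index
#' aperture midpoint sits at `center` and the aperture axis (thumb tip to
#' index tip) is aligned with `axis` (the plate-to-plate direction of a
#' two-plate pinch, thumb on the `-axis` side). This gives the inverse
#' kinematics a nearly closed pinch to start from.
#'
#' @param hand a [build_parametric_hand()] model.
#' @param center world point the aperture midpoint starts at (m).
#' @param axis world grasp-axis direction.
#' @return a [base_pose()].
#' @export
pinch_base_default <- function(hand, center = c(0, 0, 0), axis = c(0, 1, 0)) {
  fk <- forward_kinematics(hand, hand$q0, base_pose())
  thumb <- fk$tips["thumb", ]
  index <- fk$tips["index", ]
  d <- unitize(index - thumb)
  b <- unitize(axis)
  cr <- cross3(d, b)
  s <- sqrt(sum(cr^2)); co <- sum(d * b)
  R1 <- if (s < 1e-9) {
    if (co > 0) diag(3) else rot_axis(unitize(cross3(d, c(1, 0, 0))), pi)
  } else rot_axis(cr / s, atan2(s, co))
  mid <- (thumb + index) / 2
  base_pose(p = as.numeric(center - R1 %*% mid), e = R_to_rotvec(R1))
}

#' Configure the posture search
#'
#' @param object the grasped [rigid_object()].
#' @param fingers grasping fingers (names), in contact order.
#' @param surfaces index of the assigned contact surface per finger.
#' @param site contact site on the distal phalanx, `"tip"` or `"pulp"`
#'   (recycled per finger).
#' @param base0 initial carpal pose; `NULL` (default) auto-aligns the
#'   natural pinch with the grasp axis via [pinch_base_default()] when the
#'   search runs.
#' @param weights inverse-kinematics weights.
#' @param uv0 initial in-plane mean per finger (2 x nf matrix or length-2
#'   vector recycled); defaults to the patch centres.
#' @param margin_m border of the patch excluded from the search (m).
#' @param sigma0 initial CMA-ES step size; default the largest patch
#'   half-extent, so the first generations sample the entire plate and the
#'   search cannot be trapped by a distant start.
#' @param lambda,max_gen,tol_fun,tol_gen CMA-ES controls.
#' @param seed integer seed for the search.
#' @param ik_maxit inner IK iteration cap per candidate.
#' @param press_depth how far inside the surface the IK target is placed
#'   (m); emulates pad compression so the balance against the skin
#'   non-penetration term lands the fingertip on the plate.
#' @param contact_tol max in-plane fingertip-to-target residual for a
#'   candidate to count as in contact (m); the normal gap may additionally
#'   be up to twice this.
#' @param mu_eff effective friction coefficient; default
#'   [effective_mu()] of the object's actual one.
#' @param strength_scale conversion of the tabulated relative muscle
#'   capacities to newtons (see [load_muscle_table()]). The default 100 is
#'   chosen so the packaged parametric hand can execute the full pinch
#'   protocol - including off-centre grips whose torsional couples saturate
#'   the friction cones and demand several-fold larger grip forces - with
#'   activation headroom; the generic chain lacks the real hand's broad
#'   contact patches and posture-dependent moment arms, which this raw
#'   capacity compensates.
#' @return list of class `search_config`.
#' @export
search_config <- function(object,
                          fingers = c("thumb", "index"),
                          surfaces = c(1, 2),
                          site = "tip",
                          base0 = NULL,
                          weights = ik_weights_default(),
                          uv0 = NULL, margin_m = 0.002,
                          sigma0 = NULL, lambda = NULL,
                          max_gen = 200, tol_fun = 1e-6, tol_gen = 20,
                          seed = 1L, ik_maxit = 120,
                          press_depth = 0.0015,
                          contact_tol = 0.002,
                          mu_eff = NULL, strength_scale = 100) {
  nf <- length(fingers)
  stopifnot(length(surfaces) == nf)
  site <- rep(site, length.out = nf)
  hu <- vapply(surfaces, function(s) object$surfaces[[s]]$half_u, 0)
  hv <- vapply(surfaces, function(s) object$surfaces[[s]]$half_v, 0)
  lower <- as.numeric(rbind(-(hu - margin_m), -(hv - margin_m)))
  upper <- -lower
  if (is.null(uv0)) uv0 <- rep(0, 2 * nf)
  if (is.null(sigma0)) sigma0 <- max(c(hu, hv))
  if (is.null(mu_eff)) mu_eff <- effective_mu(object$mu_actual)
  joint_sets <- list(thumb = 1:5, index = 6:9, middle = 10:13,
                     ring = 14:17, little = 18:21)
  active <- sort(unlist(joint_sets[fingers]))
  structure(list(fingers = fingers, surfaces = surfaces, site = site,
                 base0 = base0, weights = weights,
                 uv0 = as.numeric(uv0), lower = lower, upper = upper,
                 sigma0 = sigma0, lambda = lambda, max_gen = max_gen,
                 tol_fun = tol_fun, tol_gen = tol_gen, seed = as.integer(seed),
                 ik_maxit = ik_maxit, press_depth = press_depth,
                 contact_tol = contact_tol,
                 mu_eff = mu_eff, strength_scale = strength_scale,
                 active_joints = active),
            class = "search_config")
}

#' Evaluate one fingertip-placement candidate
#'
#' Runs inverse kinematics for targets at the candidate's (u, v) positions,
#' builds the contacts and solves the effort QP. Never raises on
#' infeasibility: unreachable targets or an infeasible QP yield the
#' [infeasibility_penalty()].
#'
#' @param hand a [build_parametric_hand()] model.
#' @param object the grasped [rigid_object()].
#' @param config a [search_config()].
#' @param uv numeric vector `c(u1, v1, u2, v2, ...)`, one (u, v) pair per
#'   grasping finger, within the configured bounds.
#' @param warm optional warm-start state for the inner IK.
#' @return list with `E`, `feasible`, `ik`, `qp`, `contacts`, `targets`.
#' @export
evaluate_candidate <- function(hand, object, config, uv, warm = NULL) {
  nf <- length(config$fingers)
  stopifnot(length(uv) == 2 * nf)
  if (is.null(config$base0)) config$base0 <- pinch_base_default(hand)
  targets <- vector("list", nf)
  for (i in seq_len(nf)) {
    srf <- object$surfaces[[config$surfaces[i]]]
    site_r <- hand$fingertips[[config$fingers[i]]]$sites[[config$site[i]]]$r
    # place the contact sphere centre one radius off the surface (minus the
    # pad-compression press depth), tangency then being orientation-free
    d0 <- surface_point(srf, uv[2 * i - 1], uv[2 * i]) -
      (site_r - config$press_depth) * srf$normal
    targets[[i]] <- list(finger = config$fingers[i], site = config$site[i],
                         d0 = d0)
  }
  prob <- ik_problem(hand, targets, object = object, base0 = config$base0,
                     weights = config$weights,
                     active_joints = config$active_joints)
  ik <- solve_ik(prob, init = warm, maxit = config$ik_maxit)
  fk <- forward_kinematics(hand, ik$q, list(p = ik$p, e = ik$e))

  # contact centroids: converged sites projected onto their plates
  contacts <- list()
  reach_ok <- TRUE
  for (i in seq_len(nf)) {
    srf <- object$surfaces[[config$surfaces[i]]]
    ctr <- fingertip_site(fk, hand, config$fingers[i], config$site[i])
    site_r <- attr(ctr, "radius")
    gap_n <- sum((ctr - srf$origin) * srf$normal)  # negative outside
    err <- ctr - targets[[i]]$d0
    err_t <- err - sum(err * srf$normal) * srf$normal
    if (sqrt(sum(err_t^2)) > config$contact_tol ||
        abs(gap_n + site_r - config$press_depth) > 2 * config$contact_tol)
      reach_ok <- FALSE
    centroid <- as.numeric(ctr - gap_n * srf$normal)
    dseg <- hand$fingertips[[config$fingers[i]]]$segment
    lat <- as.numeric(fk$R[[dseg]][, 2])  # distal phalanx medio-lateral axis
    lat_ip <- lat - sum(lat * srf$normal) * srf$normal
    if (sqrt(sum(lat_ip^2)) < 1e-6) lat <- srf$u  # fallback: long plate axis
    pair <- soft_contact_pair(centroid, srf$normal, lat, segment = dseg)
    contacts <- c(contacts, pair)
  }

  if (!reach_ok) {
    return(list(E = infeasibility_penalty(ik$q, prob$q0), feasible = FALSE,
                ik = ik, qp = NULL, contacts = contacts, targets = targets))
  }

  J <- contact_jacobian(hand, ik$q, NULL, contacts, fk = fk)
  G <- grasp_matrix(contacts, com = object$com)
  pyr <- lapply(contacts, function(ct) friction_pyramid(ct$normal, config$mu_eff))
  N <- assemble_facet_matrix(pyr)
  ms <- get_muscle_set(config$strength_scale)
  qp <- solve_grasp_qp(grasp_problem(J, ms, G, N, object$mass_kg,
                                     object$gravity))
  if (qp$status != "optimal") {
    return(list(E = infeasibility_penalty(ik$q, prob$q0), feasible = FALSE,
                ik = ik, qp = qp, contacts = contacts, targets = targets))
  }
  list(E = qp$E, feasible = TRUE, ik = ik, qp = qp,
       contacts = contacts, targets = targets)
}

# muscle table cache (the packaged table is immutable)
the <- new.env(parent = emptyenv())
get_muscle_set <- function(strength_scale = 1) {
  key <- paste0("s", strength_scale)
  if (is.null(the[[key]])) the[[key]] <- load_muscle_table(
    strength_scale = strength_scale)
  the[[key]]
}

#' Synthesize a precision grip
#'
#' Outer CMA-ES search over the fingertip contact positions; each candidate
#' is scored through inverse kinematics and the effort QP
#' (see [evaluate_candidate()]). The best-so-far effort is non-increasing
#' across generations and the run is reproducible for a fixed seed.
#'
#' @param hand a [build_parametric_hand()] model.
#' @param object the grasped [rigid_object()].
#' @param config a [search_config()].
#' @return an object of class `grasp_synthesis`: best `E`, `uv`, inner `ik`
#'   and `qp` solutions, `contacts`, the CMA-ES `trace` and diagnostics.
#' @export
synthesize_grasp <- function(hand, object, config = search_config(object)) {
  if (is.null(config$base0)) config$base0 <- pinch_base_default(hand)
  state <- new.env(parent = emptyenv())
  state$warm <- NULL
  state$bestE <- Inf
  fn <- function(uv) {
    ev <- evaluate_candidate(hand, object, config, uv, warm = state$warm)
    if (ev$feasible && ev$E < state$bestE) {
      state$bestE <- ev$E
      state$warm <- list(p = ev$ik$p, e = ev$ik$e, q = ev$ik$q)
    }
    ev$E
  }
  opt <- cmaes_minimize(fn, config$uv0, config$sigma0,
                        config$lower, config$upper,
                        lambda = config$lambda, max_gen = config$max_gen,
                        tol_fun = config$tol_fun, tol_gen = config$tol_gen,
                        seed = config$seed)
  best <- evaluate_candidate(hand, object, config, opt$x, warm = state$warm)
  structure(list(E = best$E, uv = opt$x, feasible = best$feasible,
                 ik = best$ik, qp = best$qp, contacts = best$contacts,
                 targets = best$targets, trace = opt$trace,
                 generations = opt$generations,
                 evaluations = opt$evaluations,
                 config = config, object = object),
            class = "grasp_synthesis")
}

#' @export
print.grasp_synthesis <- function(x, ...) {
  cat("Precision-grip synthesis",
      if (x$feasible) "(feasible grasp found)" else "(NO feasible grasp)", "\n")
  cat(" muscle effort E =", format(x$E, digits = 6),
      "after", x$generations, "generations (",
      x$evaluations, "candidate evaluations )\n")
  nf <- length(x$config$fingers)
  for (i in seq_len(nf)) {
    cat(sprintf("  %-6s (u, v) = (%+.1f, %+.1f) mm on surface %d [%s]\n",
                x$config$fingers[i], 1000 * x$uv[2 * i - 1],
                1000 * x$uv[2 * i], x$config$surfaces[i], x$config$site[i]))
  }
  invisible(x)
}

#' @export
summary.grasp_synthesis <- function(object, ...) {
  print(object)
  if (object$feasible) {
    f <- object$qp$f
    cat(" contact forces (N, world frame):\n")
    for (k in seq_len(nrow(f)))
      cat(sprintf("  contact %d: (%+.3f, %+.3f, %+.3f)\n",
                  k, f[k, 1], f[k, 2], f[k, 3]))
    a <- coef(object)
    on <- a[a > 0.01]
    cat(" activations > 0.01:\n")
    for (nm in names(on)) cat(sprintf("  %-5s %.3f\n", nm, on[[nm]]))
    cat(" vertical force total:", format(sum(f[, 3]), digits = 5), "N",
        "( object weight:",
        format(object$object$mass_kg * 9.81, digits = 5), "N )\n")
  }
  invisible(object)
}

#' @export
coef.grasp_synthesis <- function(object, ...) {
  if (is.null(object$qp)) return(NULL)
  object$qp$a
}

#' @export
residuals.grasp_synthesis <- function(object, ...) {
  if (is.null(object$qp)) return(NULL)
  object$qp$residuals
}

#' @export
plot.grasp_synthesis <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$generation, tr$best_so_far, type = "s",
                 xlab = "generation", ylab = "best effort E so far",
                 main = "CMA-ES posture search", ...)
  graphics::points(tr$generation, tr$best, pch = 20, col = "grey50")
  invisible(x)
}
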