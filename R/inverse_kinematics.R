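# Penalized inverse kinematics of the hand.
#
# For given target fingertip positions, the carpal pose (p, e) and joint
# angles q are found by quasi-Newton minimization of
#
#   L = w1 sum_l |d_l(p,q,e) - d_l^0|^2 + w2 sum_m s_m^2
#     + w3 |p - p0|^2 + w4 |e - e0|^2 + w5 |q - q0|^2
#
# where d_l are the fingertip contact sites of the active fingers, s_m the
# penetration depths of the 65 skin spheres into the object (penalized as
# depth^2: the flatter depth^4 reading gives no restoring gradient near
# the surface), and (p0, e0, q0) the initial, anatomically natural state.
# Weights are configurable; the defaults make target reaching and
# non-penetration dominant and posture naturalness a regularizer. Joint
# angles are box-limited; gradients are central finite differences.

#' Default inverse-kinematics weights
#'
#' `w1` target reaching, `w2` non-penetration, `w3` carpal translation,
#' `w4` carpal rotation, `w5` joint deviation (SI units: m^2 terms for
#' w1-w3, rad^2 for w4-w5). The ordering encodes that fingertip contact and
#' non-penetration dominate while posture naturalness regularizes.
#' @export
ik_weights_default <- function() {
  c(w1 = 100, w2 = 100, w3 = 1, w4 = 1, w5 = 0.1)
}

#' Define an inverse-kinematics problem
#'
#' @param model a [build_parametric_hand()] model.
#' @param targets list of targets, each `list(finger =, site =, d0 =)` with
#'   `finger` a name or index, `site` `"tip"` or `"pulp"` and `d0` the target
#'   world position (m). Only fingers with a target contribute the reaching
#'   term.
#' @param object optional [rigid_object()] for the penetration term (w2).
#' @param base0 initial carpal pose ([base_pose()]).
#' @param q0 initial joint angles (defaults to the model's natural posture).
#' @param weights the five weights (see [ik_weights_default()]).
#' @param active_joints indices (or names) of joints the solver may move;
#'   the rest stay pinned at `q0`. Default: all 21.
#' @return an object of class `ik_problem`.
#' @export
ik_problem <- function(model, targets, object = NULL,
                       base0 = base_pose(), q0 = model$q0,
                       weights = ik_weights_default(),
                       active_joints = seq_len(21)) {
  if (length(targets) < 1) stop("at least one fingertip target is required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is.character(active_joints))
    active_joints <- match(active_joints, JOINT_NAMES)
  targets <- lapply(targets, function(tg) {
    tg$site <- match.arg(tg$site, c("tip", "pulp"))
    tg$d0 <- as.numeric(tg$d0)
    tg
  })
  structure(list(model = model, targets = targets, object = object,
                 base0 = base0, q0 = as.numeric(q0), weights = weights,
                 active = sort(unique(active_joints))),
            class = "ik_problem")
}

#' Inverse-kinematics objective L with its term breakdown
#'
#' @param problem an [ik_problem()].
#' @param p,e,q carpal position, carpal rotation vector, 21 joint angles.
#' @return list with `L` and the five weighted `terms`.
#' @export
objective_L <- function(problem, p, e, q) {
  w <- problem$weights
  fk <- forward_kinematics(problem$model, q, list(p = p, e = e))
  t_target <- 0
  for (tg in problem$targets) {
    dpos <- fingertip_site(fk, problem$model, tg$finger, tg$site)
    t_target <- t_target + sum((dpos - tg$d0)^2)
  }
  t_pen <- 0
  if (!is.null(problem$object) && w[2] > 0) {
    s <- penetration_depths(problem$model, q, NULL, problem$object, fk = fk)
    t_pen <- sum(s^2)
  }
  terms <- c(target = w[1] * t_target,
             penetration = w[2] * t_pen,
             translation = w[3] * sum((p - problem$base0$p)^2),
             rotation = w[4] * sum((e - problem$base0$e)^2),
             joints = w[5] * sum((q - problem$q0)^2))
  list(L = sum(terms), terms = terms)
}

#' Analytic gradient of L over (p, e, active q)
#'
#' Target and penetration terms differentiate through the world position of
#' points on the chain: identity in the carpal translation, the SO(3)
#' right-Jacobian pullback in the carpal rotation vector, and
#' `axis x (point - centre)` for joints on the root-to-segment path.
#' @keywords internal
ik_gradient <- function(problem, p, e, q, fk = NULL) {
  model <- problem$model
  w <- problem$weights
  act <- problem$active
  if (is.null(fk)) fk <- forward_kinematics(model, q, list(p = p, e = e))
  Rb <- rotvec_to_R(e)
  Jr <- rotvec_right_jacobian(e)
  g_p <- numeric(3); g_e <- numeric(3); g_q <- numeric(21)

  add_point <- function(nm, wpt, r) {
    # r = dL/d(point), length 3
    g_p <<- g_p + r
    xc <- as.numeric(crossprod(Rb, wpt - p))
    g_e <<- g_e - as.numeric(crossprod(Rb %*% skew3(xc) %*% Jr, r))
    for (j in model$joint_path[[nm]]) {
      g_q[j] <<- g_q[j] + sum(r * cross3(fk$axis[j, ], wpt - fk$center[j, ]))
    }
  }

  for (tg in problem$targets) {
    ft <- model$fingertips[[tg$finger]]
    wpt <- as.numeric(fk$o[[ft$segment]] +
                        fk$R[[ft$segment]] %*% ft$sites[[tg$site]]$center)
    add_point(ft$segment, wpt, 2 * w[1] * (wpt - tg$d0))
  }

  if (!is.null(problem$object) && w[2] > 0) {
    centres <- matrix(NA_real_, 65, 3)
    for (blk in model$sphere_local) {
      nm <- model$spheres$segment[blk$idx[1]]
      centres[blk$idx, ] <- t(fk$R[[nm]] %*% blk$xyz + fk$o[[nm]])
    }
    depth <- pmax(0, model$spheres$r - object_signed_distance(problem$object, centres))
    pen <- which(depth > 0)
    if (length(pen)) {
      gs <- object_signed_distance_grad(problem$object,
                                        centres[pen, , drop = FALSE])
      for (ii in seq_along(pen)) {
        m <- pen[ii]
        add_point(model$spheres$segment[m], centres[m, ],
                  -2 * w[2] * depth[m] * gs[ii, ])
      }
    }
  }

  g_p <- g_p + 2 * w[[3]] * (p - problem$base0$p)
  g_e <- g_e + 2 * w[[4]] * (e - problem$base0$e)
  g_q <- g_q + 2 * w[[5]] * (q - problem$q0)
  unname(c(g_p, g_e, g_q[act]))
}

#' Solve the inverse kinematics by a quasi-Newton method
#'
#' Minimizes L over the carpal pose and the active joint angles with
#' L-BFGS-B (box limits on joints, central-difference gradients). The
#' returned L never exceeds the initial one.
#'
#' @param problem an [ik_problem()].
#' @param init optional warm start `list(p =, e =, q =)`.
#' @param maxit iteration cap.
#' @param factr L-BFGS-B relative convergence tolerance.
#' @param gradient `"analytic"` (default) or `"numeric"` (central
#'   differences; the analytic gradient is validated against it in the test
#'   suite).
#' @param grad_h central-difference step for the numeric gradient.
#' @param optimize_base if `FALSE` the carpal pose is pinned at its initial
#'   value and only the active joint angles are optimized.
#' @return class `ik_solution`: `p`, `e`, `q` (full 21), `L`, `terms`,
#'   `converged`, `counts`.
#' @export
solve_ik <- function(problem, init = NULL, maxit = 500, factr = 1e4,
                     gradient = c("analytic", "numeric"), grad_h = 1e-6,
                     optimize_base = TRUE) {
  gradient <- match.arg(gradient)
  model <- problem$model
  act <- problem$active
  p0 <- if (is.null(init)) problem$base0$p else init$p
  e0 <- if (is.null(init)) problem$base0$e else init$e
  qfull <- if (is.null(init)) problem$q0 else init$q

  nb <- if (optimize_base) 6L else 0L
  unpack <- function(th) {
    q <- qfull
    q[act] <- th[nb + seq_along(act)]
    if (optimize_base) list(p = th[1:3], e = th[4:6], q = q)
    else list(p = p0, e = e0, q = q)
  }
  fn <- function(th) {
    st <- unpack(th)
    objective_L(problem, st$p, st$e, st$q)$L
  }
  gr <- if (gradient == "analytic") {
    function(th) {
      st <- unpack(th)
      g <- ik_gradient(problem, st$p, st$e, st$q)
      if (optimize_base) g else g[-(1:6)]
    }
  } else {
    function(th) {
      g <- numeric(length(th))
      for (i in seq_along(th)) {
        tp <- th; tm <- th
        tp[i] <- tp[i] + grad_h; tm[i] <- tm[i] - grad_h
        g[i] <- (fn(tp) - fn(tm)) / (2 * grad_h)
      }
      g
    }
  }

  lims <- sapply(model$joints[act], function(j) j$limits)
  lower <- c(rep(-Inf, nb), lims[1, ])
  upper <- c(rep(Inf, nb), lims[2, ])
  th0 <- c(if (optimize_base) c(p0, e0),
           pmin(pmax(qfull[act], lims[1, ]), lims[2, ]))

  L_init <- fn(th0)
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr))
  th <- if (opt$value <= L_init) opt$par else th0
  st <- unpack(th)
  ob <- objective_L(problem, st$p, st$e, st$q)
  structure(list(p = unname(st$p), e = unname(st$e), q = unname(st$q),
                 L = ob$L, terms = ob$terms,
                 converged = opt$convergence == 0,
                 counts = opt$counts, message = opt$message),
            class = "ik_solution")
}

#' @export
print.ik_solution <- function(x, ...) {
  cat("Inverse-kinematics solution: L =", format(x$L, digits = 6),
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  cat(" terms:", paste(names(x$terms),
                       format(x$terms, digits = 3), collapse = " | "), "\n")
  invisible(x)
}
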