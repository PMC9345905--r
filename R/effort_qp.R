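# Core effort-minimization quadratic program.
#
# Decision vector x = [f_1 ... f_n, a_1 ... a_37] stacks the contact forces
# and muscle activations. The objective is the muscle effort E = sum(a_i^2)
# (a positive-semidefinite quadratic; the force block carries no cost).
# Constraints: object force/moment equilibrium G f = [-m g; 0], the
# muscle-to-fingertip force balance J^T f - M^T F^max a = 0 over the 21
# actuated axes (the 6-DOF carpal base is unactuated and excluded),
# linearized friction N f <= 0, and activation bounds 0 <= a <= 1.
#
# The QP is convex but not strictly so in f; a tiny ridge (force_reg) on the
# force block makes it strictly convex and selects the minimum-norm force
# distribution among effort-optimal ones, which keeps solutions deterministic
# across backends. Two formulations of the same program are provided as
# mutually checking backends: the full stacked form and a null-space-reduced
# form that eliminates the equality constraints first.

#' Assemble a grasp QP
#'
#' @param J contact Jacobian, 3n x 21 (from [contact_jacobian()]).
#' @param muscle_set a [load_muscle_table()] result.
#' @param G grasp matrix, 6 x 3n.
#' @param N friction-facet matrix, 12n x 3n.
#' @param mass_kg object mass (kg).
#' @param gravity gravity vector (m/s^2, world frame).
#' @return an object of class `grasp_problem`.
#' @export
grasp_problem <- function(J, muscle_set, G, N, mass_kg,
                          gravity = c(0, 0, -9.81)) {
  n <- nrow(J) / 3
  if (n != round(n) || n < 1) stop("J must have 3n rows")
  nq <- ncol(J)
  if (ncol(G) != 3 * n) stop("G must have 3n columns")
  if (nrow(G) != 6) stop("G must have 6 rows")
  if (ncol(N) != 3 * n || nrow(N) != 12 * n)
    stop("N must be 12n x 3n")
  if (ncol(muscle_set$M) != nq)
    stop("Jacobian and moment-arm matrix disagree on the number of joints")
  structure(list(J = J, M = muscle_set$M, F_max = muscle_set$F_max,
                 G = G, N = N, mass_kg = mass_kg, gravity = gravity,
                 n = n),
            class = "grasp_problem")
}

qp_blocks <- function(problem) {
  n <- problem$n
  nf <- 3 * n
  na <- length(problem$F_max)
  MtF <- t(problem$M) %*% diag(problem$F_max)   # 21 x 37
  Aeq <- rbind(cbind(problem$G, matrix(0, 6, na)),
               cbind(t(problem$J), -MtF))
  beq <- c(-problem$mass_kg * problem$gravity, rep(0, 3),
           rep(0, ncol(problem$J)))
  Ain <- cbind(problem$N, matrix(0, 12 * n, na))
  list(nf = nf, na = na, Aeq = Aeq, beq = beq, Ain = Ain)
}

#' Solve the grasp effort-minimization QP
#'
#' Minimizes `E = sum(a^2)` (plus a `force_reg` ridge on f, see file notes)
#' subject to equilibrium, force balance, friction facets and activation
#' bounds. Any convex-QP backend must reproduce the optimal effort; the two
#' provided formulations are used to cross-check each other in the tests.
#'
#' @param problem a [grasp_problem()].
#' @param backend `"activeset"` (full stacked form) or `"nullspace"`
#'   (equalities eliminated through an orthonormal null-space basis first).
#' @param force_reg ridge weight on the force block.
#' @param f_bound box bound on each force component (N); must exceed any
#'   force the hand can produce, it only closes the feasible set.
#' @param tol feasibility tolerance for the reported status.
#' @return an object of class `grasp_qp` with elements `status`
#'   (`"optimal"`/`"infeasible"`), `E` (sum of squared activations), `f`
#'   (n x 3 contact forces, N), `a` (37 activations), `x`, and `residuals`
#'   (equality inf-norm, max facet violation, max bound violation).
#' @export
solve_grasp_qp <- function(problem, backend = c("activeset", "nullspace"),
                           force_reg = 1e-7, f_bound = 200, tol = 1e-8) {
  backend <- match.arg(backend)
  bl <- qp_blocks(problem)
  nf <- bl$nf; na <- bl$na
  nv <- nf + na
  lb <- c(rep(-f_bound, nf), rep(0, na))
  ub <- c(rep(f_bound, nf), rep(1, na))

  # substitute x = s * y so the objective x' diag(reg.., 1..) x becomes the
  # identity in y; all conditioning moves into the constraint matrix, which
  # the dual active-set method handles through its QR factorization
  s <- c(rep(1 / sqrt(2 * force_reg), nf), rep(1 / sqrt(2), na))

  x <- NULL
  if (backend == "activeset") {
    H <- rbind(bl$Aeq, -bl$Ain, diag(nv), -diag(nv))
    fv <- c(bl$beq, rep(0, nrow(bl$Ain)), lb, -ub)
    Hy <- t(t(H) * s)
    sol <- tryCatch(
      quadprog::solve.QP(diag(nv), rep(0, nv), t(Hy), fv,
                         meq = nrow(bl$Aeq)),
      error = function(e) NULL)
    if (!is.null(sol)) x <- s * sol$solution
  } else {
    Aeq_y <- t(t(bl$Aeq) * s)
    sv <- svd(Aeq_y, nv = nv)
    rk <- sum(sv$d > max(dim(Aeq_y)) * max(sv$d) * 1e-12)
    yp <- sv$v[, seq_len(rk), drop = FALSE] %*%
      ((t(sv$u[, seq_len(rk), drop = FALSE]) %*% bl$beq) / sv$d[seq_len(rk)])
    if (max(abs(Aeq_y %*% yp - bl$beq)) <
        tol * max(1, max(abs(bl$beq)))) {
      Z <- sv$v[, (rk + 1):nv, drop = FALSE]
      Dg <- s * Z                       # diag(s) %*% Z
      Ain_yZ <- t(t(bl$Ain) * s) %*% Z
      Ain_yp <- as.numeric(t(t(bl$Ain) * s) %*% yp)
      xp <- s * yp
      Amat <- rbind(-Ain_yZ, Dg, -Dg)
      bvec <- c(Ain_yp, lb - xp, xp - ub)
      # yp is orthogonal to the null space, so the reduced objective is t't
      sol <- tryCatch(
        quadprog::solve.QP(diag(ncol(Z)), rep(0, ncol(Z)), t(Amat), bvec),
        error = function(e) NULL)
      if (!is.null(sol)) x <- s * as.numeric(yp + Z %*% sol$solution)
    }
  }

  if (is.null(x)) {
    out <- list(status = "infeasible", E = NA_real_, f = NULL, a = NULL,
                x = NULL, residuals = NULL, backend = backend,
                problem = problem)
    class(out) <- "grasp_qp"
    return(out)
  }

  f <- x[seq_len(nf)]
  a <- x[nf + seq_len(na)]
  scale <- max(1, problem$mass_kg * sqrt(sum(problem$gravity^2)))
  resid <- c(equality = max(abs(bl$Aeq %*% x - bl$beq)),
             facet = max(c(bl$Ain %*% x, 0)),
             bounds = max(c(lb - x, x - ub, 0)))
  status <- if (resid["equality"] <= 1e-6 * scale &&
                resid["facet"] <= 1e-6 && resid["bounds"] <= 1e-6)
    "optimal" else "infeasible"
  a <- pmin(pmax(a, 0), 1)
  out <- list(status = status, E = sum(a^2),
              f = matrix(f, ncol = 3, byrow = TRUE),
              a = stats::setNames(a, names(problem$F_max)),
              x = x, residuals = resid, backend = backend,
              problem = problem)
  class(out) <- "grasp_qp"
  out
}

#' @export
print.grasp_qp <- function(x, ...) {
  cat("Grasp effort QP (", x$backend, " backend): ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(" muscle effort E =", format(x$E, digits = 6), "\n")
    cat(" max |activation| =", format(max(x$a), digits = 4),
        "; active muscles (a > 0.01):",
        paste(names(x$a)[x$a > 0.01], collapse = ", "), "\n")
    cat(" residuals: equality", format(x$residuals["equality"], digits = 3),
        "facet", format(x$residuals["facet"], digits = 3), "\n")
  }
  invisible(x)
}

#' @export
coef.grasp_qp <- function(object, ...) object$a

#' Infeasibility penalty for the outer posture search
#'
#' When no activation/force pattern satisfies the grasp constraints at a
#' candidate posture, the posture is scored by a large constant plus the sum
#' of squared deviations of the current joint angles from the initial
#' (natural) posture, so that any feasible posture outranks any infeasible
#' one and infeasible postures are still ordered by naturalness.
#'
#' @param q,q0 current and initial joint angle vectors (rad, length 21).
#' @param constant offset; the default 100 exceeds the largest possible
#'   effort (37, all muscles saturated).
#' @return penalty value of the effort objective.
#' @export
infeasibility_penalty <- function(q, q0, constant = 100) {
  if (length(q) != length(q0)) stop("q and q0 must have equal length")
  constant + sum((q - q0)^2)
}
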