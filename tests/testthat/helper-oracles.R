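# Independent multi-start nonlinear oracle for the effort QP.
#
# Eliminates the equality constraints through an orthonormal null-space
# basis, finds strictly feasible points by minimizing squared hinge
# violations from random starts, and then minimizes the exact effort
# sum(a^2) with the logarithmic-barrier solver constrOptim. Entirely
# independent of the quadratic-programming path under test.

nl_effort_oracle <- function(problem, nstarts = 50, seed = 1,
                             f_bound = 200) {
  bl <- gripsynth:::qp_blocks(problem)
  nv <- bl$nf + bl$na
  sv <- svd(bl$Aeq, nv = nv)
  rk <- sum(sv$d > max(dim(bl$Aeq)) * max(sv$d) * 1e-12)
  xp <- sv$v[, seq_len(rk), drop = FALSE] %*%
    ((t(sv$u[, seq_len(rk), drop = FALSE]) %*% bl$beq) / sv$d[seq_len(rk)])
  if (max(abs(bl$Aeq %*% xp - bl$beq)) > 1e-8) return(NA_real_)
  Z <- sv$v[, (rk + 1):nv, drop = FALSE]
  k <- ncol(Z)
  lb <- c(rep(-f_bound, bl$nf), rep(0, bl$na))
  ub <- c(rep(f_bound, bl$nf), rep(1, bl$na))
  Aall <- rbind(bl$Ain, diag(nv), -diag(nv))
  ball <- c(rep(0, nrow(bl$Ain)), ub, -lb)   # Aall x <= ball
  AZ <- Aall %*% Z
  b0 <- as.numeric(ball - Aall %*% xp)       # AZ t <= b0

  a_rows <- bl$nf + seq_len(bl$na)
  Za <- Z[a_rows, , drop = FALSE]
  ap <- as.numeric(xp[a_rows])
  fE <- function(t) { a <- ap + Za %*% t; sum(a^2) }
  gE <- function(t) as.numeric(2 * crossprod(Za, ap + Za %*% t))

  hinge <- function(t) sum(pmax(AZ %*% t - b0 + 1e-6, 0)^2)
  ghinge <- function(t) {
    v <- pmax(AZ %*% t - b0 + 1e-6, 0)
    as.numeric(2 * crossprod(AZ, v))
  }

  set.seed(seed)
  best <- Inf
  for (s in seq_len(nstarts)) {
    t0 <- rnorm(k, 0, 0.5)
    ph <- stats::optim(t0, hinge, ghinge, method = "BFGS",
                       control = list(maxit = 400, reltol = 1e-14))
    if (max(AZ %*% ph$par - b0) >= -1e-7) next   # not strictly feasible
    co <- tryCatch(
      stats::constrOptim(ph$par, fE, gE, ui = -AZ, ci = -b0,
                         method = "BFGS", outer.iterations = 40,
                         outer.eps = 1e-10,
                         control = list(maxit = 300, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(co) && co$value < best) best <- co$value
  }
  best
}
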