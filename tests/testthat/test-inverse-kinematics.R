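make_targets_at_current <- function(hand, base0 = base_pose()) {
  fk <- forward_kinematics(hand, hand$q0, base0)
  list(list(finger = "thumb", site = "tip",
            d0 = as.numeric(fingertip_site(fk, hand, "thumb", "tip"))),
       list(finger = "index", site = "tip",
            d0 = as.numeric(fingertip_site(fk, hand, "index", "tip"))))
}

test_that("objective vanishes at a state that already satisfies everything", {
  hand <- fixture_hand()
  prob <- ik_problem(hand, make_targets_at_current(hand))
  ob <- objective_L(prob, c(0, 0, 0), c(0, 0, 0), hand$q0)
  expect_equal(ob$L, 0, tolerance = 1e-18)
  expect_equal(sum(ob$terms), ob$L)
})

test_that("each penalty term isolates as its weighted quadratic", {
  hand <- fixture_hand()
  tg <- make_targets_at_current(hand)
  # only the joint-deviation weight active
  prob <- ik_problem(hand, tg, weights = c(0, 0, 0, 0, 0.7))
  dq <- rep(0, 21); dq[c(3, 9)] <- c(0.2, -0.1)
  ob <- objective_L(prob, c(0, 0, 0), c(0, 0, 0), hand$q0 + dq)
  expect_equal(ob$L, 0.7 * sum(dq^2), tolerance = 1e-12)
  # one target offset by 3 mm under w1 = 100: L = 100 * (0.003)^2
  tg2 <- tg
  tg2[[1]]$d0 <- tg2[[1]]$d0 + c(0, 0, 0.003)
  prob2 <- ik_problem(hand, tg2[1], weights = c(100, 0, 0, 0, 0))
  ob2 <- objective_L(prob2, c(0, 0, 0), c(0, 0, 0), hand$q0)
  expect_equal(ob2$L, 9e-4, tolerance = 1e-12)
})

test_that("analytic gradient of L matches central finite differences", {
  hand <- fixture_hand()
  obj <- fixture_device()
  base0 <- pinch_base_default(hand)
  tg <- list(list(finger = "thumb", site = "tip", d0 = c(0, -0.013, 0)),
             list(finger = "index", site = "pulp", d0 = c(0.002, 0.014, 0)))
  prob <- ik_problem(hand, tg, object = obj, base0 = base0,
                     active_joints = 1:9)
  set.seed(31)
  for (rep in 1:4) {
    p <- base0$p + rnorm(3, 0, 0.01)
    e <- base0$e + rnorm(3, 0, 0.05)
    q <- hand$q0; q[1:9] <- q[1:9] + rnorm(9, 0, 0.1)
    ga <- gripsynth:::ik_gradient(prob, p, e, q)
    th <- c(p, e, q[1:9])
    fn <- function(t2) {
      q2 <- hand$q0; q2[1:9] <- t2[7:15]
      objective_L(prob, t2[1:3], t2[4:6], q2)$L
    }
    gn <- sapply(seq_along(th), function(i) {
      h <- 1e-6; tp <- th; tm <- th
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (fn(tp) - fn(tm)) / (2 * h)
    })
    expect_equal(ga, gn, tolerance = 1e-6)
  }
})

test_that("solver leaves an already optimal state untouched", {
  hand <- fixture_hand()
  prob <- ik_problem(hand, make_targets_at_current(hand))
  sol <- solve_ik(prob)
  expect_lt(sol$L, 1e-12)
  expect_equal(sol$q, unname(hand$q0), tolerance = 1e-5)
})

test_that("two-hinge finger reaches a target consistently with the cosine rule", {
  hand <- fixture_hand()
  # actuate only index PIP and DIP (two parallel hinges): a planar 2-link arm
  # from the PIP centre, link 1 = middle phalanx, link 2 = DIP-to-site
  q_true <- hand$q0
  q_true[c(8, 9)] <- c(0.9, 0.5)
  fk_t <- forward_kinematics(hand, q_true, base_pose())
  target <- as.numeric(fingertip_site(fk_t, hand, "index", "tip"))
  tg <- list(list(finger = "index", site = "tip", d0 = target))
  prob <- ik_problem(hand, tg, weights = c(100, 0, 0, 0, 1e-6),
                     active_joints = c("pip2", "dip2"))
  init <- list(p = c(0, 0, 0), e = c(0, 0, 0),
               q = replace(hand$q0, c(8, 9), c(0.5, 0.2)))
  sol <- solve_ik(prob, init = init, maxit = 400, factr = 10,
                  optimize_base = FALSE)
  expect_lt(sqrt(sol$terms[["target"]] / 100), 1e-5)  # target reached
  expect_equal(sol$q[c(8, 9)], unname(q_true[c(8, 9)]), tolerance = 1e-4)

  # independent closed-form check: distance from the PIP centre to the
  # target fixes the elbow angle by the law of cosines
  fk0 <- forward_kinematics(hand, hand$q0, base_pose())
  L1 <- hand$segments[["mid2"]]$length
  site <- hand$fingertips[["index"]]$sites$tip$center
  L2 <- sqrt(sum(site^2))
  r2 <- sum((target - fk0$center[8, ])^2)
  # interior angle between the links; our DIP angle is its supplement offset
  cos_dip <- (r2 - L1^2 - L2^2) / (2 * L1 * L2)
  phi <- atan2(site[1], site[3])   # fixed palmar offset of the site vector
  expect_equal(as.numeric(cos(sol$q[9] + phi)), cos_dip, tolerance = 1e-4)
})

test_that("strong non-penetration halts the fingertip at the object surface", {
  hand <- fixture_hand()
  obj <- fixture_device()
  base0 <- pinch_base_default(hand)
  # target centre placed well inside the object
  tg <- list(list(finger = "index", site = "tip", d0 = c(0, 0.005, 0)))
  prob <- ik_problem(hand, tg, object = obj, base0 = base0,
                     weights = c(100, 1e4, 1, 1, 0.1), active_joints = 6:9)
  sol <- solve_ik(prob, maxit = 300)
  pen <- penetration_depths(hand, sol$q, list(p = sol$p, e = sol$e), obj)
  expect_lt(max(pen), 5e-4)   # all depths within half a millimetre

  # 1-D slice oracle: moving the converged state further along the target
  # approach direction only increases L (the minimum sits at the surface side)
  dirn <- c(0, 1, 0)
  Ls <- sapply(seq(-0.002, 0.004, by = 5e-4), function(s)
    objective_L(prob, sol$p + s * dirn, sol$e, sol$q)$L)
  expect_equal(which.min(Ls), which(seq(-0.002, 0.004, by = 5e-4) == 0))
})

test_that("accepted quasi-Newton steps never increase L", {
  hand <- fixture_hand()
  obj <- fixture_device()
  base0 <- pinch_base_default(hand)
  set.seed(37)
  for (i in 1:5) {
    tg <- list(list(finger = "thumb", site = "tip",
                    d0 = c(runif(1, -0.01, 0.01), -0.02, runif(1, -0.008, 0.008))),
               list(finger = "index", site = "tip",
                    d0 = c(runif(1, -0.01, 0.01), 0.02, runif(1, -0.008, 0.008))))
    prob <- ik_problem(hand, tg, object = obj, base0 = base0,
                       active_joints = 1:9)
    L0 <- objective_L(prob, base0$p, base0$e, hand$q0)$L
    sol <- solve_ik(prob, maxit = 120)
    expect_lte(sol$L, L0)
    expect_equal(sum(sol$terms), sol$L)
  }
})

test_that("solutions are equivariant under a rigid change of world frame", {
  hand <- fixture_hand()
  obj <- fixture_device()
  base0 <- pinch_base_default(hand)
  tg <- list(list(finger = "thumb", site = "tip", d0 = c(0, -0.02, 0)),
             list(finger = "index", site = "tip", d0 = c(0, 0.02, 0)))
  prob <- ik_problem(hand, tg, object = obj, base0 = base0, active_joints = 1:9)
  sol <- solve_ik(prob, maxit = 2000, factr = 1)

  # translation applied to targets, object and initial pose together:
  # the objective is invariant at mapped states and the mapped solution is
  # a fixed point of the translated problem
  t <- c(0.2, -0.1, 0.35)
  obj_t <- obj; obj_t$com <- obj$com + t
  obj_t$surfaces <- lapply(obj$surfaces, function(s) {
    s$origin <- s$origin + t; s })
  tg_t <- lapply(tg, function(x) { x$d0 <- x$d0 + t; x })
  prob_t <- ik_problem(hand, tg_t, object = obj_t,
                       base0 = base_pose(p = base0$p + t, e = base0$e),
                       active_joints = 1:9)
  expect_equal(objective_L(prob_t, sol$p + t, sol$e, sol$q)$L, sol$L,
               tolerance = 1e-9)
  sol_t <- solve_ik(prob_t, init = list(p = sol$p + t, e = sol$e, q = sol$q),
                    maxit = 2000, factr = 1)
  expect_equal(sol_t$L, sol$L, tolerance = 1e-6)
  expect_equal(sol_t$q, sol$q, tolerance = 1e-4)
  expect_equal(sol_t$p, sol$p + t, tolerance = 1e-4)

  # rotation of the whole frame (penetration off: the box distance is
  # frame-bound; the carpal-rotation penalty off: rotation-vector
  # differences are not conjugation-invariant)
  probR <- ik_problem(hand, tg, base0 = base0,
                      weights = c(100, 0, 1, 0, 0.1), active_joints = 1:9)
  solR0 <- solve_ik(probR, maxit = 2000, factr = 1)
  R <- gripsynth:::rotvec_to_R(c(0, 0, 0.9))
  tg_R <- lapply(tg, function(x) { x$d0 <- as.numeric(R %*% x$d0); x })
  eR0 <- gripsynth:::R_to_rotvec(R %*% gripsynth:::rotvec_to_R(base0$e))
  probR2 <- ik_problem(hand, tg_R,
                       base0 = base_pose(p = as.numeric(R %*% base0$p), e = eR0),
                       weights = c(100, 0, 1, 0, 0.1), active_joints = 1:9)
  eRs <- gripsynth:::R_to_rotvec(R %*% gripsynth:::rotvec_to_R(solR0$e))
  expect_equal(objective_L(probR2, as.numeric(R %*% solR0$p), eRs, solR0$q)$L,
               solR0$L, tolerance = 1e-9)
  solR <- solve_ik(probR2, init = list(p = as.numeric(R %*% solR0$p), e = eRs,
                                       q = solR0$q), maxit = 2000, factr = 1)
  expect_equal(solR$L, solR0$L, tolerance = 1e-6)
  expect_equal(solR$q, solR0$q, tolerance = 1e-3)
})
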