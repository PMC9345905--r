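test_that("grasp matrix stacks identity over cross-product blocks", {
  # single contact exactly at the COM: skew block is zero
  G0 <- grasp_matrix(list(list(point = c(0.01, 0.02, 0.03))),
                     com = c(0.01, 0.02, 0.03))
  expect_equal(G0[4:6, ], matrix(0, 3, 3))
  expect_equal(G0[1:3, ], diag(3))

  # hand-computed moment: r = (0,0,0.1), f = (1,0,0) -> r x f = (0, 0.1, 0)
  G <- grasp_matrix(list(list(point = c(0, 0, 0.1))))
  expect_equal(as.numeric(G[4:6, ] %*% c(1, 0, 0)), c(0, 0.1, 0))

  # dimensions: n = 2 -> 6 x 6
  G2 <- grasp_matrix(list(list(point = c(0.1, 0, 0)),
                          list(point = c(-0.1, 0, 0))))
  expect_equal(dim(G2), c(6, 6))

  # moment rows reproduce sum r_k x f_k on random inputs
  set.seed(11)
  for (i in 1:20) {
    pts <- lapply(1:3, function(k) list(point = rnorm(3)))
    com <- rnorm(3)
    f <- rnorm(9)
    G <- grasp_matrix(pts, com)
    manual <- Reduce(`+`, lapply(1:3, function(k)
      gripsynth:::cross3(pts[[k]]$point - com, f[(3 * k - 2):(3 * k)])))
    expect_equal(as.numeric(G[4:6, ] %*% f), manual, tolerance = 1e-12)
  }
  expect_error(grasp_matrix(list()), "at least one")
})

test_that("friction pyramid admits the cone axis and rejects tangential force", {
  p <- friction_pyramid(c(0, 0, 1), 0.4)
  expect_equal(nrow(p$facets), 12)
  expect_true(all(p$facets %*% c(0, 0, 1) < 0))       # axis strictly inside
  expect_true(any(p$facets %*% c(1, 0, 0) > 0))       # pure tangential outside
  expect_error(friction_pyramid(c(0, 0, 0), 0.4), "zero")
  expect_error(friction_pyramid(c(0, 0, 1), -0.1), "non-negative")
})

test_that("pyramid edge rays lie on exactly two adjacent facets", {
  p <- friction_pyramid(c(0.2, -0.5, 0.7), 0.35)
  th <- atan(0.35)
  for (k in 0:11) {
    ed <- cos(k * pi / 6) * p$t1 + sin(k * pi / 6) * p$t2
    ray <- cos(th) * p$axis + sin(th) * ed
    prods <- p$facets %*% ray
    expect_equal(sum(abs(prods) < 1e-10), 2)
    expect_true(all(prods < 1e-10))
  }
})

test_that("inscribed pyramid is conservative for the exact cone", {
  set.seed(5)
  normals <- matrix(rnorm(9), 3)
  for (i in 1:3) {
    n <- normals[, i] / sqrt(sum(normals[, i]^2))
    mu <- c(0.2, 0.4, 0.9)[i]
    p <- friction_pyramid(n, mu)
    f <- matrix(rnorm(3 * 1e4), ncol = 3)
    inside_pyr <- rowSums((f %*% t(p$facets)) > 0) == 0
    fn <- as.numeric(f %*% n)
    ft <- sqrt(pmax(rowSums(f^2) - fn^2, 0))
    inside_cone <- fn > 0 & ft <= mu * fn + 1e-12
    expect_true(all(!inside_pyr | inside_cone))
    # the inscribed margin: ratio <= mu cos(pi/12) is always admitted
    ok <- fn > 0 & ft <= mu * cos(pi / 12) * fn - 1e-9
    expect_true(all(!ok | inside_pyr))
  }
})

test_that("soft contact pair sits 2 mm either side of the centroid", {
  pr <- soft_contact_pair(c(0.01, 0.02, 0), c(0, 1, 0), c(1, 0, 0.4))
  d <- sapply(pr, function(ct) sqrt(sum((ct$point - c(0.01, 0.02, 0))^2)))
  expect_equal(d, c(0.002, 0.002))
  expect_equal((pr[[1]]$point + pr[[2]]$point) / 2, c(0.01, 0.02, 0))
  # both points stay in the contact plane
  expect_equal(sapply(pr, function(ct) sum((ct$point - c(0.01, 0.02, 0)) * c(0, 1, 0))),
               c(0, 0))
  # equal and opposite tangential forces F produce the couple 0.004 F
  Fmag <- 2.5
  lat <- (pr[[2]]$point - pr[[1]]$point) / 0.004
  tang <- gripsynth:::cross3(c(0, 1, 0), lat)
  m <- gripsynth:::cross3(pr[[1]]$point - c(0.01, 0.02, 0), -Fmag * tang) +
    gripsynth:::cross3(pr[[2]]$point - c(0.01, 0.02, 0), Fmag * tang)
  expect_equal(abs(sum(m * c(0, 1, 0))), 0.004 * Fmag, tolerance = 1e-12)
  expect_error(soft_contact_pair(c(0, 0, 0), c(0, 1, 0), c(0, 1, 0)),
               "parallel")
})

test_that("facet matrix is block diagonal and equivalent to per-contact checks", {
  pyr <- list(friction_pyramid(c(0, 1, 0), 0.4),
              friction_pyramid(c(0, -1, 0), 0.4))
  N <- assemble_facet_matrix(pyr)
  expect_equal(dim(N), c(24, 6))
  expect_true(all(N[1:12, 4:6] == 0))
  expect_true(all(N[13:24, 1:3] == 0))
  set.seed(13)
  for (i in 1:50) {
    f <- rnorm(6)
    per <- all(pyr[[1]]$facets %*% f[1:3] <= 0) &&
      all(pyr[[2]]$facets %*% f[4:6] <= 0)
    expect_equal(all(N %*% f <= 0), per)
  }
})

test_that("planner halves the perceived friction coefficient", {
  expect_equal(effective_mu(0.8), 0.4)
  expect_equal(effective_mu(0), 0)
  expect_equal(effective_mu(1.0), 0.5)
  expect_error(effective_mu(-0.2), "non-negative")
})

test_that("sensing device fixture matches its physical description", {
  obj <- fixture_device()
  expect_equal(obj$mass_kg, 0.1984)
  expect_length(obj$surfaces, 2)
  s <- obj$surfaces[[1]]
  expect_equal(2000 * c(s$half_u, s$half_v), c(49, 20))
  expect_equal(obj$mu_actual, 0.8)
  # plates 40 mm apart, normals opposing and unit
  expect_equal(sum(obj$surfaces[[1]]$origin * c(0, 1, 0)), -0.020)
  expect_equal(obj$surfaces[[1]]$normal, -obj$surfaces[[2]]$normal)
  expect_error(rigid_object(-1, mu_actual = 0.5, half_extents = c(1, 1, 1),
                            surfaces = list()), "non-negative")
})

test_that("box signed distance and its gradient agree with finite differences", {
  obj <- fixture_device()
  set.seed(17)
  pts <- cbind(runif(40, -0.05, 0.05), runif(40, -0.05, 0.05),
               runif(40, -0.05, 0.05))
  g <- object_signed_distance_grad(obj, pts)
  h <- 1e-7
  for (i in sample(40, 10)) {
    gn <- sapply(1:3, function(j) {
      e <- rep(0, 3); e[j] <- h
      (object_signed_distance(obj, matrix(pts[i, ] + e, 1)) -
         object_signed_distance(obj, matrix(pts[i, ] - e, 1))) / (2 * h)
    })
    expect_equal(as.numeric(g[i, ]), gn, tolerance = 1e-5)
  }
})
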