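# Shared fixtures built in code. The hand/object pair is the packaged
# sensing-device pinch scenario; the planar toy is a hand-auditable
# two-contact problem used as an independent oracle for the effort QP.

fixture_hand <- local({
  h <- NULL
  function() {
    if (is.null(h)) h <<- build_parametric_hand()
    h
  }
})

fixture_device <- function() sensing_device()

# a custom "muscle set" with arbitrary dimensions (the QP layer is generic
# in the number of joints and muscles)
toy_muscle_set <- function(M, F_max) {
  structure(list(M = M, F_max = F_max), class = "muscle_set")
}

# planar toy: point mass held between two opposing horizontal contacts,
# one actuated joint per side driven by an antagonist muscle pair with
# 10 mm arms. Given the contact forces, the optimal activations have the
# closed form a_agonist = |tau|/(arm * F_max), a_antagonist = 0, so the
# whole problem reduces to a low-dimensional search over the statically
# indeterminate force components - which a dense grid can scan.
planar_toy <- function(mass_kg = 1, d = 0.05, mu = 0.5,
                       arm = 0.01, fmax = 50) {
  contacts <- list(list(point = c(-d, 0, 0), normal = c(1, 0, 0)),
                   list(point = c(d, 0, 0), normal = c(-1, 0, 0)))
  # joint 1 moves contact 1 along (0.3, 0, 1), joint 2 contact 2 along
  # (-0.3, 0, 1): the torque demand then depends on the statically
  # indeterminate squeeze force, so the effort is a nontrivial function of it
  J <- matrix(0, 6, 2)
  J[1:3, 1] <- c(0.3, 0, 1)
  J[4:6, 2] <- c(-0.3, 0, 1)
  M <- rbind(c(arm, 0), c(-arm, 0), c(0, arm), c(0, -arm))
  ms <- toy_muscle_set(M, rep(fmax, 4))
  G <- grasp_matrix(contacts)
  N <- assemble_facet_matrix(lapply(contacts, function(ct)
    friction_pyramid(ct$normal, mu)))
  list(problem = grasp_problem(J, ms, G, N, mass_kg),
       contacts = contacts, arm = arm, fmax = fmax, mu = mu,
       mass_kg = mass_kg, d = d)
}
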