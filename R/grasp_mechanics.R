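# Object-side statics of the grasp.
#
# The grasped object is rigid, described by its mass, centre of mass,
# friction coefficient and planar contact patches. The equilibrium map is the
# 6 x 3n grasp matrix G (identity blocks over skew blocks S(r_k)); Coulomb
# friction cones of apex angle atan(mu) are linearized as inscribed
# twelve-sided pyramids; torsion transmitted by the fingertip pad ("soft
# contact") is emulated by a pair of contact points 2 mm either side of the
# contact centroid.

#' Rigid object with planar contact surfaces
#'
#' @param mass_kg object mass (kg).
#' @param com centre of mass in the object frame (m).
#' @param mu_actual actual Coulomb friction coefficient of the surfaces.
#' @param half_extents half-widths of the bounding box used for the signed
#'   distance (m, object frame, centred on `com`).
#' @param surfaces list of planar patches; each has `origin` (patch centre,
#'   m), `normal` (unit, pointing into the object, i.e. the direction a
#'   fingertip presses), in-plane axes `u` and `v` (unit, m) and `half_u`,
#'   `half_v` patch half-extents (m).
#' @param gravity gravitational acceleration vector (m/s^2, world frame).
#' @return an object of class `rigid_object`.
#' @export
rigid_object <- function(mass_kg, com = c(0, 0, 0), mu_actual,
                         half_extents, surfaces,
                         gravity = c(0, 0, -9.81)) {
  if (mass_kg < 0) stop("mass must be non-negative")
  if (mu_actual < 0) stop("friction coefficient must be non-negative")
  for (s in surfaces) {
    if (abs(sqrt(sum(s$normal^2)) - 1) > 1e-9)
      stop("surface normal must be unit length")
  }
  obj <- list(mass_kg = mass_kg, com = as.numeric(com),
              mu_actual = mu_actual,
              half_extents = as.numeric(half_extents),
              surfaces = surfaces, gravity = as.numeric(gravity))
  class(obj) <- "rigid_object"
  obj
}

#' The packaged fingertip force-sensing device fixture
#'
#' A 198.4 g box-shaped device with two parallel vertical grasp plates of
#' 20 mm x 49 mm, mounted on opposite sides and held with the long plate
#' axis horizontal (pinching toward either end of a plate therefore offsets
#' the grip horizontally from the centre of mass and demands a torsional
#' couple). Plate separation and friction coefficient are configurable; the
#' friction default corresponds to the worked safety-margin example (actual
#' mu 0.8, halved to 0.4 by the grasp planner).
#'
#' @param mass_g device mass in grams.
#' @param plate_mm plate in-plane dimensions, `c(width, height)` in mm.
#' @param separation_mm distance between the two plates (mm).
#' @param mu_actual actual friction coefficient of the plates.
#' @return a [rigid_object()] whose surfaces 1 (thumb side, y < 0) and 2
#'   (index side, y > 0) are the plates; in-plane `u` is the long axis,
#'   horizontal (+x, "far/near" direction), `v` the short axis, vertical
#'   (+z).
#' @export
sensing_device <- function(mass_g = 198.4, plate_mm = c(20, 49),
                           separation_mm = 40, mu_actual = 0.8) {
  hw <- separation_mm / 2000
  hu <- plate_mm[2] / 2000   # long (horizontal) half-extent
  hv <- plate_mm[1] / 2000   # short (vertical) half-extent
  surf <- function(side) {    # side -1 = thumb plate, +1 = index plate
    list(origin = c(0, side * hw, 0),
         normal = c(0, -side, 0),
         u = c(1, 0, 0), v = c(0, 0, 1),
         half_u = hu, half_v = hv)
  }
  rigid_object(mass_kg = mass_g / 1000, com = c(0, 0, 0),
               mu_actual = mu_actual,
               half_extents = c(hu, hw, hv),
               surfaces = list(thumb = surf(-1), index = surf(+1)))
}

#' @export
print.rigid_object <- function(x, ...) {
  cat("Rigid object:", x$mass_kg * 1000, "g, mu =", x$mu_actual, ",",
      length(x$surfaces), "contact surface(s)\n")
  invisible(x)
}

#' Signed distance from points to the object
#'
#' Box signed distance in the object frame (negative inside), evaluated
#' rowwise.
#'
#' @param object a [rigid_object()].
#' @param points n x 3 matrix of points (m, object frame).
#' @return numeric vector of n signed distances (m).
#' @export
object_signed_distance <- function(object, points) {
  p <- matrix(points, ncol = 3)
  h <- object$half_extents
  q1 <- abs(p[, 1] - object$com[1]) - h[1]
  q2 <- abs(p[, 2] - object$com[2]) - h[2]
  q3 <- abs(p[, 3] - object$com[3]) - h[3]
  outside <- sqrt(pmax(q1, 0)^2 + pmax(q2, 0)^2 + pmax(q3, 0)^2)
  inside <- pmin(pmax(q1, q2, q3), 0)
  outside + inside
}

#' Gradient of the object signed distance
#'
#' Rowwise gradient of [object_signed_distance()] with respect to the point
#' (unit outward direction; on the inside, the outward direction of the
#' nearest face). Kinks of the box distance (edges, centre) have measure
#' zero and are resolved arbitrarily.
#'
#' @inheritParams object_signed_distance
#' @return n x 3 matrix of gradients.
#' @export
object_signed_distance_grad <- function(object, points) {
  p <- matrix(points, ncol = 3)
  n <- nrow(p)
  pc <- sweep(p, 2, object$com)
  q <- abs(pc) - rep(object$half_extents, each = n)
  qp <- pmax(q, 0)
  out <- sqrt(rowSums(qp^2))
  g <- matrix(0, n, 3)
  outside <- out > 0
  if (any(outside)) {
    g[outside, ] <- (qp[outside, , drop = FALSE] / out[outside]) *
      sign(pc[outside, , drop = FALSE])
  }
  if (any(!outside)) {
    for (i in which(!outside)) {
      j <- which.max(q[i, ])
      g[i, j] <- sign(pc[i, j])
      if (pc[i, j] == 0) g[i, j] <- 1
    }
  }
  g
}

#' Point on a planar contact patch
#' @param surface one element of `object$surfaces`.
#' @param u,v in-plane coordinates (m) from the patch centre.
#' @export
surface_point <- function(surface, u, v) {
  surface$origin + u * surface$u + v * surface$v
}

#' Grasp matrix G
#'
#' The 6 x 3n map from stacked contact forces to net object force and moment
#' about the centre of mass: identity blocks on top, skew blocks `S(r_k)`
#' (with `S(r) f = r x f`) below, `r_k` running from the COM to contact k.
#'
#' @param contacts list of contacts, each with `point` (m, object frame).
#' @param com centre of mass (m, object frame).
#' @return a 6 x 3n matrix.
#' @export
grasp_matrix <- function(contacts, com = c(0, 0, 0)) {
  n <- length(contacts)
  if (n < 1) stop("at least one contact is required")
  G <- matrix(0, 6, 3 * n)
  for (k in seq_len(n)) {
    cols <- (3 * k - 2):(3 * k)
    r <- contacts[[k]]$point - com
    G[1:3, cols] <- diag(3)
    G[4:6, cols] <- skew3(r)
  }
  G
}

#' Linearized friction cone (inscribed twelve-sided pyramid)
#'
#' The Coulomb cone of apex half-angle `atan(mu_eff)` about the inward
#' contact normal is approximated from the inside: the pyramid's edge rays
#' lie exactly on the cone at twelve equal azimuths, so every force admitted
#' by the pyramid is admitted by the exact cone (conservative, preserving the
#' no-slip guarantee). A force f is admissible iff `n_h . f <= 0` for all
#' twelve outward facet normals `n_h`.
#'
#' @param normal inward contact normal (direction of admissible pressing).
#' @param mu_eff effective friction coefficient used by the planner.
#' @return class `friction_pyramid`: 12 x 3 matrix `facets` of outward facet
#'   normals, plus the `axis`, `mu_eff` and tangent basis used.
#' @export
friction_pyramid <- function(normal, mu_eff) {
  if (mu_eff < 0) stop("mu_eff must be non-negative")
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("zero contact normal")
  axis <- normal / nrm
  # tangent basis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- unitize(cross3(axis, ref))
  t2 <- cross3(axis, t1)
  phi <- 2 * pi * (0:11) / 12
  # edge rays on the exact cone: axis + mu_eff * (cos(phi) t1 + sin(phi) t2)
  edges <- t(sapply(phi, function(p) axis + mu_eff * (cos(p) * t1 + sin(p) * t2)))
  facets <- matrix(NA_real_, 12, 3)
  for (h in 1:12) {
    e1 <- edges[h, ]; e2 <- edges[if (h == 12) 1 else h + 1, ]
    nh <- cross3(e1, e2)
    if (max(abs(nh)) < 1e-14) {          # mu_eff = 0: cone degenerates to the ray
      nh <- -(cos(phi[h] + pi / 12) * t1 + sin(phi[h] + pi / 12) * t2)
    }
    nh <- unitize(nh)
    if (sum(nh * axis) > 0) nh <- -nh    # outward: axis strictly inside
    facets[h, ] <- nh
  }
  structure(list(facets = facets, axis = axis, mu_eff = mu_eff,
                 t1 = t1, t2 = t2),
            class = "friction_pyramid")
}

#' Soft-contact point pair for a fingertip pad
#'
#' Torsion about the contact normal transmitted by the deformable fingertip
#' pad is emulated by two contact points placed in the contact plane, 2 mm
#' either side of the contact centroid along a lateral axis.
#'
#' @param centroid contact-area centroid (m).
#' @param normal inward contact normal.
#' @param lateral_axis direction (need not be unit or in-plane) along which
#'   the pair is split; its projection onto the contact plane is used.
#' @param segment owning hand segment name (carried through to the Jacobian).
#' @param offset half-separation of the pair (m); 2 mm.
#' @return list of two contacts (`point`, `normal`, `segment`,
#'   `is_soft_pair = TRUE`).
#' @export
soft_contact_pair <- function(centroid, normal, lateral_axis,
                              segment = NA_character_, offset = 0.002) {
  nrm <- unitize(normal)
  lat <- lateral_axis - sum(lateral_axis * nrm) * nrm
  if (sqrt(sum(lat^2)) < 1e-9)
    stop("lateral axis is (nearly) parallel to the contact normal")
  lat <- unitize(lat)
  lapply(c(-1, 1), function(s)
    list(point = centroid + s * offset * lat, normal = nrm,
         segment = segment, is_soft_pair = TRUE))
}

#' Stacked friction-facet matrix N
#'
#' Block-diagonal stacking of the per-contact 12 x 3 facet-normal blocks;
#' `N f <= 0` is equivalent to all per-contact pyramid conditions.
#'
#' @param pyramids list of [friction_pyramid()] objects, one per contact.
#' @return a 12n x 3n matrix.
#' @export
assemble_facet_matrix <- function(pyramids) {
  n <- length(pyramids)
  N <- matrix(0, 12 * n, 3 * n)
  for (k in seq_len(n)) {
    N[(12 * k - 11):(12 * k), (3 * k - 2):(3 * k)] <- pyramids[[k]]$facets
  }
  N
}

#' Planner's effective friction coefficient
#'
#' The grasp planner keeps a safety margin against slip by planning with half
#' the actual friction coefficient (an actual mu of 0.8 is treated as 0.4).
#'
#' @param mu_actual actual surface friction coefficient (>= 0).
#' @return `mu_actual / 2`.
#' @export
effective_mu <- function(mu_actual) {
  if (any(mu_actual < 0)) stop("friction coefficient must be non-negative")
  mu_actual / 2
}
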