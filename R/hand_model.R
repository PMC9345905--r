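# Parametric 21-segment hand kinematic chain.
#
# The hand is a chain of 21 rigid bone segments (forearm, carpus, metacarpals
# 1-5, 14 phalanges) with 21 actuated revolute axes: the thumb has CMC1
# flexion-extension + adduction-abduction, MP1 flexion-extension +
# adduction-abduction and IP1 flexion-extension; each finger 2-5 has MP
# flexion-extension + adduction-abduction, PIP and DIP. CMC joints 2-5 are
# immobile. The palmar skin is approximated by 65 spheres used for
# non-penetration penalties. Geometry is parametric (configurable segment
# lengths and axes) because subject-specific CT geometry is not portable;
# defaults follow a generic anthropometric hand of ~19 cm length.
#
# Segment frames: +x dorso-palmar (palmar positive), +y radial-to-ulnar,
# +z proximo-distal (along the bone). Flexion-extension axes are local +y
# (positive angle = flexion, tipping the bone palmarly), adduction-abduction
# axes local +x. Two-DOF joints compose flexion-extension first, then
# adduction-abduction about the flexed frame (intrinsic composition).

FINGER_NAMES <- c("thumb", "index", "middle", "ring", "little")

JOINT_NAMES <- c(
  "cmc1_fe", "cmc1_aa", "mp1_fe", "mp1_aa", "ip1_fe",
  "mp2_fe", "mp2_aa", "pip2", "dip2",
  "mp3_fe", "mp3_aa", "pip3", "dip3",
  "mp4_fe", "mp4_aa", "pip4", "dip4",
  "mp5_fe", "mp5_aa", "pip5", "dip5")

SEGMENT_NAMES <- c(
  "carpus", "forearm",
  paste0("mc", 1:5),           # metacarpals
  paste0("pp", 1:5),           # proximal phalanges
  paste0("mid", 2:5),          # middle phalanges (fingers only)
  paste0("dp", 1:5))           # distal phalanges

#' Default parametric hand geometry configuration
#'
#' Returns the packaged geometry for a generic adult hand of about 19 cm
#' length: segment lengths, metacarpal base offsets and mounting rotations in
#' the carpal frame, skin-sphere layout (65 spheres) and joint limits. All
#' linear dimensions are in millimetres in the config (converted to metres at
#' build time) and scale jointly with `hand_scale`.
#'
#' @param hand_scale multiplicative scale applied to every linear dimension
#'   (1 = the packaged ~19 cm hand).
#' @param joint_limits logical; include box limits on the joint angles.
#' @return a list understood by [build_parametric_hand()].
#' @export
hand_geometry_default <- function(hand_scale = 1, joint_limits = TRUE) {
  lengths <- c(
    forearm = 250, carpus = 35,
    mc1 = 45, mc2 = 70, mc3 = 67, mc4 = 60, mc5 = 55,
    pp1 = 32, pp2 = 45, pp3 = 50, pp4 = 46, pp5 = 36,
    mid2 = 25, mid3 = 30, mid4 = 28, mid5 = 20,
    dp1 = 25, dp2 = 23, dp3 = 25, dp4 = 24, dp5 = 22)

  mc_base <- rbind(  # carpal-frame origin of each metacarpal [mm]
    mc1 = c(12, -22, 15),
    mc2 = c(8, -12, 32),
    mc3 = c(6, 0, 33),
    mc4 = c(4, 11, 31),
    mc5 = c(2, 22, 28))

  # thumb column mounting: bone axis palmar-radial-distal, pad facing
  # ulnar-palmar so that flexion opposes the fingers
  z1 <- unitize(c(0.45, -0.55, 0.70))
  u <- c(0.60, 0.80, 0)
  x1 <- unitize(u - sum(u * z1) * z1)
  y1 <- cross3(z1, x1)
  mount_mc1 <- cbind(x1, y1, z1)

  splay <- c(mc2 = 3, mc3 = 0, mc4 = -3, mc5 = -6) * pi / 180

  radii <- c(forearm = 25, carpus = 14,
             mc1 = 11, mc2 = 10, mc3 = 10, mc4 = 9.5, mc5 = 9,
             pp1 = 9, pp2 = 8.5, pp3 = 8.5, pp4 = 8, pp5 = 7.5,
             mid2 = 7.5, mid3 = 7.5, mid4 = 7, mid5 = 6.5,
             dp1 = 8, dp2 = 7, dp3 = 7, dp4 = 6.5, dp5 = 6)

  # fractions of segment length at which skin spheres sit (along local +z);
  # counts sum to 65
  sphere_frac <- list(
    forearm = c(0.08, 0.20),
    carpus = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.75, 0.75, 0.75, 0.75, 0.75),
    mc = c(0.25, 0.55, 0.85),
    pp = c(0.20, 0.50, 0.80),
    mid = c(0.30, 0.70),
    dp = c(0.25, 0.60, NA))  # NA = tip sphere, centred at L - r
  carpus_y <- c(-20, -10, 0, 10, 20, -20, -10, 0, 10, 20)  # palm spread [mm]

  limits <- NULL
  if (joint_limits) {
    limits <- rbind(
      cmc1_fe = c(-0.60, 1.20), cmc1_aa = c(-0.60, 0.60),
      mp1_fe = c(-0.20, 1.20), mp1_aa = c(-0.50, 0.50),
      ip1_fe = c(-0.20, 1.50))
    for (f in 2:5) {
      limits <- rbind(limits,
        c(-0.50, 1.60), c(-0.45, 0.45), c(-0.10, 1.90), c(-0.20, 1.40))
    }
    rownames(limits) <- JOINT_NAMES
    colnames(limits) <- c("lower", "upper")
  }

  # natural pre-pinch posture: thumb opposed, index moderately flexed (the
  # distal segments then meet the grasped surfaces nearly bone-on, which is
  # how fingertip forces are transmitted efficiently); uninvolved fingers
  # curled fully toward the palm and out of the way
  q0 <- c(0.50, 0.15, 0.30, 0.00, 0.30,
          0.90, 0.00, 0.70, 0.30,
          rep(c(1.45, 0.00, 1.60, 0.90), 3))
  names(q0) <- JOINT_NAMES

  list(hand_scale = hand_scale,
       segment_lengths_mm = lengths,
       mc_base_mm = mc_base,
       mount_mc1 = mount_mc1,
       splay_rad = splay,
       sphere_radii_mm = radii,
       sphere_frac = sphere_frac,
       carpus_sphere_y_mm = carpus_y,
       joint_limits = limits,
       q0 = q0)
}

#' Build the parametric hand musculoskeletal chain
#'
#' Assembles the 21-segment, 21-DOF hand model with its 65-sphere skin proxy
#' from a geometry configuration (see [hand_geometry_default()]). The model is
#' deterministic for a fixed configuration.
#'
#' @param config geometry configuration list; defaults to the packaged hand.
#' @return an object of class `hand_model` with elements `segments` (parent,
#'   offset, mount per segment), `joints` (owning segment, local axis, limits),
#'   `fingertips` (distal-segment contact sites), `spheres` (65 x 5 table) and
#'   `q0` (neutral posture, rad).
#' @export
build_parametric_hand <- function(config = hand_geometry_default()) {
  s <- config$hand_scale
  if (!is.numeric(s) || s <= 0) stop("hand_scale must be positive")
  len <- config$segment_lengths_mm * s / 1000
  if (any(len <= 0)) stop("non-positive segment length")
  mc_base <- config$mc_base_mm * s / 1000
  radii <- config$sphere_radii_mm * s / 1000

  if (abs(det(config$mount_mc1) - 1) > 1e-8 ||
      max(abs(crossprod(config$mount_mc1) - diag(3))) > 1e-8)
    stop("malformed thumb mounting rotation (not a rotation matrix)")

  segments <- list()
  seg <- function(name, parent, offset, mount) {
    segments[[name]] <<- list(name = name, parent = parent,
                              offset = offset, mount = mount,
                              length = unname(len[name]))
  }
  Rx <- function(a) rot_axis(c(1, 0, 0), a)
  flip <- rot_axis(c(1, 0, 0), pi)  # forearm z points proximal

  seg("carpus", NA, c(0, 0, 0), diag(3))
  seg("forearm", "carpus", c(0, 0, 0), flip)
  seg("mc1", "carpus", mc_base["mc1", ], config$mount_mc1)
  for (f in 2:5) {
    nm <- paste0("mc", f)
    seg(nm, "carpus", mc_base[nm, ], Rx(config$splay_rad[[nm]]))
  }
  for (f in 1:5) {
    seg(paste0("pp", f), paste0("mc", f), c(0, 0, len[paste0("mc", f)]), diag(3))
  }
  for (f in 2:5) {
    seg(paste0("mid", f), paste0("pp", f), c(0, 0, len[paste0("pp", f)]), diag(3))
  }
  seg("dp1", "pp1", c(0, 0, len["pp1"]), diag(3))
  for (f in 2:5) {
    seg(paste0("dp", f), paste0("mid", f), c(0, 0, len[paste0("mid", f)]), diag(3))
  }
  segments <- segments[SEGMENT_NAMES]

  ax_fe <- c(0, 1, 0)
  ax_aa <- c(1, 0, 0)
  joints <- list(
    cmc1_fe = list(segment = "mc1", axis = ax_fe),
    cmc1_aa = list(segment = "mc1", axis = ax_aa),
    mp1_fe = list(segment = "pp1", axis = ax_fe),
    mp1_aa = list(segment = "pp1", axis = ax_aa),
    ip1_fe = list(segment = "dp1", axis = ax_fe))
  for (f in 2:5) {
    joints[[paste0("mp", f, "_fe")]] <- list(segment = paste0("pp", f), axis = ax_fe)
    joints[[paste0("mp", f, "_aa")]] <- list(segment = paste0("pp", f), axis = ax_aa)
    joints[[paste0("pip", f)]] <- list(segment = paste0("mid", f), axis = ax_fe)
    joints[[paste0("dip", f)]] <- list(segment = paste0("dp", f), axis = ax_fe)
  }
  joints <- joints[JOINT_NAMES]
  for (j in seq_along(joints)) {
    a <- joints[[j]]$axis
    if (abs(sqrt(sum(a^2)) - 1) > 1e-10) stop("malformed joint axis")
    joints[[j]]$axis_id <- if (all(a == c(1, 0, 0))) 1L
                           else if (all(a == c(0, 1, 0))) 2L else 0L
    joints[[j]]$limits <-
      if (is.null(config$joint_limits)) c(-Inf, Inf)
      else unname(config$joint_limits[JOINT_NAMES[j], ])
  }

  # segment -> joints rotating it (in order applied); and root->segment joint path
  seg_joints <- stats::setNames(vector("list", length(SEGMENT_NAMES)), SEGMENT_NAMES)
  for (j in seq_along(joints)) {
    sg <- joints[[j]]$segment
    seg_joints[[sg]] <- c(seg_joints[[sg]], j)
  }
  joint_path <- stats::setNames(vector("list", length(SEGMENT_NAMES)), SEGMENT_NAMES)
  for (nm in SEGMENT_NAMES) {
    path <- integer(0)
    cur <- nm
    while (!is.na(cur)) {
      path <- c(seg_joints[[cur]], path)
      cur <- segments[[cur]]$parent
    }
    joint_path[[nm]] <- path
  }

  # fingertip contact sites: contact is transmitted through the distal skin
  # spheres, so a site is a sphere (centre in segment frame + radius); the
  # "tip" site is the terminal sphere, the "pulp" site the mid-pad sphere
  fingertips <- list()
  for (f in 1:5) {
    dseg <- paste0("dp", f)
    L <- len[dseg]; r <- radii[[dseg]]
    fingertips[[FINGER_NAMES[f]]] <- list(
      segment = dseg,
      apex = c(0, 0, L),
      sites = list(tip = list(center = c(0, 0, L - r), r = r),
                   pulp = list(center = c(0, 0, 0.6 * L), r = r)))
  }

  # skin spheres: 65 rows (segment, centre in segment frame, radius)
  sph <- list()
  add_sph <- function(segment, centre, r)
    sph[[length(sph) + 1]] <<- data.frame(segment = segment,
      cx = centre[1], cy = centre[2], cz = centre[3], r = r)
  fr <- config$sphere_frac
  for (i in seq_along(fr$forearm))
    add_sph("forearm", c(0, 0, fr$forearm[i] * len["forearm"]), radii[["forearm"]])
  for (i in seq_along(fr$carpus))
    add_sph("carpus", c(0.004 * s, config$carpus_sphere_y_mm[i] * s / 1000,
                        fr$carpus[i] * len["carpus"] + 0.015 * s), radii[["carpus"]])
  for (f in 1:5) {
    nm <- paste0("mc", f)
    for (u in fr$mc) add_sph(nm, c(0, 0, u * len[nm]), radii[[nm]])
  }
  for (f in 1:5) {
    nm <- paste0("pp", f)
    for (u in fr$pp) add_sph(nm, c(0, 0, u * len[nm]), radii[[nm]])
  }
  for (f in 2:5) {
    nm <- paste0("mid", f)
    for (u in fr$mid) add_sph(nm, c(0, 0, u * len[nm]), radii[[nm]])
  }
  for (f in 1:5) {
    nm <- paste0("dp", f)
    r <- radii[[nm]]
    for (u in fr$dp) {
      ctr <- if (is.na(u)) c(0, 0, len[nm] - r) else c(0, 0, u * len[nm])
      add_sph(nm, ctr, r)
    }
  }
  spheres <- do.call(rbind, sph)
  if (nrow(spheres) != 65) stop("sphere layout must contain exactly 65 spheres")
  if (any(spheres$r <= 0)) stop("sphere radius must be positive")

  # per-segment sphere blocks precomputed for fast penetration checks
  sphere_local <- lapply(split(seq_len(65), spheres$segment), function(idx)
    list(idx = idx, xyz = t(as.matrix(spheres[idx, c("cx", "cy", "cz")]))))

  model <- list(segments = segments, joints = joints,
                seg_joints = seg_joints, joint_path = joint_path,
                fingertips = fingertips, spheres = spheres,
                sphere_local = sphere_local,
                q0 = config$q0, config = config)
  class(model) <- "hand_model"
  model
}

#' @export
print.hand_model <- function(x, ...) {
  cat("Parametric hand musculoskeletal chain\n")
  cat(" segments:", length(x$segments),
      "| actuated joints:", length(x$joints),
      "| skin spheres:", nrow(x$spheres), "\n")
  cat(" hand scale:", x$config$hand_scale, "\n")
  invisible(x)
}

#' Neutral base pose
#' @param p carpal position (m, world frame).
#' @param e carpal orientation as a rotation vector (rad).
#' @return a list with elements `p` and `e`.
#' @export
base_pose <- function(p = c(0, 0, 0), e = c(0, 0, 0)) {
  stopifnot(length(p) == 3, length(e) == 3)
  if (sqrt(sum(e^2)) > pi + 1e-6) stop("rotation vector magnitude exceeds pi")
  list(p = as.numeric(p), e = as.numeric(e))
}

#' Forward kinematics of the hand chain
#'
#' Composes each segment pose from its parent pose, fixed mounting transform
#' and joint rotations, with the carpal segment placed at the given base pose.
#'
#' @param model a `hand_model`.
#' @param q numeric vector of 21 joint angles (rad), ordered as
#'   `JOINT_NAMES`.
#' @param base carpal base pose from [base_pose()].
#' @return a list with per-segment world rotations `R` and origins `o`,
#'   per-joint world `axis` and `center` (21 x 3 matrices), and `tips`
#'   (5 x 3 world positions of the fingertip tip sites).
#' @export
forward_kinematics <- function(model, q, base = base_pose()) {
  if (length(q) != 21) stop("q must have length 21")
  segs <- model$segments
  R <- vector("list", length(segs)); names(R) <- names(segs)
  o <- vector("list", length(segs)); names(o) <- names(segs)
  jaxis <- matrix(NA_real_, 21, 3)
  jcenter <- matrix(NA_real_, 21, 3)

  Rb <- rotvec_to_R(base$e)
  for (nm in names(segs)) {
    sg <- segs[[nm]]
    if (is.na(sg$parent)) {
      Rp <- Rb; op <- base$p
      Rw <- Rp %*% sg$mount
      ow <- op
    } else {
      Rp <- R[[sg$parent]]; op <- o[[sg$parent]]
      ow <- op + as.numeric(Rp %*% sg$offset)
      Rw <- Rp %*% sg$mount
    }
    for (j in model$seg_joints[[nm]]) {
      jt <- model$joints[[j]]
      jaxis[j, ] <- Rw %*% jt$axis
      jcenter[j, ] <- ow
      ct <- cos(q[j]); st <- sin(q[j])
      Rj <- if (jt$axis_id == 2L)
        matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
      else if (jt$axis_id == 1L)
        matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
      else rot_axis(jt$axis, q[j])
      Rw <- Rw %*% Rj
    }
    R[[nm]] <- Rw
    o[[nm]] <- ow
  }

  tips <- matrix(NA_real_, 5, 3, dimnames = list(FINGER_NAMES, NULL))
  for (f in 1:5) {
    ft <- model$fingertips[[f]]
    tips[f, ] <- o[[ft$segment]] + as.numeric(R[[ft$segment]] %*% ft$apex)
  }
  list(R = R, o = o, axis = jaxis, center = jcenter, tips = tips)
}

#' Fingertip contact-site sphere in world coordinates
#'
#' Contact between a fingertip and a surface is carried by a distal skin
#' sphere; this returns that sphere's world-frame centre (and radius as the
#' `"radius"` attribute).
#'
#' @param fk output of [forward_kinematics()].
#' @param model a `hand_model`.
#' @param finger finger name or index (1 = thumb).
#' @param site `"tip"` (terminal sphere) or `"pulp"` (mid-pad sphere).
#' @export
fingertip_site <- function(fk, model, finger, site = c("tip", "pulp")) {
  site <- match.arg(site)
  ft <- model$fingertips[[finger]]
  sp <- ft$sites[[site]]
  structure(as.numeric(fk$o[[ft$segment]] + fk$R[[ft$segment]] %*% sp$center),
            radius = sp$r)
}

#' Contact-point Jacobian with respect to the joint angles
#'
#' Row-blocks are ordered as the contacts; column j holds the partial
#' derivative of the contact position with respect to joint angle j
#' (`axis_j x (c - center_j)` for joints on the carpus-to-segment path, zero
#' otherwise). The carpal base pose is held fixed.
#'
#' @param model a `hand_model`.
#' @param q,base posture at which to evaluate.
#' @param contact_points list of contacts, each a list with `segment` (owning
#'   segment name) and `point` (world position, m).
#' @param fk optional precomputed [forward_kinematics()] result.
#' @return a `3n x 21` numeric matrix.
#' @export
contact_jacobian <- function(model, q, base, contact_points, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q, base)
  n <- length(contact_points)
  J <- matrix(0, 3 * n, 21)
  for (k in seq_len(n)) {
    cp <- contact_points[[k]]
    if (is.null(model$segments[[cp$segment]]))
      stop("contact attached to unknown segment: ", cp$segment)
    rows <- (3 * k - 3 + 1):(3 * k)
    for (j in model$joint_path[[cp$segment]]) {
      J[rows, j] <- cross3(fk$axis[j, ], cp$point - fk$center[j, ])
    }
  }
  J
}

#' Skin-sphere penetration depths against an object
#'
#' Depth of each of the 65 skin spheres into the object:
#' `max(0, radius - signed_distance(centre))`, zero when not penetrating.
#'
#' @param model a `hand_model`.
#' @param q,base posture.
#' @param object a [rigid_object()] providing a signed distance.
#' @param fk optional precomputed forward kinematics.
#' @return numeric vector of 65 non-negative depths (m).
#' @export
penetration_depths <- function(model, q, base, object, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q, base)
  centres <- matrix(NA_real_, 65, 3)
  for (blk in model$sphere_local) {
    nm <- model$spheres$segment[blk$idx[1]]
    centres[blk$idx, ] <- t(fk$R[[nm]] %*% blk$xyz + fk$o[[nm]])
  }
  d <- object_signed_distance(object, centres)
  pmax(0, model$spheres$r - d)
}
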