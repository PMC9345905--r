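# 37-muscle force model with constant moment arms.
#
# Each muscle i produces force F_i = F_i^max * a_i for an activation
# a_i in [0, 1]; joint torques are tau = M^T F^max a, where M is the 37 x 21
# moment-arm matrix (arms constant with respect to joint angle; positive arm
# = flexion/adduction torque). No pennation angle and no force-length or
# force-velocity scaling are modelled. The parameter table ships with the
# package (muscles.csv); entries absent from the table are exactly zero in M.

#' Load the packaged hand-muscle parameter table
#'
#' Reads the 37-muscle table (maximum forces and signed constant moment arms,
#' one column per actuated joint axis, blank = axis not spanned) and
#' assembles the moment-arm matrix in SI units. Note two transcription
#' resolutions in the shipped file: the middle-finger deep flexor is stored
#' under the unique abbreviation FDP3, and the index deep flexor's PIP arm is
#' kept at its printed, anomalously extensor-signed value of -8.5 mm.
#'
#' @param source path to a muscle CSV; defaults to the packaged table.
#' @param strength_scale multiplier applied to the tabulated maximum-force
#'   column. The default 1 uses the printed values as-is. The printed
#'   magnitudes are relative tension capacities proportional to
#'   physiological cross-sectional area (a few units per muscle, 65.1 in
#'   total); converting them to newtons via the specific muscle tension of
#'   35 N/cm^2 (`strength_scale = 35`, treating one printed unit as 1 cm^2)
#'   yields physiologically realistic capacities, and the grasp-synthesis
#'   pipeline uses that scale (see [search_config()]). Effort values are
#'   activation-based and unaffected by the scale except through
#'   feasibility.
#' @return an object of class `muscle_set`: data frame `muscles`, moment-arm
#'   matrix `M` (37 x 21, metres), maximum-force diagonal `F_max` (N).
#' @export
load_muscle_table <- function(source = NULL, strength_scale = 1) {
  if (is.null(source))
    source <- system.file("extdata", "muscles.csv", package = "gripsynth",
                          mustWork = TRUE)
  tab <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("no", "finger", "name", "abbreviation", "f_max_N", JOINT_NAMES)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("muscle table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) != 37) stop("muscle table must have exactly 37 rows, found ",
                            nrow(tab))
  if (any(!is.finite(tab$f_max_N)) || any(tab$f_max_N <= 0))
    stop("all maximum forces must be positive")

  arms_mm <- as.matrix(tab[, JOINT_NAMES])
  arms_mm[is.na(arms_mm)] <- 0
  M <- arms_mm / 1000  # mm -> m
  dimnames(M) <- list(tab$abbreviation, JOINT_NAMES)

  if (!is.numeric(strength_scale) || strength_scale <= 0)
    stop("strength_scale must be positive")
  out <- list(muscles = tab[, c("no", "finger", "name", "abbreviation", "f_max_N")],
              M = M,
              F_max = stats::setNames(tab$f_max_N * strength_scale,
                                      tab$abbreviation),
              strength_scale = strength_scale)
  class(out) <- "muscle_set"
  out
}

#' @export
print.muscle_set <- function(x, ...) {
  cat("Hand muscle set:", nrow(x$M), "muscles,",
      ncol(x$M), "joint axes (constant moment arms)\n")
  cat(" total maximum force:", sum(x$F_max), "N\n")
  invisible(x)
}

check_activations <- function(muscle_set, a) {
  if (length(a) != nrow(muscle_set$M))
    stop("activation vector must have length ", nrow(muscle_set$M))
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("activations must lie in [0, 1]")
  pmin(pmax(a, 0), 1)
}

#' Muscle forces from activations
#'
#' `F_i = F_i^max a_i`, elementwise.
#'
#' @param muscle_set a [load_muscle_table()] result.
#' @param a numeric vector of 37 activations in `[0, 1]`.
#' @return named numeric vector of 37 muscle forces (N).
#' @export
muscle_forces <- function(muscle_set, a) {
  a <- check_activations(muscle_set, a)
  muscle_set$F_max * a
}

#' Joint torques generated by muscle activations
#'
#' `tau = M^T F^max a` with moment arms in metres; exactly linear in `a`.
#'
#' @inheritParams muscle_forces
#' @return named numeric vector of 21 joint torques (N m).
#' @export
joint_torques <- function(muscle_set, a) {
  a <- check_activations(muscle_set, a)
  as.numeric(t(muscle_set$M) %*% (muscle_set$F_max * a)) |>
    stats::setNames(colnames(muscle_set$M))
}
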