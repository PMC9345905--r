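# Measured-versus-simulated fingertip force comparison.
#
# Force records are expressed in the object-fixed frame: F_i load (vertical),
# F_j transverse, F_k grip (normal) in N, and M_k the torsional moment about
# the contact normal in N m. Differences are defined as simulated minus
# measured; "accuracy" is the mean of the differences over conditions and
# "precision" their sample (n-1 denominator) standard deviation. Packaged
# fixtures transcribe a published six-condition precision-grip validation
# experiment (measured, simulated and printed-difference tables) plus its
# free-pinch comparison.

FORCE_COLS <- c("F_i", "F_j", "F_k", "M_k")

#' Read a fingertip force/moment table
#'
#' CSV with columns `condition`, `finger` (thumb | index), `F_i`, `F_j`,
#' `F_k` (N) and `M_k` (N m).
#'
#' @param path CSV path, or one of the packaged fixture names
#'   `"table2_measured"`, `"table2_simulated"`, `"table2_delta"`,
#'   `"table3_free_pinch"`.
#' @return data frame of force records.
#' @export
read_force_table <- function(path) {
  fixtures <- c("table2_measured", "table2_simulated", "table2_delta",
                "table3_free_pinch")
  if (path %in% fixtures)
    path <- system.file("extdata", paste0(path, ".csv"),
                        package = "gripsynth", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("condition", "finger", FORCE_COLS), names(tab))
  if (length(miss))
    stop("force table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(tab[, FORCE_COLS]))))
    stop("force table contains non-finite values")
  tab
}

#' Componentwise differences, simulated minus measured
#'
#' @param measured,simulated force tables with matching (condition, finger)
#'   keys.
#' @return data frame keyed like the inputs with `F_i`, `F_j`, `F_k`, `M_k`
#'   holding `simulated - measured`.
#' @export
compute_deltas <- function(measured, simulated) {
  key <- function(d) paste(d$condition, d$finger)
  if (!setequal(key(measured), key(simulated)) ||
      nrow(measured) != nrow(simulated))
    stop("measured and simulated tables do not share the same (condition, finger) keys")
  simulated <- simulated[match(key(measured), key(simulated)), ]
  out <- measured
  out[, FORCE_COLS] <- simulated[, FORCE_COLS] - measured[, FORCE_COLS]
  out
}

#' Accuracy and precision of a difference column
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' simulated-minus-measured differences.
#'
#' @param delta_column numeric vector of at least two differences.
#' @return named numeric vector `c(accuracy, precision)`.
#' @export
accuracy_precision <- function(delta_column) {
  if (length(delta_column) < 2)
    stop("at least two differences are required")
  c(accuracy = mean(delta_column),
    precision = stats::sd(delta_column))
}

#' Full measured-versus-simulated comparison
#'
#' Computes the per-condition differences and the accuracy/precision summary
#' for every finger and force/moment component.
#'
#' @param measured,simulated force tables (see [read_force_table()]).
#' @param deltas optional difference table to summarize instead of the
#'   recomputed one (e.g. a published difference table kept at its printed
#'   precision).
#' @return class `grip_validation`: `deltas` and a `summary` data frame with
#'   one row per (finger, component) holding accuracy and precision.
#' @export
compare_force_tables <- function(measured, simulated, deltas = NULL) {
  computed <- compute_deltas(measured, simulated)
  use <- if (is.null(deltas)) computed else deltas
  rows <- list()
  for (fing in unique(use$finger)) {
    sub <- use[use$finger == fing, ]
    for (comp in FORCE_COLS) {
      ap <- accuracy_precision(sub[[comp]])
      rows[[length(rows) + 1]] <- data.frame(
        finger = fing, component = comp,
        accuracy = ap[["accuracy"]], precision = ap[["precision"]])
    }
  }
  structure(list(deltas = use, deltas_recomputed = computed,
                 summary = do.call(rbind, rows)),
            class = "grip_validation")
}

#' @export
print.grip_validation <- function(x, digits = 4, ...) {
  cat("Fingertip force validation: simulated - measured over",
      nrow(x$deltas), "records\n")
  s <- x$summary
  s$accuracy <- signif(s$accuracy, digits)
  s$precision <- signif(s$precision, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
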