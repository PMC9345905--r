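# Covariance matrix adaptation evolution strategy (CMA-ES).
#
# Standard (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation and
# rank-one + rank-mu covariance updates (Hansen's parameterization). Box
# constraints are handled by reflecting sampled candidates back into the box
# (triangle-wave reflection), which keeps the sampling distribution update
# consistent and never evaluates the objective outside the bounds.

reflect_into_box <- function(x, lower, upper) {
  w <- upper - lower
  y <- (x - lower) %% (2 * w)
  lower + ifelse(y > w, 2 * w - y, y)
}

#' Minimize a black-box function with CMA-ES
#'
#' @param fn objective, called with a single numeric vector inside the box.
#' @param x0 initial mean.
#' @param sigma0 initial step size.
#' @param lower,upper box bounds (finite).
#' @param lambda population size; default `4 + floor(3 log d)`.
#' @param max_gen generation cap.
#' @param tol_fun stop when the best value improved by less than this over
#'   the last `tol_gen` generations.
#' @param tol_gen window for the `tol_fun` test.
#' @param seed optional integer seed; the run is fully reproducible for a
#'   fixed seed (the caller's RNG state is restored on exit).
#' @return list with `x` (best point), `value`, `trace` (per-generation data
#'   frame: generation, best value in the generation, best so far, sigma),
#'   `generations`, `evaluations`.
#' @export
cmaes_minimize <- function(fn, x0, sigma0, lower, upper,
                           lambda = NULL, max_gen = 200,
                           tol_fun = 1e-6, tol_gen = 20, seed = NULL) {
  d <- length(x0)
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower),
            sigma0 > 0)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  if (is.null(lambda)) lambda <- 4 + floor(3 * log(d))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  csig <- (mueff + 2) / (d + mueff + 5)
  dsig <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + csig
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  m <- reflect_into_box(as.numeric(x0), lower, upper)
  sigma <- sigma0
  C <- diag(d)
  psig <- numeric(d); pc <- numeric(d)
  best_x <- m; best_val <- Inf
  trace <- vector("list", max_gen)
  evals <- 0

  for (gen in seq_len(max_gen)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    Z <- matrix(stats::rnorm(d * lambda), d, lambda)
    Y <- B %*% (D * Z)
    X <- m + sigma * Y
    for (k in seq_len(lambda)) X[, k] <- reflect_into_box(X[, k], lower, upper)
    Yr <- (X - m) / sigma   # reflected steps actually taken
    vals <- apply(X, 2, fn)
    evals <- evals + lambda
    ord <- order(vals)
    if (vals[ord[1]] < best_val) {
      best_val <- vals[ord[1]]
      best_x <- X[, ord[1]]
    }
    trace[[gen]] <- data.frame(generation = gen,
                               best = vals[ord[1]],
                               best_so_far = best_val,
                               sigma = sigma)

    ysel <- Yr[, ord[seq_len(mu)], drop = FALSE]
    ybar <- as.numeric(ysel %*% w)
    m <- m + sigma * ybar

    Cinvsqrt <- B %*% ((1 / D) * t(B))
    psig <- (1 - csig) * psig +
      sqrt(csig * (2 - csig) * mueff) * as.numeric(Cinvsqrt %*% ybar)
    hsig <- as.numeric(
      sqrt(sum(psig^2)) / sqrt(1 - (1 - csig)^(2 * gen)) / chiN <
        1.4 + 2 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    rank1 <- pc %o% pc + (1 - hsig) * cc * (2 - cc) * C
    rankmu <- ysel %*% (w * t(ysel))
    C <- (1 - c1 - cmu) * C + c1 * rank1 + cmu * rankmu
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((csig / dsig) * (sqrt(sum(psig^2)) / chiN - 1))

    if (gen >= tol_gen) {
      prev <- trace[[gen - tol_gen + 1]]$best_so_far
      if (prev - best_val < tol_fun) break
    }
    if (sigma < 1e-12) break
  }

  list(x = best_x, value = best_val,
       trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
       generations = gen, evaluations = evals)
}
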