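#' Gaussian expected improvement
#'
#' Closed form of `E[max(f(x) - f*, 0)]` for a Gaussian posterior with mean
#' `mu` and standard deviation `sigma` at incumbent best `f_star`
#' (maximisation): `(mu - f*) * pnorm(z) + sigma * dnorm(z)` with
#' `z = (mu - f*)/sigma`. When `sigma = 0` the improvement is deterministic:
#' `max(mu - f*, 0)`.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), >= 0.
#' @param f_star incumbent best observed score.
#' @return expected improvement, same length as `mu`.
#' @export
expected_improvement <- function(mu, sigma, f_star) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  d <- mu - f_star
  out <- pmax(d, 0)
  pos <- sigma > 0
  z <- d[pos] / sigma[pos]
  out[pos] <- d[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  out
}

# Matern 5/2 kernel on scaled coordinates (isotropic lengthscale).
matern52 <- function(d, lengthscale) {
  r <- sqrt(5) * d / lengthscale
  (1 + r + r^2 / 3) * exp(-r)
}

# Minimal GP regression surrogate: zero-mean (after centring y), Matern 5/2,
# signal variance = var(y), lengthscale = median pairwise distance, small
# nugget for conditioning. Returns posterior mean/sd at candidate points.
gp_posterior <- function(X, y, Xstar, lengthscale = NULL, nugget = 1e-6) {
  mu_y <- mean(y)
  sf2 <- stats::var(y)
  if (!is.finite(sf2) || sf2 == 0) sf2 <- 1e-12
  D <- as.matrix(stats::dist(X))
  if (is.null(lengthscale)) {
    lengthscale <- stats::median(D[upper.tri(D)])
    if (!is.finite(lengthscale) || lengthscale <= 0) lengthscale <- 0.5
  }
  K <- sf2 * matern52(D, lengthscale) + diag(sf2 * nugget, nrow(X))
  cross_d <- sqrt(outer(rowSums(Xstar^2), rowSums(X^2), "+") -
                    2 * Xstar %*% t(X))
  cross_d[!is.finite(cross_d) | cross_d < 0] <- 0
  Ks <- sf2 * matern52(cross_d, lengthscale)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu_y))
  mu <- as.numeric(Ks %*% alpha) + mu_y
  V <- forwardsolve(t(L), t(Ks))
  var <- pmax(sf2 - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' Hyperparameter search space
#'
#' @param ... named dimensions; each either a numeric `c(lower, upper)`
#'   bound (continuous) or a list/vector of discrete choices.
#' @return an object of class `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (!length(dims) || is.null(names(dims)) || any(!nzchar(names(dims))))
    stop("search_space needs named dimensions")
  dims <- lapply(dims, function(d) {
    if (is.numeric(d) && length(d) == 2L && d[1] < d[2])
      list(type = "continuous", lower = d[1], upper = d[2])
    else list(type = "choice", values = d)
  })
  structure(dims, class = "search_space")
}

space_decode <- function(space, u) {
  u <- unname(u)
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (j in seq_along(space)) {
    d <- space[[j]]
    out[[j]] <- if (d$type == "continuous")
      d$lower + u[j] * (d$upper - d$lower)
    else d$values[[1L + min(length(d$values) - 1L,
                            floor(u[j] * length(d$values)))]]
  }
  out
}

#' Sequential model-based (Bayesian) hyperparameter optimisation
#'
#' Maximises `objective` over the search space with a Gaussian-process
#' surrogate (Matern 5/2) and the expected-improvement acquisition:
#' `n_init` Latin-hypercube evaluations, then `n_iter` rounds of fitting the
#' surrogate to all observations and evaluating the EI-maximising point from
#' a fresh uniform candidate pool (pool-based acquisition; no inner-loop
#' optimiser). A failing objective evaluation is recorded as the worst score
#' observed so far and the search continues.
#'
#' @param space a [search_space()].
#' @param objective function taking a named list of hyperparameter values
#'   and returning a scalar score to maximise.
#' @param n_init number of initial design points (>= 2, default 5).
#' @param n_iter number of surrogate-guided evaluations (default 20).
#' @param pool_size size of the EI candidate pool per round (default 1024).
#' @param seed integer RNG seed; the whole search is deterministic given it.
#' @return list with `best` (named hyperparameter list), `best_score`, and
#'   `trace` (data.frame: one row per evaluation with the unit-cube
#'   coordinates, score, and running incumbent `best_so_far`).
#' @export
smbo_optimize <- function(space, objective, n_init = 5L, n_iter = 20L,
                          pool_size = 1024L, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (n_init < 2L) stop("n_init must be >= 2")
  d <- length(space)
  withr::with_seed(seed, {
    U <- lhs::randomLHS(n_init, d)
    y <- numeric(0)
    evaluate <- function(u) {
      params <- space_decode(space, u)
      val <- tryCatch(as.numeric(objective(params)),
                      error = function(e) {
                        message("smbo: objective failed (",
                                conditionMessage(e),
                                "); recording worst observed")
                        NA_real_
                      })
      if (!length(val) || !is.finite(val))
        val <- if (length(y)) min(y) else -Inf
      val
    }
    for (i in seq_len(n_init)) y[i] <- evaluate(U[i, ])
    y[!is.finite(y)] <- min(y[is.finite(y)], 0)
    for (i in seq_len(n_iter)) {
      pool <- matrix(stats::runif(pool_size * d), ncol = d)
      post <- gp_posterior(U, y, pool)
      ei <- expected_improvement(post$mean, post$sd, max(y))
      u_next <- pool[which.max(ei), , drop = TRUE]
      U <- rbind(U, u_next)
      y <- c(y, evaluate(u_next))
    }
  })
  best_i <- which.max(y)
  trace <- as.data.frame(U)
  names(trace) <- paste0("u_", names(space))
  trace$score <- y
  trace$best_so_far <- cummax(y)
  list(best = space_decode(space, U[best_i, ]), best_score = y[best_i],
       trace = trace)
}
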