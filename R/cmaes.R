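#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' A self-contained implementation of the standard (mu/mu_w, lambda)-CMA-ES
#' with cumulative step-size adaptation and rank-one plus rank-mu covariance
#' updates, exposed through an ask/tell interface so a caller can control
#' evaluation, logging and stopping. The strategy minimizes; callers that
#' maximize negate their objective.
#'
#' `cma_init()` builds the strategy state; `cma_ask()` samples a population
#' of candidate solutions from the current search distribution (consuming
#' the R random stream); `cma_tell()` updates the distribution from the
#' evaluated candidates.
#'
#' @param mean Initial distribution mean (numeric vector, the search-space
#'   dimension is `length(mean)`).
#' @param sigma Initial global step size.
#' @param lambda Population size (>= 2); defaults to `4 + floor(3 log n)`.
#' @return `cma_init()`: an environment of class `cma_state` (mutated in
#'   place by `cma_tell()`); `cma_ask()`: a `lambda x n` matrix of
#'   candidates; `cma_tell()`: the state, invisibly.
#' @examples
#' set.seed(1)
#' st <- cma_init(rep(1, 5), sigma = 0.5)
#' for (i in 1:60) {
#'   x <- cma_ask(st)
#'   cma_tell(st, x, rowSums(x^2))   # sphere
#' }
#' st$best_value < 1e-8
#' @export
cma_init <- function(mean, sigma = 0.5, lambda = NULL) {
  n <- length(mean)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- as.integer(lambda)
  if (lambda < 2L) stop("lambda must be >= 2")
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$lambda <- lambda
  st$mu <- mu
  st$weights <- w
  st$mueff <- mueff
  st$mean <- as.numeric(mean)
  st$sigma <- sigma
  st$cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  st$cs <- (mueff + 2) / (n + mueff + 5)
  st$c1 <- 2 / ((n + 1.3)^2 + mueff)
  st$cmu <- min(1 - st$c1,
                2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  st$damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + st$cs
  st$chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  st$pc <- numeric(n)
  st$ps <- numeric(n)
  st$B <- diag(n)
  st$D <- rep(1, n)
  st$C <- diag(n)
  st$invsqrtC <- diag(n)
  st$eigen_eval <- 0
  st$count_eval <- 0
  st$generation <- 0L
  st$last_z <- NULL
  st$best_value <- Inf
  st$best_x <- NULL
  class(st) <- "cma_state"
  st
}

#' @param state A `cma_state` from `cma_init()`.
#' @rdname cma_init
#' @export
cma_ask <- function(state) {
  z <- matrix(stats::rnorm(state$n * state$lambda), state$n, state$lambda)
  y <- state$B %*% (state$D * z)
  x <- sweep(state$sigma * y, 1, state$mean, `+`)
  state$last_z <- z
  t(x)   # lambda x n, one candidate per row
}

#' @param candidates The matrix returned by the matching `cma_ask()` call.
#' @param values Numeric vector of objective values (to be minimized), one
#'   per candidate row.
#' @rdname cma_init
#' @export
cma_tell <- function(state, candidates, values) {
  if (length(values) != state$lambda)
    stop("one objective value per candidate is required")
  n <- state$n
  ord <- order(values)
  sel <- ord[seq_len(state$mu)]
  z_sel <- state$last_z[, sel, drop = FALSE]
  x_sel <- t(candidates)[, sel, drop = FALSE]
  old_mean <- state$mean
  state$mean <- drop(x_sel %*% state$weights)
  zmean <- drop(z_sel %*% state$weights)

  state$ps <- (1 - state$cs) * state$ps +
    sqrt(state$cs * (2 - state$cs) * state$mueff) * drop(state$B %*% zmean)
  state$count_eval <- state$count_eval + state$lambda
  hsig <- sqrt(sum(state$ps^2)) /
    sqrt(1 - (1 - state$cs)^(2 * state$count_eval / state$lambda)) /
    state$chi_n < 1.4 + 2 / (n + 1)
  y_mean <- (state$mean - old_mean) / state$sigma
  state$pc <- (1 - state$cc) * state$pc +
    (if (hsig) sqrt(state$cc * (2 - state$cc) * state$mueff) else 0) * y_mean

  y_sel <- sweep(x_sel, 1, old_mean, `-`) / state$sigma
  rank_mu <- y_sel %*% (state$weights * t(y_sel))
  state$C <- (1 - state$c1 - state$cmu) * state$C +
    state$c1 * (tcrossprod(state$pc) +
                (if (hsig) 0 else state$cc * (2 - state$cc)) * state$C) +
    state$cmu * rank_mu
  state$sigma <- state$sigma *
    exp((state$cs / state$damps) * (sqrt(sum(state$ps^2)) / state$chi_n - 1))

  # lazy eigendecomposition: O(n^3), refreshed every ~1/(10 n (c1+cmu)) gens
  if (state$count_eval - state$eigen_eval >
      state$lambda / (state$c1 + state$cmu) / n / 10) {
    state$eigen_eval <- state$count_eval
    state$C <- (state$C + t(state$C)) / 2
    eg <- eigen(state$C, symmetric = TRUE)
    d2 <- pmax(eg$values, .Machine$double.eps)
    state$B <- eg$vectors
    state$D <- sqrt(d2)
    state$invsqrtC <- eg$vectors %*% (t(eg$vectors) / state$D)
  }

  gen_best <- which.min(values)
  if (values[gen_best] < state$best_value) {
    state$best_value <- values[gen_best]
    state$best_x <- candidates[gen_best, ]
  }
  state$generation <- state$generation + 1L
  invisible(state)
}

#' @export
print.cma_state <- function(x, ...) {
  cat(sprintf("<cma_state> n=%d, lambda=%d, generation %d, sigma %.3g, best %.4g\n",
              x$n, x$lambda, x$generation, x$sigma, x$best_value))
  invisible(x)
}
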