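# Markov model of karyotype-cluster evolution.
#
# States are clusters of C(Xa:A) karyotypes around the dominant genotypes:
#   x1 ~ C(1:2)  (the normal somatic karyotype)
#   x2 ~ C(2:2)  (active X doubled)
#   x3 ~ C(2:3)  (a haploid autosome complement added)
#   x4 ~ C(2:4)  (4-state model only)
# X-count changes occur at rate u per unit time, autosome-set changes at
# the slower rate v; a, b, c (> 1) multiply the backward/downward rates
# because gain/loss probability grows with chromosome number. Time is
# discrete; one step is one unit of 1/v when v is given per step.

#' Build the neutral 3-state karyotype-cluster chain
#'
#' The transition matrix is
#' \deqn{M = \begin{pmatrix} 1-u & u & 0 \\ au & 1-au-v & v \\
#'   0 & bv & 1-bv \end{pmatrix}}
#' with cluster frequencies evolving as X(T) = X(0) M^T.
#'
#' @param u Per-step probability of the X-doubling transition x1 -> x2.
#' @param v Per-step probability of the autosome-set gain x2 -> x3.
#' @param a Back-multiplier of the X step (x2 -> x1 at a*u).
#' @param b Back-multiplier of the autosome step (x3 -> x2 at b*v).
#' @return Object of class `neutral_model`: `u`, `v`, `a`, `b`, the 3x3
#'   row-stochastic matrix `M` and the stationary vector.
#' @export
#' @examples
#' build_neutral(u = 0.1, v = 0.01, a = 2, b = 1.5)$M
build_neutral <- function(u, v, a, b) {
  check_rates(u = u, v = v, a = a, b = b)
  M <- rbind(
    c(1 - u, u, 0),
    c(a * u, 1 - a * u - v, v),
    c(0, b * v, 1 - b * v)
  )
  check_stochastic(M, c("x1", "x2", "x3"))
  structure(
    list(u = u, v = v, a = a, b = b, M = M,
         stationary = neutral_equilibrium(a, b)),
    class = "neutral_model"
  )
}

check_rates <- function(...) {
  r <- list(...)
  for (nm in names(r)) {
    x <- r[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stopf("parameter '%s' must be a single non-negative number", nm)
    }
  }
  invisible(r)
}

check_stochastic <- function(M, state_names) {
  neg <- which(M < -1e-12, arr.ind = TRUE)
  if (nrow(neg)) {
    stopf("inadmissible rates: row '%s' of the transition matrix has a negative entry (diagonal would be %g); reduce u, v or the multipliers",
          state_names[neg[1L, 1L]], M[neg[1L, , drop = FALSE]])
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    stopf("transition matrix rows must sum to 1 (max deviation %g)", max(abs(rs - 1)))
  }
  invisible(M)
}

#' Neutral equilibrium of the 3-cluster chain
#'
#' For T >> 0 the cluster frequencies approach
#' \deqn{[x_1, x_2, x_3] = [ab, b, 1] / z, \quad z = ab + b + 1,}
#' independent of u and v. With a, b > 1 this forces
#' x1 > x2 > x3 and in particular x3 < 1/3: under neutrality the C(2:3)
#' cluster can never dominate.
#'
#' @param a,b Back-multipliers (> 0).
#' @return Frequency vector of length 3 summing to 1.
#' @export
#' @examples
#' neutral_equilibrium(2, 1.5)  # [3, 1.5, 1] / 5.5
neutral_equilibrium <- function(a, b) {
  check_rates(a = a, b = b)
  if (a <= 0 || b <= 0) stopf("neutral_equilibrium: a and b must be positive")
  z <- a * b + b + 1
  stats::setNames(c(a * b, b, 1) / z, c("x1", "x2", "x3"))
}

#' Propagate a cluster-frequency vector T steps
#'
#' Computes X(T) = X(0) M^T by exponentiation-by-squaring of the transition
#' matrix.
#'
#' @param model A `neutral_model` (or any list with a row-stochastic `M`).
#' @param X0 Initial frequency vector (non-negative, sums to 1).
#' @param T Non-negative integer number of steps.
#' @return Frequency vector X(T).
#' @export
#' @examples
#' m <- build_neutral(0.1, 0.01, 2, 1.5)
#' trajectory(m, c(1, 0, 0), 500)
trajectory <- function(model, X0, T) {
  M <- model$M %||% model
  if (!is_count(T)) stopf("trajectory: T must be a non-negative integer")
  check_state(X0, ncol(M))
  drop(X0 %*% mat_pow(M, T))
}

check_state <- function(X, k) {
  if (length(X) != k) stopf("state vector must have length %d", k)
  if (any(X < -1e-12)) stopf("state vector must be non-negative")
  if (abs(sum(X) - 1) > 1e-9) stopf("state vector must sum to 1 (got %.12f)", sum(X))
  invisible(X)
}

mat_pow <- function(M, T) {
  out <- diag(nrow(M))
  P <- M
  while (T > 0) {
    if (T %% 2 == 1) out <- out %*% P
    P <- P %*% P
    T <- T %/% 2
  }
  out
}

#' Build the 4-state karyotype chain with selection
#'
#' Extends the neutral chain with a fourth cluster, C(2:4), reached from
#' C(2:3) at rate v and left at rate c*v (default c = b: the same
#' more-chromosomes-change-more principle). Fitnesses are
#' W = \[1, 1+s, 1+t, 1\]: the wild type C(1:2) and C(2:4) sit at 1, s is
#' the selection coefficient of C(2:2) and t that of C(2:3).
#'
#' Selection enters through an expanded transition matrix followed by a
#' normalization step: each neutral transition probability M_ij is
#' multiplied by the fitness W_j of the destination cluster (a karyotype
#' change only spreads through a line in proportion to the fitness of the
#' new karyotype) and rows are renormalized, giving the selection chain
#' `M_sel`. Because the chain is tridiagonal and reversible, its stationary
#' vector is, to first order in the rates, proportional to
#' \deqn{[1,\; (1+s)/a,\; (1+t)/(ab),\; 1/(abc)],}
#' which reduces to the neutral \[ab, b, 1\]/z on the first three states
#' when s = t = 0. Hence s < 0 is necessary for x2 < x3 (given b > 1) and
#' t > 0 for x3 to approach x1.
#'
#' @param u,v,a,b As in [build_neutral()].
#' @param c Multiplier of the C(2:4) -> C(2:3) back rate.
#' @param s,t Selection coefficients (> -1) of C(2:2) and C(2:3).
#' @return Object of class `selection_model` with the neutral matrix `M4`,
#'   fitness vector `W`, selection chain `M_sel` (alias `M`, so
#'   [trajectory()] works on it) and the parameters.
#' @export
build_selection <- function(u, v, a, b, c = b, s = 0, t = 0) {
  check_rates(u = u, v = v, a = a, b = b, c = c)
  if (s <= -1 || t <= -1) stopf("selection coefficients must exceed -1")
  M4 <- rbind(
    c(1 - u, u, 0, 0),
    c(a * u, 1 - a * u - v, v, 0),
    c(0, b * v, 1 - b * v - v, v),
    c(0, 0, c * v, 1 - c * v)
  )
  check_stochastic(M4, c("x1", "x2", "x3", "x4"))
  W <- c(1, 1 + s, 1 + t, 1)
  A <- M4 %*% diag(W)
  M_sel <- A / rowSums(A)
  structure(
    list(u = u, v = v, a = a, b = b, c = c, s = s, t = t,
         M4 = M4, W = W, M_sel = M_sel, M = M_sel),
    class = "selection_model"
  )
}

#' One generation of the selection chain
#'
#' @param model A `selection_model`.
#' @param X Frequency 4-vector.
#' @param update `"transition"` (default): one step of the fitness-weighted,
#'   row-renormalized chain `M_sel`. `"population"`: the classical
#'   mutation-selection iteration (multiply by the neutral `M4`, weight by
#'   `W`, renormalize the vector); its equilibrium concentrates on the
#'   fittest cluster once |s|, |t| exceed the transition rates, which is not
#'   the regime the cluster-frequency observations live in — provided for
#'   comparison.
#' @return The next generation's frequency vector (sums to 1).
#' @export
selection_step <- function(model, X, update = c("transition", "population")) {
  update <- match.arg(update)
  check_state(X, 4L)
  if (update == "transition") {
    drop(X %*% model$M_sel)
  } else {
    y <- drop(X %*% model$M4) * model$W
    y / sum(y)
  }
}

#' Equilibrium of the selection chain
#'
#' Fixed point of [selection_step()]. The default solver iterates the step
#' to convergence; `method = "eigen"` instead takes the dominant left
#' eigenvector of the (normalized) fitness-weighted transition matrix. The
#' two agree to the tolerance; the eigen route is the cross-check and the
#' fast path for grid fitting.
#'
#' @param model A `selection_model`.
#' @param tol L-infinity convergence tolerance.
#' @param max_iter Iteration cap.
#' @param method `"iterate"` or `"eigen"`.
#' @param X0 Starting vector for the iteration.
#' @param update Passed to [selection_step()]; the eigen method uses the
#'   matching matrix (`M_sel`, or `M4 diag(W)` for `"population"`).
#' @return Equilibrium frequency 4-vector.
#' @export
selection_equilibrium <- function(model, tol = 1e-12, max_iter = 1e6,
                                  method = c("iterate", "eigen"),
                                  X0 = rep(0.25, 4),
                                  update = c("transition", "population")) {
  method <- match.arg(method)
  update <- match.arg(update)
  if (method == "eigen") {
    A <- if (update == "transition") model$M_sel else model$M4 %*% diag(model$W)
    e <- eigen(t(A))
    i <- which.max(Re(e$values))
    vec <- Re(e$vectors[, i])
    if (all(vec <= 0)) vec <- -vec
    if (any(vec < -1e-8)) stopf("eigen solver: dominant eigenvector not non-negative")
    vec <- pmax(vec, 0)
    return(vec / sum(vec))
  }
  X <- X0 / sum(X0)
  for (i in seq_len(max_iter)) {
    Xn <- selection_step(model, X, update)
    if (max(abs(Xn - X)) < tol) return(Xn)
    X <- Xn
  }
  stopf("selection_equilibrium did not converge in %d iterations (residual %g)",
        max_iter, max(abs(Xn - X)))
}

#' Test whether observed cluster frequencies are compatible with neutrality
#'
#' Under neutrality with a, b > 1, the C(2:3) cluster frequency x3(T)
#' starting from the all-wild-type state X(0) = \[1, 0, 0\] stays below its
#' equilibrium value 1/(ab+b+1) < 1/3 at every T, and the equilibrium
#' ordering is x1 > x2 > x3. The test computes the supremum of neutral
#' x3(T) over a grid of (a, b) and a log-spaced range of T and rejects
#' neutrality when the observed x3 exceeds it; it also reports whether the
#' observed ordering matches the neutral prediction.
#'
#' @param observed Observed 3-cluster frequencies (renormalized to sum 1;
#'   a `cluster_tally` is accepted, in which case x1, x2, x3 are
#'   renormalized over the three clusters).
#' @param a_range,b_range Ranges of multipliers, lower bound > 1.
#' @param n_grid Grid points per parameter.
#' @param v Autosome transition rate per step used for the trajectories
#'   (u = `u_over_v` * v); must keep all rows admissible over the grid.
#' @param u_over_v Ratio u/v (X changes faster than the autosome set).
#' @param T_max Largest trajectory time scanned.
#' @return List of class `neutrality_report`: `rejected`, `observed`,
#'   `max_neutral_x3` (with the (a, b, T) attaining it),
#'   `ordering_neutral`, `ordering_observed`, `ordering_consistent`, `grid`.
#' @export
neutrality_test <- function(observed, a_range = c(1, 10), b_range = c(1, 10),
                            n_grid = 8L, v = 1e-3, u_over_v = 10,
                            T_max = 1e4) {
  if (inherits(observed, "cluster_tally")) {
    observed <- c(observed$x1, observed$x2, observed$x3)
  }
  if (length(observed) != 3L) stopf("neutrality_test: observed must have 3 components")
  observed <- observed / sum(observed)
  # open lower bound: a, b strictly greater than 1
  lo_a <- max(a_range[1L], 1) + 1e-6
  lo_b <- max(b_range[1L], 1) + 1e-6
  as <- seq(lo_a, a_range[2L], length.out = n_grid)
  bs <- seq(lo_b, b_range[2L], length.out = n_grid)
  u <- u_over_v * v
  Ts <- unique(c(0L, as.integer(round(exp(seq(0, log(T_max), length.out = 60))))))
  grid <- expand.grid(a = as, b = bs)
  grid$max_x3 <- NA_real_
  X0 <- c(1, 0, 0)
  for (i in seq_len(nrow(grid))) {
    m <- build_neutral(u, v, grid$a[i], grid$b[i])
    x3 <- vapply(Ts, function(T) trajectory(m, X0, T)[3L], numeric(1))
    eq <- neutral_equilibrium(grid$a[i], grid$b[i])[3L]
    grid$max_x3[i] <- max(x3, eq)
  }
  imax <- which.max(grid$max_x3)
  max_x3 <- grid$max_x3[imax]
  ordering_neutral <- c("x1", "x2", "x3")  # descending, from [ab,b,1]/z with a,b>1
  ordering_observed <- c("x1", "x2", "x3")[order(-observed)]
  structure(
    list(
      rejected = observed[3L] > max_x3,
      observed = stats::setNames(observed, c("x1", "x2", "x3")),
      max_neutral_x3 = max_x3,
      argmax = list(a = grid$a[imax], b = grid$b[imax]),
      ordering_neutral = ordering_neutral,
      ordering_observed = ordering_observed,
      ordering_consistent = identical(ordering_neutral, ordering_observed),
      grid = grid
    ),
    class = "neutrality_report"
  )
}

#' @export
print.neutrality_report <- function(x, ...) {
  cat(sprintf("<neutrality_report> observed x3 = %.3f vs sup neutral x3 = %.3f\n",
              x$observed[3L], x$max_neutral_x3))
  cat(sprintf("  neutrality %s; observed ordering %s neutral prediction (x1 > x2 > x3)\n",
              if (x$rejected) "REJECTED" else "not rejected",
              if (x$ordering_consistent) "matches" else "contradicts"))
  invisible(x)
}
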