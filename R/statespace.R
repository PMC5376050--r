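#' Enumerate the social-state plane of an N-player population
#'
#' The social state of a population in one round is the occupancy triple
#' `(n_R, n_P, n_S)` counting how many players hold each action. All triples
#' of non-negative integers summing to `N` lie on a bounded triangular
#' lattice plane with `(N + 1)(N + 2) / 2` points; collective cycling is
#' rotation of the trajectory around the centroid `c0 = (N/3, N/3, N/3)`.
#'
#' States are listed in a canonical order: descending in `n_R`, then
#' descending in `n_P` (so the first state is `(N, 0, 0)` and the last
#' `(0, 0, N)`). The order is deterministic and stable across runs; the
#' `index` column is the bijection used by the Markov-model transition
#' matrices.
#'
#' @param N Even population size, `N >= 2`. Odd sizes are rejected because
#'   random pairwise matching needs a perfect matching.
#' @return An object of class `state_space`: a list with elements
#'   * `N` — the population size,
#'   * `states` — a tibble with columns `index`, `n_R`, `n_P`, `n_S`,
#'   * `centroid` — the numeric triple `(N/3, N/3, N/3)`.
#' @examples
#' sp <- enumerate_states(6)
#' nrow(sp$states) # 28
#' @export
enumerate_states <- function(N) {
  check_even_N(N)
  N <- as.integer(N)
  n_R <- rep(N:0, times = seq.int(1L, N + 1L))
  n_P <- unlist(lapply(N:0, function(r) seq.int(N - r, 0L)))
  states <- tibble::tibble(
    index = seq_along(n_R),
    n_R = n_R,
    n_P = n_P,
    n_S = N - n_R - n_P
  )
  lookup <- matrix(NA_integer_, N + 1L, N + 1L)
  lookup[cbind(n_R + 1L, n_P + 1L)] <- states$index
  structure(
    list(N = N, states = states, centroid = rep(N / 3, 3), lookup = lookup),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "<state_space> N = %d players, %d social states (n_R, n_P, n_S)\n",
    x$N, nrow(x$states)
  ))
  print(x$states, ...)
  invisible(x)
}

check_even_N <- function(N) {
  if (length(N) != 1 || !is.finite(N) || N != as.integer(N) ||
      N < 2 || N %% 2 != 0) {
    stop("N must be a single even integer >= 2 (pairwise matching needs a perfect matching)",
         call. = FALSE)
  }
  invisible(N)
}

# index of state (n_R, n_P) in the canonical order; vectorised.
state_index <- function(space, n_R, n_P) {
  space$lookup[cbind(n_R + 1L, n_P + 1L)]
}

assert_state <- function(space, s) {
  s <- as.numeric(s)
  if (length(s) != 3 || any(s < 0) || any(s != round(s)) ||
      sum(s) != space$N) {
    stop(sprintf(
      "state (%s) is not a valid occupancy triple for N = %d",
      paste(s, collapse = ", "), space$N
    ), call. = FALSE)
  }
  invisible(as.integer(s))
}

#' Rotation angle of a social-state transition around the centroid
#'
#' Each transition `s -> s_next` on the social-state plane is assigned a
#' signed angle at the centroid `c0 = (N/3, N/3, N/3)`: with in-plane
#' vectors `u = s - c0` and `v = s_next - c0`, the magnitude is
#' `acos(u.v / (|u||v|))` and the sign is the sign of the triple product
#' `(u x v) . (1, 1, 1)`. Positive angles are counter-clockwise rotations in
#' the R -> P -> S orientation (R-rich to P-rich to S-rich); negative angles
#' are clockwise. The angle is 0 when the transition is not a rotation
#' around the centroid: no movement, either endpoint at the centroid, or
#' `s`, `s_next`, `c0` collinear.
#'
#' Degeneracy (centroid coincidence and collinearity) is decided on exact
#' integers: the test uses the integer vectors `3 s - (N, N, N)`, so no
#' floating-point tolerance is involved.
#'
#' @param s,s_next Occupancy triples `(n_R, n_P, n_S)` (numeric length-3
#'   vectors summing to `N`).
#' @param space A `state_space` from [enumerate_states()].
#' @return The rotation angle in radians, in `(-pi, pi)`.
#' @examples
#' sp <- enumerate_states(6)
#' rotation_angle(c(3, 2, 1), c(2, 3, 1), sp) # pi/3
#' @export
rotation_angle <- function(s, s_next, space) {
  s <- assert_state(space, s)
  s2 <- assert_state(space, s_next)
  # integer in-plane vectors scaled by 3: 3(s - c0) = 3s - (N, N, N)
  u <- 3L * s - space$N
  v <- 3L * s2 - space$N
  if (all(u == 0L) || all(v == 0L)) return(0)
  cr <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  triple <- sum(cr) # (u x v) . (1,1,1)
  if (triple == 0L) return(0) # s, s_next, c0 collinear (includes s == s_next)
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  ang <- acos(min(1, max(-1, cosang)))
  sign(triple) * ang
}

# K x K matrix of rotation angles between all state pairs; rows = from.
rotation_angle_matrix <- function(space) {
  st <- as.matrix(space$states[, c("n_R", "n_P", "n_S")])
  K <- nrow(st)
  U <- 3L * st - space$N # integer in-plane vectors, rows
  # cross products via column arithmetic
  theta <- matrix(0, K, K)
  nu <- sqrt(rowSums(U^2))
  for (i in seq_len(K)) {
    u <- U[i, ]
    if (all(u == 0)) next
    cr <- cbind(
      u[2] * U[, 3] - u[3] * U[, 2],
      u[3] * U[, 1] - u[1] * U[, 3],
      u[1] * U[, 2] - u[2] * U[, 1]
    )
    triple <- rowSums(cr)
    dot <- U %*% u
    denom <- nu[i] * nu
    ok <- triple != 0 & denom > 0
    ang <- rep(0, K)
    ang[ok] <- sign(triple[ok]) * acos(pmin(1, pmax(-1, dot[ok] / denom[ok])))
    theta[i, ] <- ang
  }
  theta
}

#' Net cycles and cycling frequency of a rotation-angle sequence
#'
#' The net number of cycles a trajectory winds around the centroid over an
#' interval is the sum of its per-transition rotation angles divided by
#' `2 * pi`; the cycling frequency is the net cycle count per transition.
#' A 300-round session analysed over rounds 1..300 has 299 transitions, so
#' its frequency is `C / 299`.
#'
#' @param angles Numeric vector of rotation angles in radians (one per
#'   transition); may be empty.
#' @param t0,t1 First and last round of the covered interval (1-based,
#'   closed); the number of transitions is `t1 - t0` and must equal
#'   `length(angles)`.
#' @return `net_cycles()` returns the real-valued winding number `C`;
#'   `cycling_frequency()` returns `f = C / (t1 - t0)` in cycles per round.
#' @examples
#' net_cycles(c(pi / 3, 0, -2 * pi / 3)) # -1/6
#' cycling_frequency(c(pi / 3, 0, -2 * pi / 3), t0 = 1, t1 = 4)
#' @export
net_cycles <- function(angles) {
  if (length(angles) == 0) return(0)
  sum(angles) / (2 * pi)
}

#' @rdname net_cycles
#' @export
cycling_frequency <- function(angles, t0, t1) {
  if (t1 <= t0) {
    stop("interval must satisfy t1 > t0", call. = FALSE)
  }
  if (length(angles) != t1 - t0) {
    stop(sprintf(
      "expected %d angles for interval [%d, %d], got %d",
      t1 - t0, t0, t1, length(angles)
    ), call. = FALSE)
  }
  net_cycles(angles) / (t1 - t0)
}
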