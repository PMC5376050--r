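# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals.

# all perfect matchings of a set of labeled players (list of pair lists)
enumerate_matchings <- function(players) {
  if (length(players) == 0) {
    return(list(list()))
  }
  p1 <- players[1]
  rest <- players[-1]
  out <- list()
  for (i in seq_along(rest)) {
    for (sub in enumerate_matchings(rest[-i])) {
      out[[length(out) + 1]] <- c(list(c(p1, rest[i])), sub)
    }
  }
  out
}

# exact pairing-composition distribution by brute-force enumeration of all
# matchings of N labeled players with the given actions
pairing_distribution_oracle <- function(s) {
  N <- sum(s)
  actions <- rep(c("R", "P", "S"), times = s)
  ms <- enumerate_matchings(seq_len(N))
  keys <- vapply(ms, function(m) {
    cnt <- c(rr = 0, pp = 0, ss = 0, rp = 0, ps = 0, sr = 0)
    for (pair in m) {
      ab <- sort(actions[pair])
      key <- switch(
        paste(ab, collapse = ""),
        RR = "rr", PP = "pp", SS = "ss",
        PR = "rp", PS = "ps", RS = "sr"
      )
      cnt[key] <- cnt[key] + 1
    }
    paste(cnt, collapse = "-")
  }, character(1))
  tab <- table(keys) / length(ms)
  tab
}

composition_key <- function(comp_row) {
  paste(comp_row[c("n_rr", "n_pp", "n_ss", "n_rp", "n_ps", "n_sr")],
        collapse = "-")
}

# planar-geometry rotation-angle oracle: project onto an orthonormal basis
# of the plane x + y + z = N and use atan2 of the 2D cross/dot products
rotation_angle_oracle <- function(s, s_next, N) {
  c0 <- rep(N / 3, 3)
  u <- s - c0
  v <- s_next - c0
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  p1 <- c(sum(u * e1), sum(u * e2))
  p2 <- c(sum(v * e1), sum(v * e2))
  if (sum(p1^2) < 1e-12 || sum(p2^2) < 1e-12) {
    return(0)
  }
  cross <- p1[1] * p2[2] - p1[2] * p2[1]
  dot <- sum(p1 * p2)
  if (abs(cross) < 1e-9) {
    return(0)
  }
  atan2(cross, dot)
}

# winding number of a closed loop of states via accumulated atan2 angles
winding_oracle <- function(loop, N) {
  total <- 0
  for (t in seq_len(nrow(loop) - 1)) {
    total <- total + rotation_angle_oracle(loop[t, ], loop[t + 1, ], N)
  }
  total / (2 * pi)
}

# hand-built toy trajectory: 2 players, 4 rounds, actions chosen so that
# every outcome type occurs
toy_trajectory <- function() {
  tibble::tibble(
    session_id = "toy",
    round = rep(1:4, each = 2),
    player = rep(1:2, times = 4),
    action = c("R", "R", "R", "S", "P", "P", "S", "R"),
    opponent = rep(c(2L, 1L), times = 4),
    outcome = c("T", "T", "W", "L", "T", "T", "L", "W"),
    payoff = c(1, 1, 2, 0, 1, 1, 0, 2)
  )
}

# reference strategies discussed throughout: three high-payoff CR rules
# found by simplex sampling at N = 6
gamma_examples <- function() {
  list(
    g1 = cr_strategy(0.002, 0.000, 0.067, 0.110, 0.003, 0.003),
    g2 = cr_strategy(0.995, 0.001, 0.800, 0.058, 0.988, 0.012),
    g3 = cr_strategy(0.001, 0.004, 0.063, 0.791, 0.989, 0.001)
  )
}

uniform_gamma <- function() cr_strategy(1/3, 1/3, 1/3, 1/3, 1/3, 1/3)

# the closed hexagonal loop of permutations of (3, 2, 1) on the N = 6 plane
hexagon_loop <- function() {
  rbind(
    c(3, 2, 1), c(2, 3, 1), c(1, 3, 2), c(1, 2, 3),
    c(2, 1, 3), c(3, 1, 2), c(3, 2, 1)
  )
}
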