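#' Win-lose-tie conditional-response strategies
#'
#' A conditional-response (CR) strategy is a behavioural rule for iterated
#' Rock-Paper-Scissors under random pairwise matching: after each round a
#' player looks only at her own outcome `O` (win, tie, lose) and shifts her
#' action clockwise with probability `O_minus`, counter-clockwise (to the
#' action that beats her current one) with probability `O_plus`, or repeats
#' it with the remaining probability `O_0 = 1 - O_minus - O_plus`. The six
#' free probabilities `{W-, W+; T-, T+; L-, L+}` define the strategy; the
#' win-stay lose-shift (Pavlov) rule is the corner with `W_0 = 1` and
#' `L_0 = 0`.
#'
#' @param W_minus,W_plus,T_minus,T_plus,L_minus,L_plus Shift probabilities
#'   after a win, tie, and loss (clockwise and counter-clockwise). Each pair
#'   must satisfy `O_minus + O_plus <= 1`.
#' @return An object of class `cr_strategy`: a 3 x 3 matrix of response
#'   probabilities with rows `W`, `T`, `L` and columns `minus`, `stay`,
#'   `plus`.
#' @examples
#' # uniform random response, equivalent to the Nash-equilibrium mixed strategy
#' cr_strategy(1/3, 1/3, 1/3, 1/3, 1/3, 1/3)
#' @export
cr_strategy <- function(W_minus, W_plus, T_minus, T_plus, L_minus, L_plus) {
  p <- c(W_minus, W_plus, T_minus, T_plus, L_minus, L_plus)
  if (length(p) != 6 || !is.numeric(p) || any(!is.finite(p))) {
    stop("a CR strategy needs six finite shift probabilities", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("CR shift probabilities must lie in [0, 1]", call. = FALSE)
  }
  stay <- c(1 - W_minus - W_plus, 1 - T_minus - T_plus, 1 - L_minus - L_plus)
  if (any(stay < -1e-12)) {
    stop("O_minus + O_plus must not exceed 1 for each outcome", call. = FALSE)
  }
  m <- cbind(
    minus = c(W_minus, T_minus, L_minus),
    stay = pmax(stay, 0),
    plus = c(W_plus, T_plus, L_plus)
  )
  rownames(m) <- c("W", "T", "L")
  structure(m, class = c("cr_strategy", "matrix"))
}

#' @export
print.cr_strategy <- function(x, digits = 3, ...) {
  cat("<cr_strategy> shift probabilities (clockwise / stay / counter-clockwise)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

as_cr_strategy <- function(gamma) {
  if (inherits(gamma, "cr_strategy")) return(gamma)
  if (is.numeric(gamma) && length(gamma) == 6) {
    return(cr_strategy(gamma[1], gamma[2], gamma[3], gamma[4], gamma[5], gamma[6]))
  }
  stop("gamma must be a cr_strategy or a numeric vector (W-, W+, T-, T+, L-, L+)",
       call. = FALSE)
}

# double factorial (N-1)!! = 1 * 3 * ... * (N-1) for even N
double_factorial_odd <- function(N) {
  prod(seq(1, N - 1, by = 2))
}

#' Distribution of pair-type compositions under random matching
#'
#' Each round the `N` players are partitioned uniformly at random into
#' `N/2` pairs; there are `(N - 1)!!` such perfect matchings. Given the
#' social state `(n_R, n_P, n_S)`, a matching realises a composition of
#' pair types `(n_rr, n_pp, n_ss, n_rp, n_ps, n_sr)`. The number of labeled
#' matchings realising a composition is
#' `n_R! n_P! n_S! / (2^n_rr n_rr! 2^n_pp n_pp! 2^n_ss n_ss! n_rp! n_ps! n_sr!)`,
#' and dividing by `(N - 1)!!` gives the composition's probability.
#'
#' @param s Occupancy triple `(n_R, n_P, n_S)`.
#' @param N Even population size; defaults to `sum(s)`.
#' @return A tibble with one row per feasible composition: the six pair
#'   counts, the number of `matchings` realising it, and its `prob`
#'   (summing to 1).
#' @examples
#' pairing_distribution(c(2, 2, 2))
#' @export
pairing_distribution <- function(s, N = sum(s)) {
  check_even_N(N)
  if (sum(s) != N) {
    stop("state must sum to N", call. = FALSE)
  }
  space <- enumerate_states(N)
  s <- assert_state(space, s)
  comp <- feasible_compositions(s)
  matchings <- apply(comp, 1, composition_matchings, s = s)
  tibble::as_tibble(comp) |>
    dplyr::mutate(
      matchings = matchings,
      prob = matchings / double_factorial_odd(N)
    )
}

# all feasible (n_rr, n_pp, n_ss, n_rp, n_ps, n_sr) for state s; matrix
feasible_compositions <- function(s) {
  s <- unname(s)
  n_R <- s[1]; n_P <- s[2]; n_S <- s[3]
  out <- list()
  for (n_rr in 0:(n_R %/% 2)) {
    for (n_pp in 0:(n_P %/% 2)) {
      for (n_ss in 0:(n_S %/% 2)) {
        rR <- n_R - 2 * n_rr; rP <- n_P - 2 * n_pp; rS <- n_S - 2 * n_ss
        # solve n_rp + n_sr = rR, n_rp + n_ps = rP, n_ps + n_sr = rS
        tot <- rR + rP + rS
        if (tot %% 2 != 0) next
        n_rp <- (rR + rP - rS) / 2
        n_ps <- (rP + rS - rR) / 2
        n_sr <- (rR + rS - rP) / 2
        if (n_rp < 0 || n_ps < 0 || n_sr < 0) next
        if (n_rp != round(n_rp)) next
        out[[length(out) + 1]] <- c(
          n_rr = n_rr, n_pp = n_pp, n_ss = n_ss,
          n_rp = n_rp, n_ps = n_ps, n_sr = n_sr
        )
      }
    }
  }
  do.call(rbind, out)
}

composition_matchings <- function(comp, s) {
  n_rr <- comp[1]; n_pp <- comp[2]; n_ss <- comp[3]
  n_rp <- comp[4]; n_ps <- comp[5]; n_sr <- comp[6]
  factorial(s[1]) * factorial(s[2]) * factorial(s[3]) /
    (2^n_rr * factorial(n_rr) * 2^n_pp * factorial(n_pp) *
       2^n_ss * factorial(n_ss) *
       factorial(n_rp) * factorial(n_ps) * factorial(n_sr))
}

#' Win/lose/tie counts implied by a pairing composition
#'
#' Given the pair-type counts of one round, the dominance relations
#' (R beats S, P beats R, S beats P) fix how many players holding each
#' action win, lose, and tie: R-players win in S-R pairs and lose in R-P
#' pairs; P-players win in R-P pairs and lose in P-S pairs; S-players win
#' in P-S pairs and lose in S-R pairs; same-action pairs tie.
#'
#' @param composition A named numeric vector or one-row data frame with
#'   entries `n_rr, n_pp, n_ss, n_rp, n_ps, n_sr`.
#' @return A tibble with columns `action`, `winners`, `losers`, `tiers`.
#' @examples
#' outcome_counts(c(n_rr = 0, n_pp = 0, n_ss = 1, n_rp = 2, n_ps = 0, n_sr = 0))
#' @export
outcome_counts <- function(composition) {
  cmp <- unlist(composition)[c("n_rr", "n_pp", "n_ss", "n_rp", "n_ps", "n_sr")]
  if (any(is.na(cmp)) || any(cmp < 0)) {
    stop("composition must provide non-negative n_rr, n_pp, n_ss, n_rp, n_ps, n_sr",
         call. = FALSE)
  }
  tibble::tibble(
    action = c("R", "P", "S"),
    winners = c(cmp[["n_sr"]], cmp[["n_rp"]], cmp[["n_ps"]]),
    losers = c(cmp[["n_rp"]], cmp[["n_ps"]], cmp[["n_sr"]]),
    tiers = c(2 * cmp[["n_rr"]], 2 * cmp[["n_pp"]], 2 * cmp[["n_ss"]])
  )
}

# ---------------------------------------------------------------------------
# Precomputed model structure per N (cached): state space, rotation-angle
# matrix, per-state tie fraction, and the flattened composition/group table
# consumed by both the R and the C++ transition-matrix builders.
# Group order: (R,W),(R,T),(R,L),(P,W),(P,T),(P,L),(S,W),(S,T),(S,L).

.rpscycle_cache <- new.env(parent = emptyenv())

model_structure <- function(N) {
  key <- as.character(N)
  if (!is.null(.rpscycle_cache[[key]])) return(.rpscycle_cache[[key]])
  check_even_N(N)
  K <- (N + 1) * (N + 2) / 2
  if (K > 5000) {
    stop("state space too large for the dense engine ((N+1)(N+2)/2 > 5000)",
         call. = FALSE)
  }
  space <- enumerate_states(N)
  st <- as.matrix(space$states[, c("n_R", "n_P", "n_S")])
  comp_state <- integer(0)
  comp_prob <- numeric(0)
  comp_groups <- NULL
  groups_list <- vector("list", K)
  for (i in seq_len(K)) {
    s <- st[i, ]
    comp <- feasible_compositions(s)
    m <- apply(comp, 1, composition_matchings, s = s)
    pr <- m / double_factorial_odd(N)
    oc <- t(apply(comp, 1, function(cm) {
      # winners, tiers, losers per action, in group order
      c(
        cm[["n_sr"]], 2 * cm[["n_rr"]], cm[["n_rp"]], # R: W, T, L
        cm[["n_rp"]], 2 * cm[["n_pp"]], cm[["n_ps"]], # P: W, T, L
        cm[["n_ps"]], 2 * cm[["n_ss"]], cm[["n_sr"]]  # S: W, T, L
      )
    }))
    comp_state <- c(comp_state, rep(i, nrow(comp)))
    comp_prob <- c(comp_prob, pr)
    comp_groups <- rbind(comp_groups, oc)
    groups_list[[i]] <- list(prob = pr, counts = oc)
  }
  storage.mode(comp_groups) <- "integer"
  tie_frac <- (st[, 1] * (st[, 1] - 1) + st[, 2] * (st[, 2] - 1) +
                 st[, 3] * (st[, 3] - 1)) / (N * (N - 1))
  out <- list(
    N = N, K = K, space = space, states = st,
    theta = rotation_angle_matrix(space),
    tie_frac = tie_frac,
    comp_state = comp_state, comp_prob = comp_prob, comp_groups = comp_groups,
    groups_list = groups_list
  )
  .rpscycle_cache[[key]] <- out
  out
}

# destination-action probabilities (to R, to P, to S) for the 9
# (action x outcome) groups, given a 3x3 gamma (rows W,T,L; cols -,0,+)
group_destination_probs <- function(gamma) {
  dest <- matrix(0, 9, 3)
  for (q in 0:2) {
    for (o in 0:2) { # 0=W, 1=T, 2=L
      g <- q * 3 + o + 1
      dest[g, q + 1] <- dest[g, q + 1] + gamma[o + 1, "stay"]
      dest[g, (q + 1) %% 3 + 1] <- dest[g, (q + 1) %% 3 + 1] + gamma[o + 1, "plus"]
      dest[g, (q + 2) %% 3 + 1] <- dest[g, (q + 2) %% 3 + 1] + gamma[o + 1, "minus"]
    }
  }
  dest
}

# convolve independent multinomial groups over the (n_R', n_P') grid;
# groups: list of (k, p) with p = (pR, pP, pS). Returns (N+1) x (N+1) matrix.
convolve_groups <- function(groups, N) {
  D <- matrix(0, N + 1, N + 1)
  D[1, 1] <- 1
  for (g in groups) {
    k <- g$k
    if (k == 0) next
    p <- g$p
    Dn <- matrix(0, N + 1, N + 1)
    for (i in 0:k) {
      for (j in 0:(k - i)) {
        pr <- choose(k, i) * choose(k - i, j) *
          p[1]^i * p[2]^j * p[3]^(k - i - j)
        if (pr == 0) next
        Dn[(1 + i):(N + 1), (1 + j):(N + 1)] <-
          Dn[(1 + i):(N + 1), (1 + j):(N + 1)] +
          pr * D[1:(N + 1 - i), 1:(N + 1 - j)]
      }
    }
    D <- Dn
  }
  D
}

# distribution over next states from one set of 9 group counts
grid_to_state_probs <- function(D, struct) {
  idx <- cbind(struct$states[, 1] + 1L, struct$states[, 2] + 1L)
  D[idx]
}

#' Exact transition matrix of the conditional-response model
#'
#' Builds the row-stochastic Markov matrix `M[s' | s]` of a homogeneous
#' population in which every player applies the same CR strategy. For each
#' current state the pairing composition is drawn from
#' [pairing_distribution()], outcomes follow from dominance, and every
#' player independently shifts according to her outcome row of `gamma`; the
#' next-state distribution is the convolution of the nine
#' (action x outcome) multinomial groups, averaged over compositions.
#'
#' @param gamma A [cr_strategy()] (or numeric vector
#'   `(W-, W+, T-, T+, L-, L+)`).
#' @param N Even population size.
#' @param engine `"cpp"` (compiled convolution, default) or `"r"` (the
#'   reference implementation in plain R); both produce identical matrices
#'   and are cross-checked in the test suite.
#' @return An object of class `cr_markov`: list with the `state_space`, the
#'   `K x K` transition `matrix`, and the strategy.
#' @examples
#' m <- cr_transition_matrix(cr_strategy(1/3, 1/3, 1/3, 1/3, 1/3, 1/3), N = 6)
#' range(rowSums(m$matrix)) # each row sums to 1
#' @export
cr_transition_matrix <- function(gamma, N, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  gamma <- as_cr_strategy(gamma)
  struct <- model_structure(N)
  if (engine == "cpp") {
    M <- build_cr_matrix_cpp(
      unclass(gamma), struct$N, struct$K,
      struct$comp_state, struct$comp_prob, struct$comp_groups,
      struct$states
    )
  } else {
    dest <- group_destination_probs(gamma)
    K <- struct$K
    M <- matrix(0, K, K)
    for (i in seq_len(K)) {
      gl <- struct$groups_list[[i]]
      for (r in seq_along(gl$prob)) {
        counts <- gl$counts[r, ]
        groups <- lapply(which(counts > 0), function(g) {
          list(k = counts[g], p = dest[g, ])
        })
        D <- convolve_groups(groups, N)
        M[i, ] <- M[i, ] + gl$prob[r] * grid_to_state_probs(D, struct)
      }
    }
  }
  structure(
    list(space = struct$space, matrix = M, gamma = gamma, N = N),
    class = "cr_markov"
  )
}

#' @export
print.cr_markov <- function(x, ...) {
  cat(sprintf(
    "<cr_markov> N = %d, %d x %d transition matrix\n",
    x$N, nrow(x$matrix), ncol(x$matrix)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Chain diagnostics and stationary distribution

# strongly connected components of the directed graph M > 0 (Kosaraju)
strong_components <- function(A) {
  K <- nrow(A)
  adj <- apply(A, 1, function(r) which(r), simplify = FALSE)
  radj <- apply(A, 2, function(r) which(r), simplify = FALSE)
  visited <- logical(K)
  order <- integer(0)
  for (start in seq_len(K)) {
    if (visited[start]) next
    # iterative DFS recording finish order
    stack <- list(list(v = start, i = 0L))
    visited[start] <- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$v]]
      if (top$i < length(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        w <- nbrs[top$i + 1L]
        if (!visited[w]) {
          visited[w] <- TRUE
          stack[[length(stack) + 1]] <- list(v = w, i = 0L)
        }
      } else {
        order <- c(order, top$v)
        stack[[length(stack)]] <- NULL
      }
    }
  }
  comp <- integer(K)
  cur <- 0L
  for (v in rev(order)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in radj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# period of an irreducible chain: gcd of (d[u] + 1 - d[v]) over edges,
# with d the BFS levels from state 1
chain_period <- function(A) {
  K <- nrow(A)
  d <- rep(NA_integer_, K)
  d[1] <- 0L
  queue <- 1L
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]
    for (w in which(A[u, ])) {
      if (is.na(d[w])) {
        d[w] <- d[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  g <- 0L
  for (u in seq_len(K)) {
    for (w in which(A[u, ])) {
      diff <- abs(d[u] + 1L - d[w])
      g <- if (g == 0L) diff else if (diff == 0L) g else gcd_int(g, diff)
    }
  }
  if (g == 0L) 1L else g
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

format_state_set <- function(states, idx, max_show = 4) {
  shown <- utils::head(idx, max_show)
  lab <- apply(states[shown, , drop = FALSE], 1, function(s) {
    sprintf("(%d,%d,%d)", s[1], s[2], s[3])
  })
  extra <- if (length(idx) > max_show) sprintf(" ... [%d states]", length(idx)) else ""
  paste0("{", paste(lab, collapse = ", "), extra, "}")
}

#' Stationary distribution of a conditional-response chain
#'
#' Solves `pi M = pi`, `sum(pi) = 1` as a dense linear system (one balance
#' equation replaced by the normalisation constraint). The chain must be
#' irreducible and aperiodic on the whole state space, which is checked by
#' directed reachability over the non-zero entries; degenerate strategies
#' (e.g. everyone always repeats, or everyone shifts deterministically)
#' produce reducible or periodic chains and raise an error naming the
#' recurrent classes rather than silently averaging.
#'
#' @param model A `cr_markov` from [cr_transition_matrix()] (or any list
#'   with elements `matrix` and `space`).
#' @return Numeric probability vector over the canonical state order, with
#'   residual `max |pi M - pi| <= 1e-12`.
#' @export
steady_state <- function(model) {
  M <- model$matrix
  K <- nrow(M)
  A <- M > 0
  comp <- strong_components(A)
  if (max(comp) > 1) {
    # closed classes: components with no edge leaving them
    closed <- vapply(seq_len(max(comp)), function(cid) {
      members <- which(comp == cid)
      !any(A[members, -members, drop = FALSE])
    }, logical(1))
    states <- as.matrix(model$space$states[, c("n_R", "n_P", "n_S")])
    msg <- vapply(which(closed), function(cid) {
      format_state_set(states, which(comp == cid))
    }, character(1))
    stop(sprintf(
      "chain is reducible: %d recurrent class(es) %s",
      sum(closed), paste(msg, collapse = ", ")
    ), call. = FALSE)
  }
  per <- chain_period(A)
  if (per > 1) {
    stop(sprintf("chain is periodic with period %d; no unique steady state", per),
         call. = FALSE)
  }
  B <- t(M) - diag(K)
  B[K, ] <- 1
  b <- c(rep(0, K - 1), 1)
  pi_star <- solve(B, b)
  resid <- max(abs(drop(pi_star %*% M) - pi_star))
  if (resid > 1e-12 || any(pi_star < -1e-12)) {
    stop(sprintf("stationary solve failed (residual %.2e)", resid), call. = FALSE)
  }
  pmax(pi_star, 0)
}

# ---------------------------------------------------------------------------
# Model summaries

#' Fit the exact conditional-response model
#'
#' Builds the transition matrix for a homogeneous CR population, solves the
#' stationary distribution, and derives the steady-state observables:
#'
#' * `f_cr` — mean cycling frequency,
#'   `(1 / 2 pi) * sum_s sum_s' pi(s) M[s'|s] theta(s -> s')`, in cycles per
#'   round (positive = counter-clockwise, R-rich toward P-rich);
#' * `tau_cr` — expected fraction of tie pairs among the `N/2` pairs,
#'   `sum_s pi(s) [n_R(n_R - 1) + n_P(n_P - 1) + n_S(n_S - 1)] / (N(N - 1))`;
#' * `payoff_coeff` — `(1/3 - tau_cr) / 2`, the coefficient of `(a - 2)` in
#'   the payoff gap over the Nash benchmark;
#' * `g_cr` — expected payoff per round,
#'   `g0 + (a - 2) (1/3 - tau_cr) / 2` with `g0 = (1 + a) / 3`
#'   (equivalently `tau_cr + (1 - tau_cr) a / 2`);
#' * the predicted action-shift profile (stay / counter-clockwise /
#'   clockwise), identical for all three current actions by the model's
#'   cyclic symmetry.
#'
#' `f_cr`, `tau_cr` and the stationary distribution depend only on
#' `(gamma, N)`; the payoff parameter `a` enters only through `g_cr`.
#'
#' @inheritParams cr_transition_matrix
#' @param a Payoff of the winning action (`a > 1`; ties pay 1, losses 0).
#' @return An object of class `cr_model` with elements `gamma`, `N`, `a`,
#'   `matrix`, `stationary`, `f_cr`, `tau_cr`, `payoff_coeff`, `g0`, `g_cr`
#'   and `shift_profile` (a tibble). Use [glance()] for a one-row summary.
#' @examples
#' fit <- cr_model(cr_strategy(0.001, 0.004, 0.063, 0.791, 0.989, 0.001), N = 6)
#' round(fit$f_cr, 3)
#' @export
cr_model <- function(gamma, N = 6, a = 2, engine = c("cpp", "r")) {
  if (length(a) != 1 || !is.finite(a) || a <= 1) {
    stop("payoff parameter a must be a single number > 1", call. = FALSE)
  }
  chain <- cr_transition_matrix(gamma, N, engine = match.arg(engine))
  struct <- model_structure(N)
  pi_star <- steady_state(chain)
  f_cr <- sum(pi_star * rowSums(chain$matrix * struct$theta)) / (2 * pi)
  tau_cr <- sum(pi_star * struct$tie_frac)
  g0 <- (1 + a) / 3
  payoff_coeff <- (1 / 3 - tau_cr) / 2
  g_cr <- g0 + (a - 2) * payoff_coeff
  pW <- (1 - tau_cr) / 2
  wts <- c(W = pW, T = tau_cr, L = pW)
  gm <- unclass(chain$gamma)
  shift_profile <- tibble::tibble(
    shift = c("stay", "ccw", "cw"),
    prob = c(
      sum(wts * gm[, "stay"]),
      sum(wts * gm[, "plus"]),
      sum(wts * gm[, "minus"])
    )
  )
  structure(
    list(
      gamma = chain$gamma, N = N, a = a, space = chain$space,
      matrix = chain$matrix, stationary = pi_star,
      f_cr = f_cr, tau_cr = tau_cr, payoff_coeff = payoff_coeff,
      g0 = g0, g_cr = g_cr, shift_profile = shift_profile
    ),
    class = "cr_model"
  )
}

#' @export
print.cr_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cr_model> N = %d, a = %g\n",
      "  cycling frequency f_cr  = %+.4f cycles/round\n",
      "  tie fraction      tau   = %.4f\n",
      "  expected payoff   g_cr  = %.4f  (Nash benchmark g0 = %.4f)\n",
      "  payoff gap        g_cr - g0 = %+.4f * (a - 2)\n"
    ),
    x$N, x$a, x$f_cr, x$tau_cr, x$g_cr, x$g0, x$payoff_coeff
  ))
  invisible(x)
}

#' Steady-state observables of a CR strategy
#'
#' Convenience wrappers around [cr_model()] returning single quantities:
#' the steady-state cycling frequency (cycles per round), the expected tie
#' fraction among pairs, the expected payoff per round under winning payoff
#' `a`, and the model-predicted action-shift profile.
#'
#' @inheritParams cr_model
#' @return A single numeric value (`model_cycling_frequency`,
#'   `tie_fraction`, `expected_payoff`) or a tibble with columns `shift`
#'   and `prob` (`predicted_shift_profile`).
#' @examples
#' tie_fraction(cr_strategy(1/3, 1/3, 1/3, 1/3, 1/3, 1/3), N = 6) # 1/3
#' @export
model_cycling_frequency <- function(gamma, N = 6) {
  cr_model(gamma, N)$f_cr
}

#' @rdname model_cycling_frequency
#' @export
tie_fraction <- function(gamma, N = 6) {
  cr_model(gamma, N)$tau_cr
}

#' @rdname model_cycling_frequency
#' @export
expected_payoff <- function(gamma, N = 6, a = 2) {
  cr_model(gamma, N, a = a)$g_cr
}

#' @rdname model_cycling_frequency
#' @export
predicted_shift_profile <- function(gamma, N = 6) {
  cr_model(gamma, N)$shift_profile
}

#' Cycling frequency of the independent-decision null model
#'
#' The null model against which social cycling is judged: each player's
#' next action depends only on her own current action, through per-action
#' probabilities of staying, shifting counter-clockwise, or clockwise —
#' opponents' behaviour and outcomes play no role. The population
#' transition matrix is the convolution of the three per-action multinomial
#' groups; its stationary cycling frequency is returned. Empirical shift
#' profiles fed through this model give frequencies near zero even when the
#' data that produced them cycle strongly, which is the signature that
#' cycling is carried by win-lose-tie conditioning rather than by action
#' inertia alone.
#'
#' @param profile Per-action shift probabilities: a data frame with columns
#'   `action` (`"R"`, `"P"`, `"S"`), `p_stay`, `p_ccw`, `p_cw` (rows may be
#'   in any order; each triple must sum to 1), e.g. the output of
#'   [estimate_shift_profile()].
#' @param N Even population size.
#' @return Steady-state cycling frequency in cycles per round.
#' @examples
#' prof <- tibble::tibble(
#'   action = c("R", "P", "S"),
#'   p_stay = 1/3, p_ccw = 1/3, p_cw = 1/3
#' )
#' independent_model_frequency(prof, N = 6) # 0
#' @export
independent_model_frequency <- function(profile, N = 6) {
  profile <- as.data.frame(profile)
  need <- c("action", "p_stay", "p_ccw", "p_cw")
  if (!all(need %in% names(profile)) || !setequal(profile$action, ACTIONS)) {
    stop("profile must have columns action (R, P, S), p_stay, p_ccw, p_cw",
         call. = FALSE)
  }
  rownames(profile) <- profile$action
  pr <- as.matrix(profile[ACTIONS, c("p_stay", "p_ccw", "p_cw")])
  if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-8)) {
    stop("each action's (stay, ccw, cw) triple must be non-negative and sum to 1",
         call. = FALSE)
  }
  struct <- model_structure(N)
  K <- struct$K
  # destination probabilities per current action
  dest <- matrix(0, 3, 3)
  for (q in 0:2) {
    dest[q + 1, q + 1] <- dest[q + 1, q + 1] + pr[q + 1, "p_stay"]
    dest[q + 1, (q + 1) %% 3 + 1] <- dest[q + 1, (q + 1) %% 3 + 1] + pr[q + 1, "p_ccw"]
    dest[q + 1, (q + 2) %% 3 + 1] <- dest[q + 1, (q + 2) %% 3 + 1] + pr[q + 1, "p_cw"]
  }
  M <- matrix(0, K, K)
  for (i in seq_len(K)) {
    groups <- lapply(1:3, function(q) list(k = struct$states[i, q], p = dest[q, ]))
    D <- convolve_groups(groups, N)
    M[i, ] <- grid_to_state_probs(D, struct)
  }
  model <- list(matrix = M, space = struct$space)
  pi_star <- steady_state(model)
  sum(pi_star * rowSums(M * struct$theta)) / (2 * pi)
}

#' Write a one-line JSON summary of a fitted CR model
#'
#' Serialises the fitted model's strategy and steady-state observables with
#' keys `gamma`, `N`, `f_cr`, `tau_cr`, `g_cr_coeff`.
#'
#' @param model A `cr_model`.
#' @param path File path; use `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_model_summary <- function(model, path = NULL) {
  stopifnot(inherits(model, "cr_model"))
  gm <- unclass(model$gamma)
  obj <- list(
    gamma = list(
      W_minus = gm["W", "minus"], W_plus = gm["W", "plus"],
      T_minus = gm["T", "minus"], T_plus = gm["T", "plus"],
      L_minus = gm["L", "minus"], L_plus = gm["L", "plus"]
    ),
    N = model$N,
    f_cr = model$f_cr,
    tau_cr = model$tau_cr,
    g_cr_coeff = model$payoff_coeff
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
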