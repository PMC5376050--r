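#' Agent policies for simulated Rock-Paper-Scissors sessions
#'
#' Four behavioural variants are available for the agent-based simulator:
#'
#' * `policy_cr(gamma)` — win-lose-tie conditional response: the agent
#'   shifts clockwise / stays / shifts counter-clockwise according to the
#'   outcome row of her [cr_strategy()];
#' * `policy_ne()` — the Nash-equilibrium mixed strategy: uniform iid
#'   choice each round;
#' * `policy_independent(profile)` — the independent-decision rule: the
#'   next action depends only on the agent's own current action through a
#'   per-action (stay, ccw, cw) triple;
#' * `policy_fixed(action)` — always plays `action`.
#'
#' In round 1 no prior outcome exists: fixed agents play their action and
#' all other policies choose uniformly at random.
#'
#' @param gamma A [cr_strategy()].
#' @param profile Data frame with columns `action`, `p_stay`, `p_ccw`,
#'   `p_cw` covering R, P, S (each row summing to 1).
#' @param action One of `"R"`, `"P"`, `"S"`.
#' @return An object of class `agent_policy`.
#' @examples
#' policy_cr(cr_strategy(0.1, 0.1, 0.2, 0.2, 0.3, 0.3))
#' @export
policy_cr <- function(gamma) {
  gamma <- as_cr_strategy(gamma)
  gm <- unclass(gamma)
  structure(
    list(
      variant = "cr",
      params = as.numeric(t(gm[, c("minus", "stay", "plus")]))
    ),
    gamma = gamma,
    class = "agent_policy"
  )
}

#' @rdname policy_cr
#' @export
policy_ne <- function() {
  structure(list(variant = "ne", params = numeric(9)), class = "agent_policy")
}

#' @rdname policy_cr
#' @export
policy_independent <- function(profile) {
  profile <- as.data.frame(profile)
  need <- c("action", "p_stay", "p_ccw", "p_cw")
  if (!all(need %in% names(profile)) || !setequal(profile$action, ACTIONS)) {
    stop("profile must have columns action (R, P, S), p_stay, p_ccw, p_cw",
         call. = FALSE)
  }
  rownames(profile) <- profile$action
  pr <- as.matrix(profile[ACTIONS, c("p_cw", "p_stay", "p_ccw")])
  if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-8)) {
    stop("each action's shift triple must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(
    list(variant = "independent", params = as.numeric(t(pr))),
    class = "agent_policy"
  )
}

#' @rdname policy_cr
#' @export
policy_fixed <- function(action) {
  assert_actions(action)
  structure(
    list(variant = "fixed", params = c(action_code(action), numeric(8))),
    action = action,
    class = "agent_policy"
  )
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf("<agent_policy> %s\n", x$variant))
  invisible(x)
}

policy_code <- function(p) {
  switch(p$variant, cr = 0L, ne = 1L, independent = 2L, fixed = 3L)
}

#' Session configuration for the simulator
#'
#' Bundles the parameters of one simulated session: population size,
#' number of rounds, winning payoff `a`, one [agent policy][policy_cr] per
#' player (a single policy is recycled to all `N` players), and the RNG
#' seed. The defaults mirror the laboratory protocol this package models:
#' six players, 300 rounds, random pairwise matching.
#'
#' @param N Even population size.
#' @param rounds Number of rounds (>= 1).
#' @param a Winning payoff (`a > 1`); ties pay 1, losses 0. Payoffs are
#'   recorded per round even though CR play does not depend on `a`.
#' @param policies A single `agent_policy` or a list of `N` of them.
#' @param seed Integer RNG seed.
#' @param session_id Label stored in the trajectory.
#' @return A list of class `session_config`.
#' @export
session_config <- function(N = 6, rounds = 300, a = 2,
                           policies = policy_ne(), seed = 1,
                           session_id = "session1") {
  check_even_N(N)
  if (length(rounds) != 1 || rounds < 1 || rounds != round(rounds)) {
    stop("rounds must be a positive integer", call. = FALSE)
  }
  if (length(a) != 1 || !is.finite(a) || a <= 1) {
    stop("payoff parameter a must be a single number > 1", call. = FALSE)
  }
  if (inherits(policies, "agent_policy")) {
    policies <- rep(list(policies), N)
  }
  if (!is.list(policies) || length(policies) != N ||
      !all(vapply(policies, inherits, logical(1), "agent_policy"))) {
    stop("policies must be one agent_policy or a list of N of them", call. = FALSE)
  }
  structure(
    list(
      N = as.integer(N), rounds = as.integer(rounds), a = a,
      policies = policies, seed = as.integer(seed),
      session_id = as.character(session_id)
    ),
    class = "session_config"
  )
}

#' Draw a uniform random pairwise matching
#'
#' Partitions players `1..N` uniformly at random into `N/2` pairs (each of
#' the `(N - 1)!!` perfect matchings is equally likely), by shuffling the
#' players and pairing consecutive entries. Uses R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param N Even number of players.
#' @return An integer vector `opponent` of length `N`: `opponent[i]` is the
#'   player matched with `i` (an involution with no fixed point).
#' @examples
#' set.seed(1)
#' random_matching(6)
#' @export
random_matching <- function(N) {
  check_even_N(N)
  perm <- sample.int(N)
  opponent <- integer(N)
  odd <- perm[seq(1, N, by = 2)]
  even <- perm[seq(2, N, by = 2)]
  opponent[odd] <- even
  opponent[even] <- odd
  opponent
}

#' Simulate one iterated Rock-Paper-Scissors session
#'
#' Runs the discrete-round protocol: each round the players are paired by
#' a fresh uniform random matching, play one Rock-Paper-Scissors game
#' against their opponent, observe their own outcome, and choose the next
#' round's action according to their policy. Trajectories are byte-identical
#' across runs with the same configuration (seed included).
#'
#' @param config A [session_config()].
#' @return A trajectory tibble with one row per (round, player): columns
#'   `session_id`, `round`, `player`, `action`, `opponent`, `outcome`
#'   (`"W"`/`"T"`/`"L"`), `payoff`. The configuration is attached as
#'   attribute `"config"`.
#' @examples
#' traj <- simulate_session(session_config(N = 6, rounds = 20, seed = 7))
#' head(traj)
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "session_config")) {
    stop("config must be a session_config", call. = FALSE)
  }
  N <- config$N
  rounds <- config$rounds
  pol <- vapply(config$policies, policy_code, integer(1))
  par <- t(vapply(config$policies, function(p) p$params, numeric(9)))
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  core <- sim_core_cpp(pol, par, N, rounds)
  act <- core$action # rounds x N, codes 0..2
  opp <- core$opponent
  my <- as.vector(act)
  opp_act <- as.vector(act[cbind(rep(seq_len(rounds), N), as.vector(opp))])
  d <- (my - opp_act) %% 3L
  outcome <- c("T", "W", "L")[d + 1L]
  payoff <- payoff_of(outcome, config$a)
  traj <- tibble::tibble(
    session_id = config$session_id,
    round = rep(seq_len(rounds), times = N),
    player = rep(seq_len(N), each = rounds),
    action = ACTIONS[my + 1L],
    opponent = as.vector(opp),
    outcome = outcome,
    payoff = payoff
  ) |>
    dplyr::arrange(.data$round, .data$player)
  attr(traj, "config") <- config
  traj
}

#' Simulate a batch of independent sessions
#'
#' Replicates a session configuration `n_sessions` times with independent
#' seeds, emulating a set of experimental populations playing under the
#' same payoff parameter. Child seeds are derived deterministically from
#' the master seed (drawn by `sample.int()` under `set.seed(master_seed)`),
#' so a batch is fully reproducible and its sessions have independent RNG
#' streams.
#'
#' @param config A [session_config()] template (its `seed` and
#'   `session_id` are overridden per session).
#' @param n_sessions Number of sessions (>= 1).
#' @param master_seed Integer master seed.
#' @return A list of trajectory tibbles, named `session01`, `session02`, ...
#' @export
batch_sessions <- function(config, n_sessions, master_seed = 1) {
  if (!inherits(config, "session_config")) {
    stop("config must be a session_config", call. = FALSE)
  }
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(master_seed)
  child <- sample.int(.Machine$integer.max, n_sessions)
  ids <- sprintf("session%02d", seq_len(n_sessions))
  out <- lapply(seq_len(n_sessions), function(i) {
    cfg <- config
    cfg$seed <- child[i]
    cfg$session_id <- ids[i]
    simulate_session(cfg)
  })
  names(out) <- ids
  out
}
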