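#' Read and write trajectory CSV files
#'
#' Trajectories are exchanged as plain CSV with columns `session_id`,
#' `round` (1-based, contiguous), `player` (1..N), `action` (`R`/`P`/`S`),
#' `opponent` (1..N) and optionally `payoff`. Outcomes are *derived* data:
#' on read they are recomputed from the actions and the matching, and when
#' a payoff column is present it is verified against the recomputed
#' outcomes (ties must pay 1, losses 0, and all wins the same `a > 1`);
#' inconsistencies raise errors naming the offending round. The
#' write/read round trip is lossless for the schema columns.
#'
#' @param traj Trajectory tibble (see [simulate_session()]).
#' @param path CSV file path.
#' @return `read_trajectory()` returns the validated trajectory tibble
#'   with a recomputed `outcome` column; `write_trajectory()` returns
#'   `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  check_trajectory_frame(traj, need = c("session_id", "round", "player", "action", "opponent"))
  cols <- intersect(
    c("session_id", "round", "player", "action", "opponent", "payoff"),
    names(traj)
  )
  readr::write_csv(traj[cols], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  known <- list(
    session_id = readr::col_character(),
    round = readr::col_integer(),
    player = readr::col_integer(),
    action = readr::col_character(),
    opponent = readr::col_integer(),
    outcome = readr::col_character()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec <- do.call(readr::cols, c(known[intersect(names(known), header)],
                                 .default = list(readr::col_double())))
  traj <- readr::read_csv(path, col_types = spec)
  need <- c("session_id", "round", "player", "action", "opponent")
  if (!all(need %in% names(traj))) {
    stop(sprintf(
      "trajectory file must have columns %s", paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  validate_trajectory(traj)
}

validate_trajectory <- function(traj) {
  assert_actions(traj$action)
  for (sid in unique(traj$session_id)) {
    tr <- traj[traj$session_id == sid, ]
    players <- sort(unique(tr$player))
    N <- length(players)
    if (!identical(players, seq_len(N)) || N %% 2 != 0) {
      stop(sprintf(
        "session %s: players must be 1..N with N even (found %s)",
        sid, paste(players, collapse = ",")
      ), call. = FALSE)
    }
    rounds <- sort(unique(tr$round))
    if (!identical(rounds, seq_len(length(rounds)))) {
      gap <- setdiff(seq_len(max(rounds)), rounds)[1]
      stop(sprintf("session %s: rounds must be contiguous from 1 (missing round %d)",
                   sid, gap), call. = FALSE)
    }
    tr <- tr[order(tr$round, tr$player), ]
    if (nrow(tr) != N * length(rounds)) {
      stop(sprintf("session %s: expected one row per (round, player)", sid),
           call. = FALSE)
    }
    opp <- matrix(tr$opponent, nrow = N)
    act <- matrix(action_code(tr$action), nrow = N)
    for (t in seq_along(rounds)) {
      o <- opp[, t]
      if (any(o < 1 | o > N) || any(o == seq_len(N)) || any(o[o] != seq_len(N))) {
        stop(sprintf(
          "session %s, round %d: opponent column is not a perfect matching",
          sid, t
        ), call. = FALSE)
      }
    }
  }
  # recompute outcomes from actions + matching
  traj <- traj |>
    dplyr::group_by(.data$session_id, .data$round) |>
    dplyr::mutate(outcome = outcome_of(.data$action, .data$action[.data$opponent])) |>
    dplyr::ungroup()
  if ("payoff" %in% names(traj)) {
    bad_tie <- traj$outcome == "T" & traj$payoff != 1
    bad_lose <- traj$outcome == "L" & traj$payoff != 0
    if (any(bad_tie | bad_lose)) {
      r <- traj$round[which(bad_tie | bad_lose)[1]]
      stop(sprintf("payoff inconsistent with outcome at round %d (ties pay 1, losses 0)", r),
           call. = FALSE)
    }
    wins <- traj$payoff[traj$outcome == "W"]
    if (length(wins) > 0) {
      a <- wins[1]
      if (a <= 1 || any(wins != a)) {
        r <- traj$round[traj$outcome == "W"][which(wins != a | wins <= 1)[1]]
        stop(sprintf("winning payoffs must all equal one value a > 1 (violated at round %d)", r),
             call. = FALSE)
      }
    }
  }
  traj
}

#' Per-session empirical cycling frequencies fixture
#'
#' The packaged table of per-session cycling frequencies `f` observed over
#' rounds 1-300 in 59 six-player laboratory populations, grouped by the
#' payoff parameter `a` (11 sessions at `a = 1.1`, 12 each at
#' `a = 2, 4, 9, 100`). This is the input to the population-summary
#' pipeline ([summarize_populations()], [test_positive_frequency()],
#' [rank_correlation()]).
#'
#' @return A tibble with columns `a`, `session`, `f` (59 rows).
#' @examples
#' summarize_populations(session_frequencies())
#' @export
session_frequencies <- function() {
  path <- system.file("extdata", "session_cycling_frequencies.csv",
                      package = "rpscycle", mustWork = TRUE)
  readr::read_csv(path, col_types = "did", col_names = TRUE,
                  show_col_types = FALSE)
}

#' Read a run configuration from JSON
#'
#' Parses a JSON configuration with fields `N`, `rounds`, `a`, `seed`,
#' `session_id` and a `policy` specification (either one object applied to
#' all players or an array of `N` objects). A policy object has a `type`
#' (`"cr"`, `"ne"`, `"independent"`, `"fixed"`) and its parameters:
#' `gamma` as `[W-, W+, T-, T+, L-, L+]` for `"cr"`, a `profile` table for
#' `"independent"`, an `action` for `"fixed"`.
#'
#' @param path JSON file path.
#' @return A [session_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_policy <- function(p) {
    switch(
      p$type,
      cr = policy_cr(as.numeric(unlist(p$gamma))),
      ne = policy_ne(),
      independent = policy_independent(as.data.frame(p$profile)),
      fixed = policy_fixed(p$action),
      stop(sprintf("unknown policy type: %s", p$type), call. = FALSE)
    )
  }
  pol <- cfg$policy
  policies <- if (!is.null(pol$type)) {
    parse_policy(pol)
  } else {
    lapply(pol, parse_policy)
  }
  session_config(
    N = cfg$N %||% 6,
    rounds = cfg$rounds %||% 300,
    a = cfg$a %||% 2,
    policies = policies,
    seed = cfg$seed %||% 1,
    session_id = cfg$session_id %||% "session1"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
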