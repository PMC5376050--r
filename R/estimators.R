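#' Per-round social states of a trajectory
#'
#' Collapses a per-player trajectory to the population's occupancy triple
#' `(n_R, n_P, n_S)` per round.
#'
#' @param traj Trajectory tibble with columns `round`, `player`, `action`
#'   (as produced by [simulate_session()] or [read_trajectory()]).
#' @return A tibble with columns `round`, `n_R`, `n_P`, `n_S`, one row per
#'   round in order.
#' @examples
#' traj <- simulate_session(session_config(rounds = 5, seed = 1))
#' social_states_of(traj)
#' @export
social_states_of <- function(traj) {
  check_trajectory_frame(traj)
  N <- length(unique(traj$player))
  st <- traj |>
    dplyr::count(.data$round, .data$action) |>
    tidyr::pivot_wider(
      names_from = "action", values_from = "n", values_fill = 0L
    )
  for (q in ACTIONS) {
    if (!q %in% names(st)) st[[q]] <- 0L
  }
  st <- st |>
    dplyr::transmute(
      round = .data$round, n_R = .data$R, n_P = .data$P, n_S = .data$S
    ) |>
    dplyr::arrange(.data$round)
  bad <- which(st$n_R + st$n_P + st$n_S != N)
  if (length(bad) > 0) {
    stop(sprintf("round %d does not have one action per player", st$round[bad[1]]),
         call. = FALSE)
  }
  st
}

check_trajectory_frame <- function(traj, need = c("round", "player", "action")) {
  if (!is.data.frame(traj) || !all(need %in% names(traj))) {
    stop(sprintf("trajectory must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  assert_actions(traj$action)
  invisible(traj)
}

#' Net cycles and cycling frequency of one session
#'
#' Measures collective cycling over the interval `[t0, t1]`: the social
#' states of consecutive rounds are turned into rotation angles around the
#' centroid of the state plane ([rotation_angle()]), summed into the net
#' cycle count `C`, and normalised by the `t1 - t0` transitions to give the
#' cycling frequency `f`. Sub-intervals (e.g. first and second half of a
#' session) are supported.
#'
#' @inheritParams social_states_of
#' @param t0,t1 First and last round of the analysis interval (1-based,
#'   closed); defaults to the whole session.
#' @return A one-row tibble with columns `t0`, `t1`, `n_transitions`,
#'   `net_cycles`, `frequency`.
#' @examples
#' traj <- simulate_session(session_config(rounds = 50, seed = 2))
#' session_cycling(traj)
#' @export
session_cycling <- function(traj, t0 = NULL, t1 = NULL) {
  st <- social_states_of(traj)
  rounds <- nrow(st)
  if (is.null(t0)) t0 <- 1L
  if (is.null(t1)) t1 <- rounds
  if (t0 < 1 || t1 > rounds || t1 <= t0) {
    stop(sprintf("interval [%s, %s] invalid for a %d-round trajectory", t0, t1, rounds),
         call. = FALSE)
  }
  N <- st$n_R[1] + st$n_P[1] + st$n_S[1]
  space <- enumerate_states(N)
  angles <- trajectory_angles(st, space)[seq(t0, t1 - 1)]
  C <- net_cycles(angles)
  tibble::tibble(
    t0 = as.integer(t0), t1 = as.integer(t1),
    n_transitions = as.integer(t1 - t0),
    net_cycles = C,
    frequency = C / (t1 - t0)
  )
}

# per-transition rotation angles of a state sequence, via the precomputed
# pairwise angle matrix (equivalent to rotation_angle() call by call, but
# vectorised so million-round sessions are cheap)
trajectory_angles <- function(st, space) {
  idx <- state_index(space, st$n_R, st$n_P)
  theta <- rotation_angle_matrix(space)
  n <- length(idx)
  theta[cbind(idx[-n], idx[-1])]
}

# classify per-player action transitions: 0 stay, 1 ccw, 2 cw
shift_table <- function(traj) {
  check_trajectory_frame(traj)
  traj |>
    dplyr::arrange(.data$player, .data$round) |>
    dplyr::group_by(.data$player) |>
    dplyr::mutate(
      next_action = dplyr::lead(.data$action)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_action)) |>
    dplyr::mutate(
      shift = c("stay", "ccw", "cw")[
        ((action_code(.data$next_action) - action_code(.data$action)) %% 3L) + 1L
      ]
    )
}

#' Empirical action-shift profile of a trajectory
#'
#' For each current action, the observed probabilities that a player
#' repeats it at the next round (`p_stay`), shifts counter-clockwise to the
#' action that beats it (`p_ccw`, R to P, P to S, S to R), or shifts
#' clockwise (`p_cw`). An action never observed has `n = 0` and `NA`
#' probabilities rather than silent zeros.
#'
#' @inheritParams social_states_of
#' @return A tibble with one row per action: `action`, `n` (transition
#'   count), `p_stay`, `p_ccw`, `p_cw`.
#' @export
estimate_shift_profile <- function(traj) {
  tab <- shift_table(traj)
  counts <- tab |>
    dplyr::count(.data$action, .data$shift) |>
    tidyr::pivot_wider(names_from = "shift", values_from = "n", values_fill = 0L)
  for (col in c("stay", "ccw", "cw")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tibble::tibble(action = ACTIONS) |>
    dplyr::left_join(counts, by = "action") |>
    dplyr::mutate(dplyr::across(c("stay", "ccw", "cw"), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(
      n = .data$stay + .data$ccw + .data$cw,
      p_stay = ifelse(.data$n > 0, .data$stay / .data$n, NA_real_),
      p_ccw = ifelse(.data$n > 0, .data$ccw / .data$n, NA_real_),
      p_cw = ifelse(.data$n > 0, .data$cw / .data$n, NA_real_)
    ) |>
    dplyr::select("action", "n", "p_stay", "p_ccw", "p_cw")
}

#' Empirical conditional-response parameters of a trajectory
#'
#' Maximum-likelihood estimates of the win-lose-tie conditional-response
#' probabilities: every transition from round `t` to `t + 1` is classified
#' by the player's outcome at `t` (win, tie, lose) and by the direction of
#' her action shift (clockwise, stay, counter-clockwise); per-outcome
#' proportions and their binomial standard errors are returned. Outcomes
#' with no events are flagged by `n = 0` and `NA` estimates.
#'
#' @param traj Trajectory tibble with columns `round`, `player`, `action`,
#'   `outcome`.
#' @return A tibble with one row per outcome (`W`, `T`, `L`): event count
#'   `n`, estimates `p_minus`, `p_stay`, `p_plus`, and standard errors
#'   `se_minus`, `se_stay`, `se_plus`.
#' @export
estimate_cr_parameters <- function(traj) {
  check_trajectory_frame(traj, need = c("round", "player", "action", "outcome"))
  tab <- shift_table(traj)
  counts <- tab |>
    dplyr::count(.data$outcome, .data$shift) |>
    tidyr::pivot_wider(names_from = "shift", values_from = "n", values_fill = 0L)
  for (col in c("stay", "ccw", "cw")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  res <- tibble::tibble(outcome = c("W", "T", "L")) |>
    dplyr::left_join(counts, by = "outcome") |>
    dplyr::mutate(dplyr::across(c("stay", "ccw", "cw"), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(
      n = .data$stay + .data$ccw + .data$cw,
      p_minus = ifelse(.data$n > 0, .data$cw / .data$n, NA_real_),
      p_stay = ifelse(.data$n > 0, .data$stay / .data$n, NA_real_),
      p_plus = ifelse(.data$n > 0, .data$ccw / .data$n, NA_real_)
    ) |>
    dplyr::mutate(
      se_minus = sqrt(.data$p_minus * (1 - .data$p_minus) / .data$n),
      se_stay = sqrt(.data$p_stay * (1 - .data$p_stay) / .data$n),
      se_plus = sqrt(.data$p_plus * (1 - .data$p_plus) / .data$n)
    ) |>
    dplyr::select(
      "outcome", "n", "p_minus", "p_stay", "p_plus",
      "se_minus", "se_stay", "se_plus"
    )
  res
}

# cr_strategy from an estimate tibble (errors if any outcome unobserved)
cr_estimate_to_strategy <- function(est) {
  if (any(est$n == 0)) {
    stop("cannot form a CR strategy: some outcomes have no observed events",
         call. = FALSE)
  }
  rownames(est) <- NULL
  e <- as.data.frame(est)
  rownames(e) <- e$outcome
  cr_strategy(
    e["W", "p_minus"], e["W", "p_plus"],
    e["T", "p_minus"], e["T", "p_plus"],
    e["L", "p_minus"], e["L", "p_plus"]
  )
}

#' Summarise per-session cycling frequencies by payoff parameter
#'
#' Groups session-level cycling frequencies by payoff parameter and
#' reports, per group, the number of sessions `n_s`, the mean `mu`, the
#' sample standard deviation `sigma` (n - 1 denominator), and the standard
#' error of the mean `delta = sigma / sqrt(n_s)`. Groups with a single
#' session have `NA` `sigma`/`delta`.
#'
#' @param freqs Data frame with columns `a` (payoff parameter, the
#'   grouping variable) and `f` (cycling frequency per session).
#' @return A tibble with columns `a`, `n_s`, `mu`, `sigma`, `delta`.
#' @examples
#' summarize_populations(session_frequencies())
#' @export
summarize_populations <- function(freqs) {
  if (!is.data.frame(freqs) || !all(c("a", "f") %in% names(freqs))) {
    stop("freqs must have columns a and f", call. = FALSE)
  }
  freqs |>
    dplyr::group_by(.data$a) |>
    dplyr::summarise(
      n_s = dplyr::n(),
      mu = mean(.data$f),
      sigma = stats::sd(.data$f),
      delta = .data$sigma / sqrt(.data$n_s),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$a)
}

#' Wilcoxon signed-rank test for positive cycling frequencies
#'
#' Tests whether session cycling frequencies are centred above zero, the
#' population-level signature of persistent counter-clockwise cycling.
#' Zeros are dropped, absolute values are ranked with average ranks for
#' ties, and for `n <= 25` non-zero values the one-sided p-value is exact:
#' the observed positive-rank sum is compared against the full
#' randomisation distribution over all `2^n` sign assignments (computed by
#' dynamic programming, so ties are handled exactly). Larger samples fall
#' back on the normal approximation with tie correction. The two-sided
#' p-value (twice the smaller tail, capped at 1) is reported alongside.
#'
#' @param f Numeric vector of session cycling frequencies (`n >= 5`
#'   non-zero values required).
#' @return A one-row tibble: `n` (non-zero values), `statistic` (positive
#'   rank sum `V`), `p_value` (one-sided, greater), `p_two_sided`,
#'   `method`.
#' @examples
#' test_positive_frequency(c(0.04, 0.02, 0.01, 0.03, -0.01, 0.05))
#' @export
test_positive_frequency <- function(f) {
  if (!is.numeric(f)) stop("f must be numeric", call. = FALSE)
  x <- f[f != 0]
  if (length(x) < 5) {
    stop("need at least 5 non-zero values (after dropping zeros)", call. = FALSE)
  }
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  n <- length(x)
  if (n <= 25) {
    # exact randomisation null over sign assignments, average ranks kept:
    # DP over doubled ranks (integers even with .5 average ranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- numeric(total + 1)
    dp[1] <- 1
    for (w in r2) {
      dp[(w + 1):(total + 1)] <- dp[(w + 1):(total + 1)] + dp[1:(total + 1 - w)]
    }
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(dp[(v2 + 1):(total + 1)])
    p_le <- sum(dp[1:(v2 + 1)])
    method <- "exact signed-rank (randomisation over signs, average ranks)"
  } else {
    mu <- sum(r) / 2
    # variance of the rank sum with average ranks: sum(r^2) / 4
    sig <- sqrt(sum(r^2) / 4)
    p_ge <- stats::pnorm(v - 0.5, mu, sig, lower.tail = FALSE)
    p_le <- stats::pnorm(v + 0.5, mu, sig)
    method <- "normal approximation"
  }
  tibble::tibble(
    n = n,
    statistic = v,
    p_value = p_ge,
    p_two_sided = min(1, 2 * min(p_ge, p_le)),
    method = method
  )
}

#' Spearman rank correlation with tie handling
#'
#' Spearman's rank correlation between two vectors (average ranks for
#' ties), with the two-sided p-value from the asymptotic t approximation —
#' used to ask whether mean cycling frequencies vary systematically with
#' the payoff parameter.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A one-row tibble: `n`, `rho`, `p_value`, `method`.
#' @examples
#' rank_correlation(1:5, c(2, 1, 4, 3, 5))
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    n = length(x),
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    method = "Spearman rank correlation (average ranks, t approximation)"
  )
}
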