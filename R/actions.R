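#' Rock-Paper-Scissors actions
#'
#' The three actions are coded `"R"`, `"P"`, `"S"`. The cyclic
#' counter-clockwise order is R -> P -> S -> R (each action's successor is
#' the action that beats it); the clockwise order is R -> S -> P -> R.
#' Dominance is non-transitive: R beats S, P beats R, S beats P.
#'
#' Internally actions are coded 0 = R, 1 = P, 2 = S so that the successor is
#' `(q + 1) mod 3`, the predecessor `(q + 2) mod 3`, and `q` beats `q'` iff
#' `(q - q') mod 3 == 1`.
#'
#' @param action Character vector of actions (`"R"`, `"P"`, `"S"`).
#' @return `action_successor()` and `action_predecessor()` return the
#'   cyclically shifted actions; `action_beats()` returns a logical vector.
#' @examples
#' action_successor(c("R", "P", "S"))
#' action_beats("R", "S")
#' @name actions
NULL

ACTIONS <- c("R", "P", "S")

# character -> 0/1/2 code; NA for anything else
action_code <- function(action) {
  code <- match(action, ACTIONS) - 1L
  code
}

action_decode <- function(code) {
  ACTIONS[code + 1L]
}

assert_actions <- function(action, what = "action") {
  bad <- !(action %in% ACTIONS)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s value(s): %s (must be one of R, P, S)",
      what, paste(unique(action[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(action)
}

#' @rdname actions
#' @export
action_successor <- function(action) {
  assert_actions(action)
  action_decode((action_code(action) + 1L) %% 3L)
}

#' @rdname actions
#' @export
action_predecessor <- function(action) {
  assert_actions(action)
  action_decode((action_code(action) + 2L) %% 3L)
}

#' @rdname actions
#' @param opponent Character vector of opposing actions, recycled against
#'   `action`.
#' @export
action_beats <- function(action, opponent) {
  assert_actions(action)
  assert_actions(opponent, "opponent")
  (action_code(action) - action_code(opponent)) %% 3L == 1L
}

# Outcome of `action` against `opponent`, coded "W"/"T"/"L", vectorised.
outcome_of <- function(action, opponent) {
  d <- (action_code(action) - action_code(opponent)) %% 3L
  c("T", "W", "L")[d + 1L]
}

# Payoff under the standard scheme: win pays a, tie pays 1, loss pays 0.
payoff_of <- function(outcome, a) {
  unname(c(W = a, T = 1, L = 0)[outcome])
}
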