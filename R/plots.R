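# 2D embedding of the social-state plane: equilateral-triangle coordinates
# with the R corner left, P corner right, S corner top. Counter-clockwise
# rotation (R-rich -> P-rich -> S-rich) is counter-clockwise on the page.
state_plane_coords <- function(states, N) {
  tibble::tibble(
    x = states[, "n_P"] + states[, "n_S"] / 2,
    y = sqrt(3) / 2 * states[, "n_S"]
  )
}

#' Plot the stationary distribution of a fitted CR model
#'
#' Draws the social-state plane (triangular lattice) with point area and
#' colour proportional to the stationary probability of each state; the
#' centroid is marked with a cross.
#'
#' @param object A [cr_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_model <- function(object, ...) {
  st <- as.matrix(object$space$states[, c("n_R", "n_P", "n_S")])
  df <- state_plane_coords(st, object$N) |>
    dplyr::mutate(prob = object$stationary)
  c0 <- state_plane_coords(matrix(rep(object$N / 3, 3), 1,
                                  dimnames = list(NULL, c("n_R", "n_P", "n_S"))),
                           object$N)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$prob, colour = .data$prob)) +
    ggplot2::annotate("point", x = c0$x, y = c0$y, shape = 4, size = 3) +
    ggplot2::scale_colour_viridis_c(name = "stationary\nprobability") +
    ggplot2::scale_size_area(guide = "none", max_size = 8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Stationary social-state distribution (N = %d)", object$N),
      subtitle = sprintf("f_cr = %+.3f cycles/round, tau_cr = %.3f",
                         object$f_cr, object$tau_cr),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the payoff-coefficient distribution of a sampling report
#'
#' Histogram (as density) of the payoff coefficient
#' `(g_cr - g0) / (a - 2)` across uniformly sampled CR strategies, with
#' the Nash benchmark at zero marked.
#'
#' @param object A [payoff_coefficient_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sampling_report <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(
    xmin = .data$bin_left, xmax = .data$bin_right,
    ymin = 0, ymax = .data$density
  )) +
    ggplot2::geom_rect(fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_coeff, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("Payoff landscape of %d sampled CR strategies (N = %d)",
                      object$n, object$N),
      x = "(g_cr - g0) / (a - 2)", y = "density"
    ) +
    ggplot2::theme_minimal()
}

#' Plot accumulated net cycles of one or more sessions
#'
#' Line plot of the accumulated cycle count `C_{1,t}` against the round
#' `t` — the visual signature of persistent collective cycling is a
#' drifting (rather than flat) curve.
#'
#' @param trajs A trajectory tibble or a list of them (e.g. from
#'   [batch_sessions()]).
#' @return A ggplot object.
#' @export
plot_net_cycles <- function(trajs) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  df <- purrr::map_dfr(trajs, function(traj) {
    st <- social_states_of(traj)
    N <- st$n_R[1] + st$n_P[1] + st$n_S[1]
    space <- enumerate_states(N)
    ang <- trajectory_angles(st, space)
    tibble::tibble(
      session_id = traj$session_id[1],
      round = c(1L, seq_along(ang) + 1L),
      C = c(0, cumsum(ang) / (2 * pi))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$round, y = .data$C, group = .data$session_id
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "round t", y = expression(C[paste("1,", t)]),
      title = "Accumulated net cycles around the centroid"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
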