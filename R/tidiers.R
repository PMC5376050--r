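#' Tidy a fitted conditional-response model
#'
#' `tidy()` returns the nine response probabilities in long form (one row
#' per outcome x shift); `glance()` returns a one-row summary of the
#' steady-state observables.
#'
#' @param x A [cr_model()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' fit <- cr_model(cr_strategy(1/3, 1/3, 1/3, 1/3, 1/3, 1/3), N = 6)
#' glance(fit)
#' @export
tidy.cr_model <- function(x, ...) {
  gm <- unclass(x$gamma)
  tidyr::expand_grid(
    outcome = c("W", "T", "L"),
    shift = c("minus", "stay", "plus")
  ) |>
    dplyr::mutate(
      prob = gm[cbind(.data$outcome, .data$shift)]
    )
}

#' @rdname tidy.cr_model
#' @export
glance.cr_model <- function(x, ...) {
  tibble::tibble(
    N = x$N,
    a = x$a,
    f_cr = x$f_cr,
    tau_cr = x$tau_cr,
    payoff_coeff = x$payoff_coeff,
    g0 = x$g0,
    g_cr = x$g_cr
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
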