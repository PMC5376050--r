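#' Sample conditional-response strategies uniformly from the simplex
#'
#' Draws CR strategies with each outcome's shift triple
#' `(O_minus, O_0, O_plus)` sampled independently and uniformly from the
#' 2-simplex (flat Dirichlet), the reference measure for asking how likely
#' a randomly chosen conditional-response rule is to beat the Nash
#' benchmark. Under this measure each single parameter has marginal
#' density `2 (1 - x)` on `[0, 1]`.
#'
#' @param n Number of strategies (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A tibble with `n` rows and columns `W_minus`, `W_plus`,
#'   `T_minus`, `T_plus`, `L_minus`, `L_plus`.
#' @examples
#' sample_uniform_strategies(3, seed = 1)
#' @export
sample_uniform_strategies <- function(n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_triple <- function() {
    e <- matrix(stats::rexp(3 * n), n, 3)
    e / rowSums(e)
  }
  W <- draw_triple(); T_ <- draw_triple(); L <- draw_triple()
  # columns of each triple: (minus, stay, plus)
  tibble::tibble(
    W_minus = W[, 1], W_plus = W[, 3],
    T_minus = T_[, 1], T_plus = T_[, 3],
    L_minus = L[, 1], L_plus = L[, 3]
  )
}

#' Payoff landscape of the conditional-response strategy simplex
#'
#' Monte-Carlo study of how a homogeneous CR population fares against the
#' Nash mixed-strategy benchmark: `n` strategies are sampled uniformly
#' from the simplex ([sample_uniform_strategies()]) and each is evaluated
#' *exactly* with the finite-population Markov engine, yielding its tie
#' fraction `tau_cr`, cycling frequency `f_cr`, and payoff coefficient
#' `(1/3 - tau_cr) / 2` — the coefficient of `(a - 2)` in `g_cr - g0`,
#' bounded in `[-1/3, 1/6]`. Samples whose chain has no unique stationary
#' distribution (degenerate corners, measure zero under the flat simplex)
#' are excluded and counted.
#'
#' @param n Number of sampled strategies (>= 1000).
#' @param N Even population size.
#' @param seed Optional integer seed.
#' @param bins Number of equal-width histogram bins over `[-1/3, 1/6]`.
#' @return An object of class `sampling_report`: list with `n`, `N`,
#'   `seed`, `n_excluded`, `mean_coeff`, `samples` (tibble of strategies
#'   with `tau_cr`, `f_cr`, `payoff_coeff`) and `histogram` (tibble with
#'   `bin_left`, `bin_right`, `density` integrating to 1).
#' @examples
#' \donttest{
#' rep <- payoff_coefficient_report(2000, N = 6, seed = 42)
#' rep$mean_coeff
#' }
#' @export
payoff_coefficient_report <- function(n, N = 6, seed = NULL, bins = 200) {
  if (n < 1000) stop("n must be >= 1000 for a meaningful landscape", call. = FALSE)
  gam <- sample_uniform_strategies(n, seed = seed)
  struct <- model_structure(N)
  res <- eval_gammas_cpp(
    as.matrix(gam), struct$N, struct$K,
    struct$comp_state, struct$comp_prob, struct$comp_groups,
    struct$states, struct$theta, struct$tie_frac
  )
  samples <- gam |>
    dplyr::mutate(
      tau_cr = res[, 1],
      f_cr = res[, 2],
      payoff_coeff = (1 / 3 - .data$tau_cr) / 2,
      ok = res[, 3] == 1
    )
  kept <- dplyr::filter(samples, .data$ok)
  edges <- seq(-1 / 3, 1 / 6, length.out = bins + 1)
  h <- graphics::hist(kept$payoff_coeff, breaks = edges, plot = FALSE)
  structure(
    list(
      n = n, N = N, seed = seed,
      n_excluded = sum(!samples$ok),
      mean_coeff = mean(kept$payoff_coeff),
      samples = dplyr::select(kept, -"ok"),
      histogram = tibble::tibble(
        bin_left = utils::head(edges, -1),
        bin_right = edges[-1],
        density = h$density
      )
    ),
    class = "sampling_report"
  )
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sampling_report> %d CR strategies sampled uniformly (N = %d, %d excluded)\n",
      "  mean payoff coefficient (g_cr - g0) / (a - 2): %+.4f\n",
      "  fraction below the Nash benchmark: %.3f\n"
    ),
    x$n, x$N, x$n_excluded, x$mean_coeff,
    mean(x$samples$payoff_coeff < 0)
  ))
  invisible(x)
}

#' Best-performing sampled strategies
#'
#' Extracts the top `k` sampled strategies by payoff coefficient. High
#' payoff does not pin down collective behaviour: near-optimal strategies
#' exist with near-zero, strongly negative, and strongly positive cycling
#' frequencies.
#'
#' @param report A [payoff_coefficient_report()].
#' @param k Number of strategies to return; clipped (with a warning) to
#'   the number of retained samples.
#' @return A tibble of the top `k` rows of `report$samples`, sorted by
#'   decreasing `payoff_coeff`.
#' @export
best_strategies <- function(report, k = 10) {
  stopifnot(inherits(report, "sampling_report"))
  n_avail <- nrow(report$samples)
  if (k > n_avail) {
    warning(sprintf("k = %d exceeds the %d retained samples; clipping", k, n_avail))
    k <- n_avail
  }
  report$samples |>
    dplyr::arrange(dplyr::desc(.data$payoff_coeff)) |>
    dplyr::slice_head(n = k)
}

#' Serialise a sampling report to JSON
#'
#' @param report A [payoff_coefficient_report()].
#' @param path File path; `NULL` returns the JSON string.
#' @param top_k How many best strategies to embed.
#' @return JSON string, invisibly when written to a file.
#' @export
write_sampling_report <- function(report, path = NULL, top_k = 10) {
  stopifnot(inherits(report, "sampling_report"))
  obj <- list(
    n = report$n, N = report$N, seed = report$seed,
    n_excluded = report$n_excluded,
    mean_payoff_coeff = report$mean_coeff,
    histogram = report$histogram,
    best = best_strategies(report, min(top_k, nrow(report$samples)))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
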