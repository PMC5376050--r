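test_that("cr_strategy validates its probabilities", {
  g <- cr_strategy(0.1, 0.2, 0.3, 0.4, 0.5, 0.5)
  expect_s3_class(g, "cr_strategy")
  expect_equal(unclass(g)["W", "stay"], 0.7)
  expect_error(cr_strategy(0.6, 0.6, 0, 0, 0, 0), "exceed 1")
  expect_error(cr_strategy(-0.1, 0, 0, 0, 0, 0), "\\[0, 1\\]")
})

test_that("pairing distributions agree exactly with matching enumeration", {
  # degenerate states
  d <- pairing_distribution(c(6, 0, 0))
  expect_equal(nrow(d), 1)
  expect_equal(d$prob, 1)
  expect_equal(d$n_rr, 3)
  d <- pairing_distribution(c(5, 1, 0))
  expect_equal(nrow(d), 1)
  expect_equal(unlist(d[1, c("n_rr", "n_rp")], use.names = FALSE), c(2, 1))

  # exhaustive enumeration oracle: all 15 matchings at N = 6,
  # all 105 at N = 8
  states <- list(c(2, 2, 2), c(3, 2, 1), c(4, 1, 1),
                 c(3, 3, 2), c(4, 2, 2), c(2, 2, 4), c(8, 0, 0))
  for (s in states) {
    d <- pairing_distribution(s)
    expect_equal(sum(d$prob), 1, tolerance = 1e-14)
    oracle <- pairing_distribution_oracle(s)
    keys <- apply(d, 1, composition_key)
    expect_setequal(keys, names(oracle))
    expect_equal(d$prob, as.numeric(oracle[keys]), tolerance = 1e-14)
  }

  expect_error(pairing_distribution(c(2, 2, 1), N = 6), "sum to N")
  expect_error(pairing_distribution(c(2, 2, 1)), "even")
  expect_error(pairing_distribution(c(2, 2, 1), N = 5), "even")
})

test_that("outcome counts follow the dominance relations", {
  oc <- outcome_counts(c(n_rr = 1, n_pp = 1, n_ss = 1,
                         n_rp = 0, n_ps = 0, n_sr = 0))
  expect_equal(oc$winners, c(0, 0, 0))
  expect_equal(oc$tiers, c(2, 2, 2))
  oc <- outcome_counts(c(n_rr = 0, n_pp = 0, n_ss = 0,
                         n_rp = 1, n_ps = 1, n_sr = 1))
  expect_equal(oc$winners, c(1, 1, 1))
  expect_equal(oc$losers, c(1, 1, 1))
  expect_equal(oc$tiers, c(0, 0, 0))
  oc <- outcome_counts(c(n_rr = 0, n_pp = 0, n_ss = 1,
                         n_rp = 2, n_ps = 0, n_sr = 0))
  expect_equal(oc$winners, c(0, 2, 0))
  expect_equal(oc$losers, c(2, 0, 0))
  expect_equal(oc$tiers, c(0, 0, 2))
  # conservation: winners = losers, per-action totals = occupancy
  d <- pairing_distribution(c(3, 2, 1))
  for (r in seq_len(nrow(d))) {
    oc <- outcome_counts(d[r, ])
    expect_equal(sum(oc$winners), sum(oc$losers))
    expect_equal(oc$winners + oc$losers + oc$tiers, c(3, 2, 1))
  }
})

test_that("transition matrix limits, stochasticity and symmetry hold", {
  all_stay <- cr_strategy(0, 0, 0, 0, 0, 0)
  m <- cr_transition_matrix(all_stay, 6)
  expect_equal(m$matrix, diag(28))

  all_ccw <- cr_strategy(0, 1, 0, 1, 0, 1)
  m <- cr_transition_matrix(all_ccw, 6)
  sp <- m$space
  st <- as.matrix(sp$states[, c("n_R", "n_P", "n_S")])
  for (i in 1:28) {
    # every player moves to the successor action: (nR,nP,nS) -> (nS,nR,nP)
    j <- rpscycle:::state_index(sp, st[i, 3], st[i, 1])
    expect_equal(m$matrix[i, j], 1)
    expect_equal(sum(m$matrix[i, ]), 1)
  }

  set.seed(42)
  for (rep in 1:3) {
    g <- as.numeric(as.matrix(sample_uniform_strategies(1)))
    m <- cr_transition_matrix(g, 6)
    expect_equal(rowSums(m$matrix), rep(1, 28), tolerance = 1e-10)
    expect_true(all(m$matrix >= 0))
    # cyclic relabeling: sigma (nR,nP,nS) = (nS,nR,nP)
    sig <- rpscycle:::state_index(m$space, st[, 3], st[, 1])
    expect_equal(m$matrix[sig, sig], m$matrix, tolerance = 1e-12)
    # reference R engine agrees with the compiled path
    mr <- cr_transition_matrix(g, 6, engine = "r")
    expect_equal(mr$matrix, m$matrix, tolerance = 1e-12)
  }
})

test_that("stationary distribution is exact for uniform play and errors on degenerate chains", {
  u <- cr_model(uniform_gamma(), N = 6)
  st <- as.matrix(u$space$states[, c("n_R", "n_P", "n_S")])
  multinom <- apply(st, 1, function(s) {
    factorial(6) / (factorial(s[1]) * factorial(s[2]) * factorial(s[3])) / 3^6
  })
  expect_equal(u$stationary, multinom, tolerance = 1e-12)
  expect_equal(u$f_cr, 0, tolerance = 1e-10)
  expect_equal(u$tau_cr, 1 / 3, tolerance = 1e-12)

  m_stay <- cr_transition_matrix(cr_strategy(0, 0, 0, 0, 0, 0), 6)
  expect_error(steady_state(m_stay), "reducible")
  m_ccw <- cr_transition_matrix(cr_strategy(0, 1, 0, 1, 0, 1), 6)
  expect_error(steady_state(m_ccw), "reducible|periodic")
})

test_that("steady-state observables reproduce the reference strategies", {
  gs <- gamma_examples()
  fits <- lapply(gs, cr_model, N = 6, a = 4)
  f <- vapply(fits, function(x) x$f_cr, numeric(1))
  expect_equal(round(unname(f), 3), c(0.003, -0.190, 0.189))
  coeff <- vapply(fits, function(x) x$payoff_coeff, numeric(1))
  # printed coefficients 0.035 / 0.034 / 0.033; the third is truncated, so
  # agreement is asserted to one unit in the last printed digit
  expect_equal(unname(coeff), c(0.035, 0.034, 0.033), tolerance = 0.001 / 0.034)
  expect_equal(round(coeff[["g1"]], 3), 0.035)
})

test_that("payoff accounting matches the tie-fraction identity", {
  # per-state expected tie fraction at (2,2,2): 9 tie pairs over 15
  # matchings x 3 pairs = 0.2; identity n_q(n_q-1) sum / (N(N-1)) agrees
  d <- pairing_distribution(c(2, 2, 2))
  exp_tie_pairs <- sum(d$prob * (d$n_rr + d$n_pp + d$n_ss))
  expect_equal(exp_tie_pairs / 3, 0.2, tolerance = 1e-14)
  expect_equal((2 * 1 * 3) / (6 * 5), 0.2)

  # the same identity holds across all states against the exact engine
  set.seed(7)
  g <- as.numeric(as.matrix(sample_uniform_strategies(1)))
  fit <- cr_model(g, N = 6)
  st <- as.matrix(fit$space$states[, c("n_R", "n_P", "n_S")])
  tie_by_pairing <- vapply(seq_len(nrow(st)), function(i) {
    d <- pairing_distribution(st[i, ])
    sum(d$prob * (d$n_rr + d$n_pp + d$n_ss)) / 3
  }, numeric(1))
  expect_equal(sum(fit$stationary * tie_by_pairing), fit$tau_cr,
               tolerance = 1e-12)

  # g_cr forms: a = 2 collapses to g0 = 1; linearity in a via the
  # equivalent closed form tau + (1 - tau) a / 2
  expect_equal(expected_payoff(g, 6, a = 2), 1)
  for (a in c(1.1, 4)) {
    expect_equal(
      expected_payoff(g, 6, a = a),
      fit$tau_cr + (1 - fit$tau_cr) * a / 2,
      tolerance = 1e-12
    )
  }
  expect_equal(expected_payoff(uniform_gamma(), 6, a = 4), (1 + 4) / 3,
               tolerance = 1e-12)
})

test_that("f_cr, tau_cr and the stationary law do not depend on the payoff a", {
  g <- gamma_examples()$g3
  m1 <- cr_model(g, 6, a = 1.1)
  m2 <- cr_model(g, 6, a = 9)
  expect_identical(m1$f_cr, m2$f_cr)
  expect_identical(m1$tau_cr, m2$tau_cr)
  expect_identical(m1$stationary, m2$stationary)
})

test_that("predicted shift profiles interpolate between the limits", {
  p <- predicted_shift_profile(uniform_gamma(), 6)
  expect_equal(p$prob, rep(1 / 3, 3), tolerance = 1e-12)
  near_stay <- cr_strategy(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4)
  p <- predicted_shift_profile(near_stay, 6)
  expect_equal(p$prob[p$shift == "stay"], 1, tolerance = 1e-3)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
})

test_that("independent-decision model vanishes under symmetric shifting", {
  prof_uniform <- tibble::tibble(
    action = c("R", "P", "S"), p_stay = 1 / 3, p_ccw = 1 / 3, p_cw = 1 / 3
  )
  expect_equal(independent_model_frequency(prof_uniform, 6), 0,
               tolerance = 1e-10)
  prof_sym <- tibble::tibble(
    action = c("R", "P", "S"), p_stay = 0.5, p_ccw = 0.25, p_cw = 0.25
  )
  expect_equal(independent_model_frequency(prof_sym, 6), 0, tolerance = 1e-10)
  prof_ccw <- tibble::tibble(
    action = c("R", "P", "S"), p_stay = 0.5, p_ccw = 0.4, p_cw = 0.1
  )
  expect_gt(independent_model_frequency(prof_ccw, 6), 0.01)
  expect_error(
    independent_model_frequency(
      tibble::tibble(action = c("R", "P", "S"), p_stay = 0.9,
                     p_ccw = 0.3, p_cw = 0.1), 6),
    "sum to 1"
  )
})

test_that("steady-state action marginals are uniform at 1/3", {
  set.seed(11)
  for (rep in 1:3) {
    g <- as.numeric(as.matrix(sample_uniform_strategies(1)))
    fit <- cr_model(g, N = 6)
    st <- as.matrix(fit$space$states[, c("n_R", "n_P", "n_S")])
    for (col in 1:3) {
      expect_equal(sum(fit$stationary * st[, col]) / 6, 1 / 3,
                   tolerance = 1e-12)
    }
    # stationary law invariant under the cyclic relabeling
    sig <- rpscycle:::state_index(fit$space, st[, 3], st[, 1])
    expect_equal(fit$stationary[sig], fit$stationary, tolerance = 1e-12)
  }
})

test_that("model summaries serialise with the documented keys", {
  fit <- cr_model(gamma_examples()$g1, N = 6, a = 4)
  js <- jsonlite::fromJSON(write_model_summary(fit))
  expect_named(js, c("gamma", "N", "f_cr", "tau_cr", "g_cr_coeff"))
  expect_equal(js$gamma$T_plus, 0.110)
  expect_equal(js$f_cr, fit$f_cr)
  g <- glance(fit)
  expect_equal(g$payoff_coeff, fit$payoff_coeff)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$prob), 3, tolerance = 1e-12)
})
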