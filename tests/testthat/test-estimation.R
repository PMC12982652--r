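test_that("empirical transition models count adjacent ordered pairs", {
  m <- empirical_transition_model(c("R", "R", "R", "R"))
  expect_equal(m$counts["R", "R"], 3L)
  expect_equal(m$P_hat["R", "R"], 1)

  m2 <- empirical_transition_model(c("R", "W", "R", "W"), c("R", "W"))
  expect_equal(m2$counts["R", "W"], 2L)
  expect_equal(m2$counts["W", "R"], 1L)
  expect_equal(unname(m2$P_hat), matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  # occupancy counts transition sources (first T-1 symbols)
  expect_equal(unname(m2$occupancy), c(2 / 3, 1 / 3))

  expect_error(empirical_transition_model(c("R", "Q"), c("R", "W")),
               "outside alphabet")
  expect_error(empirical_transition_model("R"), "at least 2")

  sm <- empirical_transition_model(c("R", "W"), c("R", "W"),
                                   pseudo_count = 1)
  expect_equal(unname(sm$P_hat[1, ]), c(1 / 3, 2 / 3))
})

test_that("plug-in entropy rate matches closed forms", {
  expect_equal(plugin_entropy_rate(rep("R", 50)), 0)
  expect_equal(plugin_entropy_rate(rep(c("R", "W"), 25)), 0)

  set.seed(77)
  coin <- sample(c("H", "T"), 1e5, replace = TRUE)
  expect_lt(abs(plugin_entropy_rate(coin) - 1), 0.01)
})

test_that("macro windows lie fully inside runs of the macro-state", {
  tr <- structure(data.frame(day = 0:99, macro = rep("D", 100),
                             micro = rep(c("R", "W"), 50)),
                  class = c("ddm_trajectory", "data.frame"))
  w <- macro_window_segments(tr, "D", T_len = 30, step = 1)
  expect_length(w, 71)
  expect_true(all(vapply(w, length, 1L) == 30))

  expect_length(macro_window_segments(tr, "A", 30), 0)

  alt <- structure(data.frame(day = 0:19, macro = rep(c("A", "D"), 10),
                              micro = rep("R", 20)),
                   class = c("ddm_trajectory", "data.frame"))
  expect_length(macro_window_segments(alt, "A", 2), 0)

  # disjoint windows advance by T
  w2 <- macro_window_segments(tr, "D", 30, step = 30)
  expect_length(w2, 3)

  # windows never straddle two runs
  mixed <- structure(data.frame(day = 0:59,
                                macro = rep(c("D", "A"), each = 30),
                                micro = rep("R", 60)),
                     class = c("ddm_trajectory", "data.frame"))
  expect_length(macro_window_segments(mixed, "D", 20), 11)
})

test_that("window estimates aggregate into mean and standard error", {
  const <- replicate(5, rep("R", 10), simplify = FALSE)
  est <- macro_centric_entropy_estimate(const, "R")
  expect_equal(est$value, 0)
  expect_equal(est$se, 0)
  expect_equal(est$n_windows, 5L)

  expect_error(macro_centric_entropy_estimate(list(), macro = "A"),
               "insufficient data.*A")
})

test_that("plug-in mean matches an independent Monte-Carlo oracle", {
  # 2-state block with known dynamics, matched T and n
  a <- 0.3; b <- 0.1
  P <- matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE)
  pi <- stationary_2state(a, b)
  T_len <- 25; n_reps <- 400

  # oracle: direct categorical sampling, entropy from raw pair counts
  set.seed(123)
  oracle_vals <- replicate(n_reps, {
    s <- integer(T_len)
    s[1] <- sample(1:2, 1, prob = pi)
    for (t in 2:T_len) s[t] <- sample(1:2, 1, prob = P[s[t - 1], ])
    cnt <- matrix(0, 2, 2)
    for (t in 2:T_len) cnt[s[t - 1], s[t]] <- cnt[s[t - 1], s[t]] + 1
    rs <- rowSums(cnt)
    occ <- rs / sum(rs)
    h <- 0
    for (i in 1:2) if (rs[i] > 0) {
      p <- cnt[i, ] / rs[i]
      h <- h - occ[i] * sum(ifelse(p > 0, p * log2(p), 0))
    }
    h
  })

  sp <- state_space("M", c("u", "v"))
  ch <- two_scale_chain(P, sp)
  w <- simulate_conditional(ch, "M", T_len, n_reps, seed = 456)
  est <- macro_centric_entropy_estimate(w, c("u", "v"))
  se_comb <- sqrt(stats::var(oracle_vals) / n_reps + est$se^2)
  expect_lt(abs(est$value - mean(oracle_vals)), 3 * se_comb)
})

test_that("estimates approach the analytic value as the window grows", {
  ch <- two_regime_chain()
  h_true <- macro_centric_entropy_rate(ch, "H")
  for (seed in 1:5) {
    errs <- vapply(c(15, 30, 90), function(T_len) {
      w <- simulate_conditional(ch, "H", T_len, 150, seed = seed)
      abs(macro_centric_entropy_estimate(w, c("x", "y"))$value - h_true)
    }, 0)
    expect_true(all(diff(errs) < 0))
  }
})

test_that("high-entropy blocks are underestimated at short windows", {
  sp <- state_space(c("A", "B"), c("R", "W", "N", "F"))
  P <- rbind(cbind(0.95 * matrix(0.25, 4, 4), matrix(0.0125, 4, 4)),
             cbind(matrix(0.0125, 4, 4), 0.95 * matrix(0.25, 4, 4)))
  ch <- two_scale_chain(P, sp)
  h_true <- macro_centric_entropy_rate(ch, "A")   # 2 bits: the maximum
  w <- simulate_conditional(ch, "A", 15, 200, seed = 8)
  est <- macro_centric_entropy_estimate(w, c("R", "W", "N", "F"))
  expect_lt(est$value + 3 * est$se, h_true)
})

test_that("plug-in estimator is consistent at long windows", {
  ch <- example_psychosis_chain()
  h_true <- macro_centric_entropy_rate(ch, "D")
  w <- simulate_conditional(ch, "D", 1e5, 1, seed = 99)
  expect_lt(abs(plugin_entropy_rate(w[[1]], c("R", "W", "N", "F")) - h_true),
            0.01)
})

test_that("standard errors shrink as one over the square root of n", {
  ch <- two_regime_chain()
  w <- simulate_conditional(ch, "H", 15, 400, seed = 17)
  est_all <- macro_centric_entropy_estimate(w, c("x", "y"))
  est_sub <- macro_centric_entropy_estimate(w[1:100], c("x", "y"))
  ratio <- est_sub$se / est_all$se
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})

test_that("the estimation grid reports every macro-by-window cell", {
  ch <- two_regime_chain()
  g <- entropy_rate_grid(ch, T_grid = c(10, 20), n_reps = 40, seed = 3)
  expect_equal(nrow(g), 4)
  expect_equal(g$n_windows, rep(40L, 4))
  expect_true(all(g$estimate >= 0))
  g2 <- entropy_rate_grid(ch, T_grid = c(10, 20), n_reps = 40, seed = 3)
  expect_identical(g, g2)
})
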