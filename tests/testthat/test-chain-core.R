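test_that("validation renormalizes rows and records the original sums", {
  sp <- toy_space(2)
  ch <- two_scale_chain(matrix(c(1, 1, 3, 1), 2, byrow = TRUE), sp,
                        warn_tol = Inf)
  expect_equal(unname(ch$P), matrix(c(0.5, 0.5, 0.75, 0.25), 2, byrow = TRUE))
  expect_equal(ch$normalization$original_sum, c(2, 4))

  ident <- two_scale_chain(diag(3), toy_space(3))
  expect_equal(unname(ident$P), diag(3))
  expect_false(any(ident$normalization$flagged))

  expect_warning(two_scale_chain(matrix(c(1, 1, 3, 1), 2, byrow = TRUE), sp),
                 "renormalized")
  expect_error(two_scale_chain(matrix(1, 2, 3), NULL), "square")
  expect_error(two_scale_chain(matrix(c(1, -0.1, 1, 1), 2), toy_space(2)),
               "negative")
  expect_error(two_scale_chain(matrix(c(1, 1, 0, 0), 2, byrow = TRUE),
                               toy_space(2)), "all-zero")
})

test_that("state space flattening is a bijection in macro-major order", {
  sp <- state_space(c("A", "B"), list(c("R", "W", "N"), c("R", "W")))
  expect_equal(sp$n_flat, 5L)
  expect_equal(sp$flat_labels, c("AR", "AW", "AN", "BR", "BW"))
  idx <- mapply(function(m, u) flat_index(sp, m, u),
                sp$macro_of, sub("^[AB]", "", sp$flat_labels))
  expect_equal(unname(idx), 1:5)
  expect_error(flat_index(sp, "A", "F"), "unknown micro")
  expect_error(state_space(c("A", "A"), "R"), "unique")
})

test_that("stationary distribution solves the left fixed point", {
  sym <- fair_coin_chain()
  expect_equal(as.numeric(stationary_distribution(sym)), c(0.5, 0.5))

  for (seed in 1:20) {
    ch <- random_chain(3, seed)
    pi_solve <- stationary_distribution(ch, method = "solve")
    pi_power <- stationary_distribution(ch, method = "power")
    expect_stationary(pi_solve, ch$P)
    expect_lt(max(abs(pi_solve - pi_power)), 1e-9)
  }

  # long-run visit frequencies agree with the analytic solution
  ch <- random_chain(3, 42)
  pi <- as.numeric(stationary_distribution(ch))
  tr <- simulate_trajectory(ch, 2e5, seed = 7)
  for (s in 1:3) {
    hits <- as.integer(tr$micro == letters[s])
    expect_lt(abs(mean(hits) - pi[s]), 3 * batch_se(hits))
  }
})

test_that("reducible chains are rejected with their classes named", {
  P <- diag(2)
  expect_error(stationary_distribution(two_scale_chain(P, toy_space(2))),
               "reducible")
})

test_that("macro marginal sums flattened mass per macro-state", {
  sp <- state_space(c("A", "B", "C", "D", "E"), c("R", "W", "N", "F"))
  unif <- new_pi <- structure(rep(1 / 20, 20), level = "flat",
                              labels = sp$flat_labels,
                              class = "stationary_distribution")
  expect_equal(as.numeric(macro_marginal(unif, sp)), rep(0.2, 5))

  point <- structure(as.numeric(sp$flat_labels == "DR"), level = "flat",
                     labels = sp$flat_labels,
                     class = "stationary_distribution")
  expect_equal(unname(unclass(macro_marginal(point, sp))["D"]), 1)

  macro_pi <- macro_marginal(unif, sp)
  expect_error(macro_marginal(macro_pi, sp), "flat-level")
})

test_that("entropy rate obeys closed forms and bounds", {
  expect_equal(entropy_rate(fair_coin_chain()), 1.0)
  expect_equal(entropy_rate(cycle_chain(5)), 0.0)
  for (seed in 1:10) {
    ch <- random_chain(4, seed)
    h <- entropy_rate(ch)
    expect_gte(h, 0)
    expect_lte(h, log2(4))
  }
})

test_that("conditional micro chain renormalizes the within-macro block", {
  # no cross-macro mass: block passes through unchanged
  ch0 <- two_regime_chain(leak = 0)
  expect_warning(cond <- conditional_micro_chain(
    suppressWarnings(two_scale_chain(ch0$P, ch0$space)), "H"), NA)
  expect_equal(unname(cond$P), matrix(0.5, 2, 2))
  expect_equal(unname(cond$leak), c(0, 0), tolerance = 1e-12)

  # 2-micro block stationary distribution matches the closed form
  ch <- two_regime_chain(leak = 0.02)
  cl <- conditional_micro_chain(ch, "L")
  a <- cl$P[1, 2]; b <- cl$P[2, 1]
  expect_equal(as.numeric(cl$pi), stationary_2state(a, b), tolerance = 1e-12)
  expect_stationary(cl$pi, cl$P)

  expect_error(conditional_micro_chain(ch, "Z"), "unknown macro")
})

test_that("macro-centric entropy rate matches block closed forms", {
  sp <- state_space(c("A", "B"), c("R", "W", "N", "F"))
  cyc <- diag(4)[c(2, 3, 4, 1), ]
  unif <- matrix(0.25, 4, 4)
  P <- rbind(cbind(0.9 * cyc, matrix(0.025, 4, 4)),
             cbind(matrix(0.025, 4, 4), 0.9 * unif))
  ch <- two_scale_chain(P, sp)
  expect_equal(macro_centric_entropy_rate(ch, "A"), 0.0)
  expect_equal(macro_centric_entropy_rate(ch, "B"), 2.0)

  # zero cross-macro mass: equals the standalone block entropy rate
  ch0 <- two_regime_chain(leak = 0)
  low <- two_scale_chain(matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
                         toy_space(2))
  expect_equal(macro_centric_entropy_rate(ch0, "L"), entropy_rate(low))
})

test_that("the block and global-slice stationary conventions both work", {
  ch <- two_regime_chain(leak = 0.05)
  hb <- macro_centric_entropy_rate(ch, "L", pi_source = "block")
  hg <- macro_centric_entropy_rate(ch, "L", pi_source = "global")
  expect_gte(hb, 0); expect_gte(hg, 0)
  # small leak: the two conventions nearly coincide
  expect_lt(abs(hb - hg), 0.05)
})

test_that("mixing time matches the 2-state second-eigenvalue closed form", {
  for (ab in list(c(0.3, 0.2), c(0.05, 0.1), c(0.6, 0.7))) {
    a <- ab[1]; b <- ab[2]
    ch <- two_scale_chain(matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE),
                          toy_space(2))
    pi <- stationary_2state(a, b)
    lambda <- abs(1 - a - b)
    # TV from start i after t steps is lambda^t * (1 - pi_i)
    tv <- function(t) lambda^t * max(pi)
    expected <- 1L
    while (tv(expected) > 0.25) expected <- expected + 1L
    expect_equal(mixing_time(ch, 0.25), expected)
  }

  # rank-one chain mixes in one step
  rank1 <- two_scale_chain(matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE),
                           toy_space(2))
  expect_equal(mixing_time(rank1), 1L)

  # monotone non-increasing in epsilon
  ch <- random_chain(4, 5)
  eps <- c(0.4, 0.25, 0.1, 0.01)
  mts <- vapply(eps, function(e) mixing_time(ch, e), 1L)
  expect_true(all(diff(mts) >= 0))

  expect_error(mixing_time(cycle_chain(3), 0.1, max_t = 50), "cap")
})

test_that("mean recurrence time is the reciprocal stationary mass", {
  sp <- toy_space(4)
  unif <- structure(stats::setNames(rep(0.25, 4), sp$flat_labels),
                    level = "flat", labels = sp$flat_labels,
                    class = "stationary_distribution")
  for (s in sp$flat_labels)
    expect_equal(mean_recurrence_time(unif, s), 4.0)

  # matches the empirical mean return time of a long simulation
  ch <- random_chain(3, 11)
  pi <- stationary_distribution(ch)
  tr <- simulate_trajectory(ch, 2e5, seed = 13)
  visits <- which(tr$micro == "a")
  gaps <- diff(visits)
  expect_lt(abs(mean(gaps) - mean_recurrence_time(pi, "Ma")),
            3 * stats::sd(gaps) / sqrt(length(gaps)))

  zero <- structure(stats::setNames(c(0, 1), c("Ma", "Mb")),
                    level = "flat", labels = c("Ma", "Mb"),
                    class = "stationary_distribution")
  expect_error(mean_recurrence_time(zero, "Ma"), "zero stationary mass")
})
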