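# shared toy chains and independent oracles

toy_space <- function(n = 2L, macro = "M") {
  state_space(macro, letters[seq_len(n)])
}

fair_coin_chain <- function() {
  two_scale_chain(matrix(0.5, 2, 2), toy_space(2))
}

cycle_chain <- function(n = 4L) {
  P <- diag(n)[c(seq_len(n)[-1L], 1L), ]
  two_scale_chain(P, toy_space(n))
}

random_chain <- function(n, seed, space = toy_space(n)) {
  set.seed(seed)
  P <- matrix(stats::rexp(n * n), n, n)
  two_scale_chain(P / rowSums(P), space, warn_tol = Inf)
}

# two-macro chain with known block structure and small leak
two_regime_chain <- function(leak = 0.02) {
  sp <- state_space(c("L", "H"), c("x", "y"))
  low <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)   # ~0.29 bits
  high <- matrix(0.5, 2, 2)                                   # 1 bit
  P <- rbind(cbind((1 - leak) * low, matrix(leak / 2, 2, 2)),
             cbind(matrix(leak / 2, 2, 2), (1 - leak) * high))
  two_scale_chain(P, sp)
}

# stationary distribution of a 2x2 stochastic matrix, closed form
stationary_2state <- function(a, b) c(b / (a + b), a / (a + b))

# batch-means standard error for a dependent sequence of 0/1 indicators
batch_se <- function(x, n_batch = 200L) {
  m <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}

# independent brute-force ApEn: literal double loop over template pairs
apen_bruteforce <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nn <- n - mm + 1L
    cs <- numeric(nn)
    for (i in seq_len(nn)) {
      cnt <- 0L
      for (j in seq_len(nn)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      cs[i] <- cnt / nn
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1L)
}

# independent LZ76 phrase counter built on string matching: a phrase
# grows while it occurs in the prefix ending one short of the phrase end
lz76_bruteforce <- function(s) {
  s <- paste(s, collapse = "")
  n <- nchar(s)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n &&
           grepl(substr(s, i, j), substr(s, 1, j - 1L), fixed = TRUE))
      j <- j + 1L
    count <- count + 1L
    i <- j + 1L
  }
  count
}

expect_stationary <- function(pi, P, tol = 1e-9) {
  expect_lt(sum(abs(as.numeric(pi) %*% P - as.numeric(pi))), tol)
}
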