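#' Ordinal-pattern symbolization of a numeric series
#'
#' Encodes each window of `order` consecutive values by the permutation
#' that sorts it, so the symbol stream reflects the ordered relations
#' between data points rather than their values. Ties are broken by
#' index order (earlier point ranks lower), the standard convention in
#' permutation-entropy practice. The alphabet has factorial(order)
#' possible patterns.
#'
#' @param x numeric vector, length >= `order`.
#' @param order pattern length (>= 2, default 3).
#' @return object of class `symbol_series`: character vector of pattern
#'   symbols such as `"012"` (increasing triple), with attribute
#'   `alphabet` listing all factorial(order) patterns.
#' @examples
#' ordinal_symbolize(c(1, 2, 3, 2, 1), order = 3)
#' @export
ordinal_symbolize <- function(x, order = 3L) {
  stopifnot(order >= 2L)
  x <- as.numeric(x)
  n <- length(x) - order + 1L
  if (n < 1L)
    stop("series of length ", length(x), " too short for order ", order,
         call. = FALSE)
  syms <- vapply(seq_len(n), function(i) {
    w <- x[i:(i + order - 1L)]
    paste(order(w) - 1L, collapse = "")   # ties: order() is index-stable
  }, "")
  perms <- apply(perm_matrix(order), 1L, paste, collapse = "")
  structure(syms, alphabet = sort(perms), class = "symbol_series")
}

# all permutations of 0..(k-1), one per row
perm_matrix <- function(k) {
  if (k == 1L) return(matrix(0L, 1L, 1L))
  sub <- perm_matrix(k - 1L)
  out <- NULL
  for (i in seq_len(nrow(sub)))
    for (pos in 0:(k - 1L)) {
      row <- append(sub[i, ], k - 1L, after = pos)
      out <- rbind(out, row)
    }
  unname(out)
}

#' @export
print.symbol_series <- function(x, ...) {
  cat("Symbol series, length", length(x), "| alphabet size",
      length(attr(x, "alphabet")), "\n")
  utils::head(unclass(x), 20) |> print()
  invisible(x)
}

#' Approximate entropy (ApEn)
#'
#' Classical approximate entropy of a numeric series: the negative
#' average log conditional probability that runs of length `m` that are
#' close (Chebyshev distance <= `r`) remain close at length `m + 1`.
#' Self-matches are included, as in the original definition, so ApEn is
#' finite and zero for perfectly regular series.
#'
#' @param x numeric vector, length > m + 1.
#' @param m embedding dimension (default 2).
#' @param r tolerance, on the scale of `x` (a common choice is
#'   `0.2 * sd(x)`); must be positive.
#' @return nonnegative scalar (natural-log units, per the original
#'   definition).
#' @examples
#' approximate_entropy(rep(1, 50), m = 2, r = 0.1)   # 0: no irregularity
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(r > 0)
  if (n <= m + 1L)
    stop("series too short for embedding dimension ", m, call. = FALSE)
  phi <- function(mm) {
    nn <- n - mm + 1L
    # embed as nn x mm matrix of lagged windows
    E <- sapply(seq_len(mm), function(j) x[j:(j + nn - 1L)])
    if (is.null(dim(E))) E <- matrix(E, ncol = mm)
    C <- vapply(seq_len(nn), function(i) {
      d <- abs(E - matrix(E[i, ], nn, mm, byrow = TRUE))
      dmax <- if (mm == 1L) d else apply(d, 1L, max)
      mean(dmax <= r)
    }, 0)
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' Apply a scalar measure over sliding windows
#'
#' Evaluates `fn` on consecutive windows of `x`, producing a moving
#' profile of any static measure (moving ApEn, moving block entropy,
#' ...). Output length is `floor((n - window) / step) + 1`.
#'
#' @param x a vector (numeric or symbolic).
#' @param window window length.
#' @param step window advance (default 1).
#' @param fn function of one window returning a scalar.
#' @param ... passed to `fn`.
#' @return numeric vector of window values, with attribute
#'   `window_start` (1-based start index of each window).
#' @export
moving_apply <- function(x, window, step = 1L, fn, ...) {
  n <- length(x)
  stopifnot(window >= 1L, step >= 1L)
  if (n < window) stop("series shorter than window", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  vals <- vapply(starts, function(s) fn(x[s:(s + window - 1L)], ...), 0)
  attr(vals, "window_start") <- starts
  vals
}

#' Lempel-Ziv (LZ76) complexity of a symbol sequence
#'
#' Number of phrases in the exhaustive-history parsing of the sequence:
#' scanning left to right, a new phrase is closed whenever the current
#' substring cannot be reproduced from the previous history. Higher
#' counts mean the stream keeps innovating; periodic streams saturate at
#' a small count.
#'
#' @param s a character vector of symbols (or a `symbol_series`).
#' @return integer phrase count.
#' @examples
#' lempel_ziv_complexity(rep("0", 10))   # "0" then "000000000": 2
#' @export
lempel_ziv_complexity <- function(s) {
  s <- as.character(s)
  if (length(s) == 0L) stop("empty sequence", call. = FALSE)
  lz76_count(s)
}

# direct LZ76 phrase counter: a phrase ends when s[i..j] is not a
# substring of s[1..(j-1)]
lz76_count <- function(s) {
  n <- length(s)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    # grow the candidate phrase while it can be copied from the past
    while (j <= n && is_substring(s, i, j)) j <- j + 1L
    count <- count + 1L
    i <- j + 1L
  }
  count
}

# is s[i..j] a contiguous substring of s[1..(j-1)]?
is_substring <- function(s, i, j) {
  len <- j - i + 1L
  last_start <- j - len       # starts 1..(j-len) keep the copy inside s[1..(j-1)]
  if (last_start < 1L) return(FALSE)
  pat <- s[i:j]
  for (k in seq_len(last_start))
    if (identical(s[k:(k + len - 1L)], pat)) return(TRUE)
  FALSE
}

#' Block entropy of a symbol sequence
#'
#' Shannon entropy (bits) of the empirical distribution of overlapping
#' length-`k` blocks. The difference between block entropies at
#' consecutive k estimates the conditional entropy, and hence the
#' entropy rate, of the generating process.
#'
#' @param s character vector of symbols (or `symbol_series`).
#' @param k block length (>= 1), at most the sequence length.
#' @return entropy in bits.
#' @examples
#' block_entropy(rep(c("a", "b"), 50), k = 2)
#' @export
block_entropy <- function(s, k = 1L) {
  s <- as.character(s)
  n <- length(s)
  stopifnot(k >= 1L)
  if (k > n) stop("block length exceeds sequence length", call. = FALSE)
  blocks <- vapply(seq_len(n - k + 1L), function(i)
    paste(s[i:(i + k - 1L)], collapse = "\r"), "")
  p <- table(blocks) / length(blocks)
  -sum(p * log2(p))
}

#' Threshold-based mapping of a numeric profile to a symbol alphabet
#'
#' Utility plumbing from windowed information measures to a small
#' behavioural alphabet: values are cut at the supplied thresholds and
#' labelled with the corresponding symbols. How raw device data should
#' map onto behavioural micro-states is a study-design question; this
#' mapping is illustrative, not canonical.
#'
#' @param values numeric vector (e.g. a [moving_apply()] profile).
#' @param thresholds increasing cut points, length = `length(symbols) - 1`.
#' @param symbols labels for the intervals, low to high.
#' @return `symbol_series` of `length(values)` symbols.
#' @export
threshold_symbolize <- function(values, thresholds,
                                symbols = c("R", "W", "N", "F")) {
  if (length(thresholds) != length(symbols) - 1L)
    stop("need one more symbol than thresholds", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  idx <- findInterval(values, thresholds) + 1L
  structure(symbols[idx], alphabet = symbols, class = "symbol_series")
}
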