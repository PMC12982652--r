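#' Sliding-window entropy-rate series
#'
#' Applies the plug-in entropy-rate estimator to sliding windows of a
#' micro-symbol stream, producing the time series on which regime
#' shifts are detected. When the underlying macro-state is unobserved,
#' this series tracks the macro-centric entropy rate of whichever regime
#' the system currently occupies (up to finite-window bias).
#'
#' @param symbols character vector of micro symbols (or `symbol_series`).
#' @param T_len window length in days.
#' @param step window advance (default 1).
#' @param alphabet symbol alphabet (default: observed symbols).
#' @return object of class `entropy_series`: data frame with columns
#'   `window_start` (0-based day of window start) and `value`
#'   (bits/day); attributes `T` and `step`.
#' @export
sliding_entropy_series <- function(symbols, T_len, step = 1L,
                                   alphabet = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) < T_len)
    stop("series of length ", length(symbols),
         " shorter than window T = ", T_len, call. = FALSE)
  if (is.null(alphabet)) alphabet <- sort(unique(symbols))
  vals <- moving_apply(symbols, T_len, step, plugin_entropy_rate,
                       alphabet = alphabet)
  out <- data.frame(window_start = attr(vals, "window_start") - 1L,
                    value = as.numeric(vals))
  attr(out, "T") <- T_len
  attr(out, "step") <- step
  class(out) <- c("entropy_series", "data.frame")
  out
}

#' Change-point detection on an entropy series
#'
#' Flags statistically significant mean shifts in a sliding-window
#' entropy series, the operational signature of a macro-state regime
#' change. Two detectors are provided, both calibrated by a seeded
#' permutation test (shuffling the series destroys change points while
#' preserving the marginal distribution):
#'
#' * `"cusum"`: the maximum excursion of the cumulative sum of
#'   deviations from the series mean is compared with its permutation
#'   distribution; on a detection the series is split at the argmax and
#'   both halves are searched recursively.
#' * `"binseg"`: binary segmentation on the best variance-reducing mean
#'   split, with the same permutation stop rule.
#'
#' Detection is invariant to adding a constant to the whole series.
#'
#' @param es an [sliding_entropy_series()] result (or numeric vector).
#' @param method `"cusum"` (default) or `"binseg"`.
#' @param alpha permutation significance level (default 0.05).
#' @param n_perm permutation draws (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param min_seg minimum segment length (default 2).
#' @return object of class `change_point_report`: list with
#'   `change_indices` (1-based positions in the series; a change at k
#'   means the mean differs between `1..k` and `k+1..n`), `change_days`
#'   (window-start day coordinates, when available), `segment_means`,
#'   `method`, `alpha`, `n_perm`, `seed`.
#' @export
detect_changepoints <- function(es, method = c("cusum", "binseg"),
                                alpha = 0.05, n_perm = 1000, seed = NULL,
                                min_seg = 2L) {
  method <- match.arg(method)
  x <- if (is.data.frame(es)) es$value else as.numeric(es)
  days <- if (is.data.frame(es)) es$window_start else seq_along(x) - 1L
  if (length(x) < 4L)
    stop("need at least 4 points to test for a change", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cps <- if (stats::sd(x) == 0) integer(0) else
    seg_recurse(x, 1L, length(x), method, alpha, n_perm, min_seg)
  cps <- sort(cps)
  bounds <- c(0L, cps, length(x))
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), 0)
  structure(list(change_indices = cps, change_days = days[cps],
                 segment_means = means, method = method, alpha = alpha,
                 n_perm = n_perm, seed = seed, n = length(x)),
            class = "change_point_report")
}

# recursive search on x[lo..hi]; returns absolute change positions
seg_recurse <- function(x, lo, hi, method, alpha, n_perm, min_seg) {
  seg <- x[lo:hi]
  n <- length(seg)
  if (n < 2L * min_seg || stats::sd(seg) == 0) return(integer(0))
  stat <- switch(method, cusum = cusum_stat, binseg = binseg_stat)
  obs <- stat(seg)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(seg))$max, 0)
  p <- (1 + sum(null >= obs$max)) / (n_perm + 1)
  if (p > alpha) return(integer(0))
  k <- obs$at
  if (k < min_seg || n - k < min_seg) return(integer(0))
  c(seg_recurse(x, lo, lo + k - 1L, method, alpha, n_perm, min_seg),
    lo + k - 1L,
    seg_recurse(x, lo + k, hi, method, alpha, n_perm, min_seg))
}

# max |cumulative sum of mean deviations|, scale-free via series sd
cusum_stat <- function(seg) {
  s <- cumsum(seg - mean(seg))
  s <- s[-length(s)]                     # a split needs both sides non-empty
  k <- which.max(abs(s))
  list(max = abs(s[k]) / (stats::sd(seg) * sqrt(length(seg))), at = k)
}

# best reduction in within-segment sum of squares over all mean splits
binseg_stat <- function(seg) {
  n <- length(seg)
  k <- seq_len(n - 1L)
  cl <- cumsum(seg)[k]
  cr <- sum(seg) - cl
  # between-segment SS gain for a split after position k
  gain <- cl^2 / k + cr^2 / (n - k) - sum(seg)^2 / n
  at <- which.max(gain)
  list(max = gain[at] / stats::var(seg), at = at)
}

#' @export
print.change_point_report <- function(x, ...) {
  cat("Change-point report (", x$method, ", alpha = ", x$alpha, ")\n",
      sep = "")
  if (length(x$change_indices) == 0L) {
    cat("  no significant change points\n")
  } else {
    cat("  changes at series index:",
        paste(x$change_indices, collapse = ", "), "\n")
    cat("  segment means (bits/day):",
        paste(sprintf("%.3f", x$segment_means), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify an entropy level against reference regimes
#'
#' Assigns an entropy-rate value to the macro-state whose analytic
#' macro-centric entropy rate is nearest, the interpretation rule for
#' "trending toward the characteristic entropy range of another
#' macro-state". When the two nearest references are both within
#' `band` of the value the call is ambiguous and `"indeterminate"` is
#' returned; exact ties break deterministically by reference order.
#'
#' @param value entropy rate in bits/day (scalar or vector).
#' @param reference named numeric vector of analytic macro-centric
#'   entropy rates, e.g. from [macro_centric_entropy_rate()].
#' @param band half-width (bits/day) inside which two references are
#'   considered indistinguishable (default 0: always pick nearest).
#' @return character vector of macro labels (or `"indeterminate"`).
#' @export
classify_regime <- function(value, reference, band = 0) {
  if (length(reference) == 0L || is.null(names(reference)))
    stop("reference must be a non-empty named vector", call. = FALSE)
  vapply(value, function(v) {
    d <- abs(reference - v)
    o <- order(d, seq_along(d))         # tie-break by reference order
    if (length(d) > 1L && band > 0 && d[o[1L]] <= band && d[o[2L]] <= band)
      return("indeterminate")
    names(reference)[o[1L]]
  }, "")
}

#' Sustained-deviation alarm on an entropy series
#'
#' Operationalizes "sustained deviation from baseline entropy levels":
#' the alarm fires at the first window that begins a run of `K`
#' consecutive values outside `baseline mean +/- z * baseline sd`.
#'
#' @param es an [sliding_entropy_series()] (or numeric vector).
#' @param baseline_n number of initial windows defining the baseline.
#' @param K consecutive out-of-band windows required (default 3).
#' @param z band half-width in baseline standard deviations (default 2).
#' @return 1-based index of the first alarming window, or `NA` if the
#'   alarm never fires.
#' @export
sustained_deviation_alarm <- function(es, baseline_n, K = 3L, z = 2) {
  x <- if (is.data.frame(es)) es$value else as.numeric(es)
  stopifnot(baseline_n >= 2L, baseline_n < length(x))
  mu <- mean(x[seq_len(baseline_n)])
  sdev <- stats::sd(x[seq_len(baseline_n)])
  out <- abs(x - mu) > z * sdev
  out[seq_len(baseline_n)] <- FALSE
  r <- rle(out)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= K)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(ends[hit[1L]] - r$lengths[hit[1L]] + 1L)
}
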