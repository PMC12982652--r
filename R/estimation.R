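#' Empirical transition model of a symbol series
#'
#' Counts ordered adjacent symbol pairs in a finite window and
#' row-normalizes them into an empirical transition matrix. The
#' occupancy vector is the frequency of transition *sources*, i.e. of
#' the first T-1 symbols, so that occupancy and transition rows describe
#' the same set of observed transitions.
#'
#' @param series character (or factor) vector of symbols, length >= 2.
#' @param alphabet symbol alphabet; defaults to the sorted unique symbols
#'   of `series`. Symbols outside the alphabet are an error.
#' @param pseudo_count added to every cell before normalization
#'   (default 0; a positive value Laplace-smooths rare transitions).
#' @return object of class `empirical_transition_model`: list with
#'   `alphabet`, `counts` (integer matrix), `P_hat` (rows with positive
#'   counts sum to 1; unobserved rows are all zero when
#'   `pseudo_count = 0`), `occupancy`, `n_transitions`.
#' @examples
#' m <- empirical_transition_model(strsplit("RWRW", "")[[1]])
#' m$P_hat
#' @export
empirical_transition_model <- function(series, alphabet = NULL,
                                       pseudo_count = 0) {
  series <- as.character(series)
  if (length(series) < 2L)
    stop("need at least 2 symbols to observe a transition", call. = FALSE)
  if (is.null(alphabet)) alphabet <- sort(unique(series))
  bad <- setdiff(unique(series), alphabet)
  if (length(bad))
    stop("symbol(s) outside alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  k <- length(alphabet)
  from <- factor(series[-length(series)], levels = alphabet)
  to <- factor(series[-1L], levels = alphabet)
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), k, k,
                   dimnames = list(alphabet, alphabet))
  sm <- counts + pseudo_count
  rs <- rowSums(sm)
  P_hat <- sm / ifelse(rs > 0, rs, 1)   # unobserved rows stay zero
  occ <- rowSums(counts) + pseudo_count * k
  occ <- occ / sum(occ)
  structure(list(alphabet = alphabet, counts = counts, P_hat = P_hat,
                 occupancy = occ, n_transitions = length(series) - 1L),
            class = "empirical_transition_model")
}

#' Plug-in entropy-rate estimate
#'
#' Evaluates the Markov entropy-rate formula with empirical occupancy and
#' empirical transition probabilities in place of their population
#' values: H_hat = -sum_i pi_hat_i sum_j P_hat_ij log2 P_hat_ij. Rows
#' never observed as sources contribute nothing; 0 log 0 = 0. The
#' estimator is consistent but biased downward at short window lengths,
#' most strongly for high-entropy processes — short windows make
#' behaviour look more predictable than it is.
#'
#' @param x an [empirical_transition_model()], or a raw symbol series
#'   (then `alphabet` is honoured).
#' @param alphabet used only when `x` is a raw series.
#' @return entropy-rate estimate in bits/day.
#' @examples
#' plugin_entropy_rate(rep(c("R", "W"), 10))   # deterministic: 0 bits
#' @export
plugin_entropy_rate <- function(x, alphabet = NULL) {
  if (!inherits(x, "empirical_transition_model"))
    x <- empirical_transition_model(x, alphabet = alphabet)
  if (x$n_transitions < 1L) stop("no transitions observed", call. = FALSE)
  matrix_entropy_rate(x$P_hat, x$occupancy)
}

#' Windows fully contained in runs of one macro-state
#'
#' Segments a labelled trajectory into sliding windows of length `T_len`
#' that lie entirely inside a maximal run of the given macro-state; the
#' window advances by `step` days within each run, and runs shorter than
#' `T_len` contribute nothing. These are the windows over which the
#' macro-centric entropy rate can be estimated from data.
#'
#' @param traj a `ddm_trajectory` (columns `macro`, `micro`).
#' @param macro macro-state label.
#' @param T_len window length in days (>= 2).
#' @param step window advance in days (default 1, overlapping; use
#'   `step = T_len` for disjoint windows).
#' @return list of character vectors of micro symbols (possibly empty).
#' @export
macro_window_segments <- function(traj, macro, T_len, step = 1L) {
  stopifnot(T_len >= 2, step >= 1)
  if (!all(c("macro", "micro") %in% names(traj)))
    stop("trajectory must carry macro and micro columns", call. = FALSE)
  r <- rle(traj$macro == macro)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values & r$lengths >= T_len)) {
    offs <- seq.int(0L, r$lengths[i] - T_len, by = step)
    out <- c(out, lapply(offs, function(o)
      traj$micro[(starts[i] + o):(starts[i] + o + T_len - 1L)]))
  }
  out
}

#' Macro-centric entropy rate from a set of windows
#'
#' Applies the plug-in estimator to each window and summarizes the
#' resulting empirical distribution of entropy-rate estimates by its
#' mean and standard error (sample standard deviation over sqrt of the
#' number of windows). With overlapping windows the estimates are
#' positively correlated and the standard error is optimistic; pass
#' disjoint windows (`step = T_len` upstream) for a conservative one.
#'
#' @param windows list of symbol series, as from
#'   [macro_window_segments()] or [simulate_conditional()].
#' @param alphabet micro-symbol alphabet shared by the windows.
#' @param macro optional macro label recorded in the result.
#' @return object of class `entropy_estimate`: list with `value` (mean,
#'   bits/day), `se`, `T` (window length), `n_windows`, `macro`,
#'   `estimator = "plugin"`.
#' @export
macro_centric_entropy_estimate <- function(windows, alphabet = NULL,
                                           macro = NULL) {
  if (length(windows) == 0L)
    stop("insufficient data: no window of the requested length",
         if (!is.null(macro)) paste0(" for macro-state ", macro) else "",
         call. = FALSE)
  if (is.null(alphabet)) alphabet <- sort(unique(unlist(windows)))
  vals <- vapply(windows, plugin_entropy_rate, 0, alphabet = alphabet)
  se <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
  structure(list(value = mean(vals), se = se,
                 T = length(windows[[1L]]), n_windows = length(vals),
                 macro = macro, estimator = "plugin", samples = vals),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Plug-in entropy rate%s: %.3f +/- %.3f bits/day (T = %d, %d windows)\n",
              if (!is.null(x$macro)) paste0(" [", x$macro, "]") else "",
              x$value, x$se, x$T, x$n_windows))
  invisible(x)
}

#' Finite-window estimation grid across macro-states
#'
#' For each macro-state and each window length, simulates conditional
#' micro-symbol windows from the chain and summarizes the plug-in
#' entropy-rate estimates next to the analytic macro-centric value. The
#' grid shows the finite-window downward bias shrinking as the window
#' grows.
#'
#' @param chain a [two_scale_chain()].
#' @param T_grid window lengths in days (default `c(15, 30, 90)`).
#' @param n_reps independent windows per cell (default 300).
#' @param seed integer seed.
#' @param macros macro-states to include (default all).
#' @return data frame: `macro`, `T`, `theoretical`, `estimate`, `se`,
#'   `n_windows`, `seed`.
#' @examples
#' \donttest{
#' entropy_rate_grid(example_psychosis_chain(), T_grid = 15, n_reps = 50,
#'                   seed = 1)
#' }
#' @export
entropy_rate_grid <- function(chain, T_grid = c(15, 30, 90), n_reps = 300,
                              seed = NULL, macros = NULL) {
  stopifnot(inherits(chain, "two_scale_chain"))
  if (is.null(macros)) macros <- chain$space$macro_labels
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (m in macros) {
    h_true <- macro_centric_entropy_rate(chain, m)
    alphabet <- chain$space$micro_labels[[m]]
    for (T_len in T_grid) {
      w <- simulate_conditional(chain, m, T_len, n_reps)
      est <- macro_centric_entropy_estimate(w, alphabet, macro = m)
      rows[[length(rows) + 1L]] <-
        data.frame(macro = m, T = T_len, theoretical = h_true,
                   estimate = est$value, se = est$se,
                   n_windows = est$n_windows,
                   seed = if (is.null(seed)) NA_integer_ else seed)
    }
  }
  do.call(rbind, rows)
}
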