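#' Simulate a daily trajectory from a two-time-scale chain
#'
#' Draws a day-by-day (macro, micro) trajectory from the chain: the state
#' on day t+1 is drawn from the transition row of the state on day t.
#' The same seed always yields the same trajectory.
#'
#' @param chain a [two_scale_chain()].
#' @param n_days number of days (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param init starting state: `"stationary"` (default) draws day 0 from
#'   the stationary distribution, otherwise a flattened state label.
#' @return a `data.frame` of class `ddm_trajectory` with columns `day`
#'   (0-based), `macro`, `micro`; attributes `seed` and `n_states`.
#' @examples
#' ch <- example_psychosis_chain()
#' head(simulate_trajectory(ch, 10, seed = 1))
#' @export
simulate_trajectory <- function(chain, n_days, seed = NULL,
                                init = "stationary") {
  stopifnot(inherits(chain, "two_scale_chain"), n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(chain$P)
  if (identical(init, "stationary")) {
    pi <- as.numeric(stationary_distribution(chain))
    s0 <- sample.int(n, 1L, prob = pi)
  } else {
    s0 <- match(init, colnames(chain$P))
    if (is.na(s0)) stop("unknown init state: ", init, call. = FALSE)
  }
  states <- walk_states(chain$P, s0, n_days)
  labs <- colnames(chain$P)[states]
  out <- data.frame(day = seq_len(n_days) - 1L,
                    macro = chain$space$macro_of[states],
                    micro = substring(labs, nchar(chain$space$macro_of[states]) + 1L))
  attr(out, "seed") <- seed
  attr(out, "n_states") <- n
  class(out) <- c("ddm_trajectory", "data.frame")
  out
}

# one path of length n from start state s0; cumulative-row inversion so
# the per-day cost is a findInterval on a precomputed table
walk_states <- function(P, s0, n) {
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(n - 1L)
  states <- integer(n)
  states[1L] <- s0
  s <- s0
  for (t in seq_len(n - 1L)) {
    s <- findInterval(u[t], cum[s, ], left.open = TRUE) + 1L
    states[t + 1L] <- s
  }
  states
}

#' Simulate micro-symbol windows conditional on a macro-state
#'
#' Generates independent fixed-length micro-symbol series from the
#' conditional micro-state chain of one macro-state (the renormalized
#' within-macro block), each initialized from that block's stationary
#' distribution. This is the process observed during windows fully
#' contained in an occupancy period of the macro-state, and the sampling
#' model behind finite-window entropy estimation.
#'
#' @param chain a [two_scale_chain()].
#' @param macro macro-state label.
#' @param T_len window length in days (>= 2).
#' @param n_reps number of independent windows (0 returns an empty list).
#' @param seed integer seed.
#' @return list of `n_reps` character vectors of micro symbols, length
#'   `T_len` each.
#' @export
simulate_conditional <- function(chain, macro, T_len, n_reps, seed = NULL) {
  stopifnot(T_len >= 2, n_reps >= 0)
  cond <- conditional_micro_chain(chain, macro)
  if (!is.null(seed)) set.seed(seed)
  if (n_reps == 0L) return(list())
  micro <- colnames(cond$P)
  pib <- as.numeric(cond$pi)
  lapply(seq_len(n_reps), function(r) {
    s0 <- sample.int(length(micro), 1L, prob = pib)
    micro[walk_states(cond$P, s0, T_len)]
  })
}

#' Write / read a trajectory as CSV
#'
#' Columns `day`, `macro`, `micro`; an ISO `date` column is added when a
#' `start_date` is given.
#'
#' @param traj a `ddm_trajectory` (or any data frame with those columns).
#' @param path file path.
#' @param start_date optional `Date` mapped to day 0.
#' @export
write_trajectory <- function(traj, path, start_date = NULL) {
  df <- as.data.frame(traj)
  if (!is.null(start_date))
    df$date <- as.Date(start_date) + df$day
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "macro", "micro")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$macro <- as.character(df$macro)
  df$micro <- as.character(df$micro)
  class(df) <- c("ddm_trajectory", "data.frame")
  df
}
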