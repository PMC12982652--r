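#' Full analytic marker report for a chain
#'
#' Computes the three orders of markers in one pass: the macro-state
#' stationary occupancy (first order), the global entropy rate (second
#' order), and the per-macro macro-centric entropy rates together with
#' mixing and mean recurrence times (third order).
#'
#' @param chain a [two_scale_chain()], or a path to a matrix file
#'   readable by [read_chain()].
#' @param epsilon total-variation threshold for the mixing time.
#' @return list of class `ddm_metrics` with elements
#'   `macro_stationary`, `entropy_rate`, `macro_centric`,
#'   `mixing_time_days`, `recurrence_time_days`, `normalization`,
#'   `package_version`.
#' @examples
#' run_metrics(example_psychosis_chain())
#' @export
run_metrics <- function(chain, epsilon = 0.25) {
  if (is.character(chain)) chain <- read_chain(chain)
  stopifnot(inherits(chain, "two_scale_chain"))
  pi <- stationary_distribution(chain)
  pim <- macro_marginal(pi, chain$space)
  hm <- vapply(chain$space$macro_labels,
               function(m) macro_centric_entropy_rate(chain, m), 0)
  structure(list(
    macro_stationary = stats::setNames(as.numeric(pim), names(pim)),
    entropy_rate = entropy_rate(chain, pi),
    macro_centric = hm,
    mixing_time_days = mixing_time(chain, epsilon),
    recurrence_time_days = vapply(chain$space$macro_labels,
                                  function(m) mean_recurrence_time(pim, m), 0),
    normalization = chain$normalization,
    package_version = as.character(utils::packageVersion("ddmarker"))),
    class = "ddm_metrics")
}

#' @export
print.ddm_metrics <- function(x, ...) {
  cat("Markers of the two-time-scale chain\n")
  cat("  macro stationary occupancy:\n")
  print(round(x$macro_stationary, 4))
  cat(sprintf("  global entropy rate: %.3f bits/day\n", x$entropy_rate))
  cat("  macro-centric entropy rates (bits/day):\n")
  print(round(x$macro_centric, 3))
  cat(sprintf("  mixing time: %d days | recurrence times (days):\n",
              x$mixing_time_days))
  print(round(x$recurrence_time_days, 1))
  if (any(x$normalization$flagged))
    cat("  note:", sum(x$normalization$flagged),
        "input rows were renormalized (see $normalization)\n")
  invisible(x)
}

#' Write any marker report as JSON
#'
#' @param x a report (`ddm_metrics`, `change_point_report`, a data frame,
#'   or any list of numeric results).
#' @param path output file.
#' @param seed optional seed to embed for provenance.
#' @export
write_report_json <- function(x, path, seed = NULL) {
  obj <- if (is.data.frame(x)) list(table = x) else unclass(x)
  if (!is.null(seed)) obj$seed <- seed
  if (is.null(obj$package_version))
    obj$package_version <- as.character(utils::packageVersion("ddmarker"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Finite-window estimation report (analytic vs empirical grid)
#'
#' Wrapper around [entropy_rate_grid()] accepting either a chain (the
#' windows are then simulated from each conditional block) or a labelled
#' trajectory (the windows are then cut from the observed macro runs).
#'
#' @param input a `two_scale_chain`, a matrix file path, a
#'   `ddm_trajectory`, or a trajectory CSV path. Trajectory input
#'   requires `chain` for the theoretical column.
#' @param T_grid window lengths (days), default `c(15, 30, 90)`.
#' @param n_reps simulated windows per cell (chain input only).
#' @param step window advance for trajectory input (default 1).
#' @param seed integer seed.
#' @param chain reference chain when `input` is a trajectory.
#' @return data frame: macro, T, theoretical, estimate, se, n_windows,
#'   seed; cells with too few windows carry `NA` estimates and
#'   `n_windows = 0` rather than failing the run.
#' @export
run_estimate <- function(input, T_grid = c(15, 30, 90), n_reps = 300,
                         step = 1L, seed = NULL, chain = NULL) {
  if (is.character(input)) {
    input <- if (grepl("\\.csv$", input) && is_trajectory_file(input))
      read_trajectory(input) else read_chain(input)
  }
  if (inherits(input, "two_scale_chain"))
    return(entropy_rate_grid(input, T_grid, n_reps, seed))
  if (!inherits(input, "ddm_trajectory"))
    stop("input must be a chain, trajectory, or a path to one",
         call. = FALSE)
  if (is.null(chain))
    stop("trajectory input needs `chain` for the theoretical column",
         call. = FALSE)
  rows <- list()
  for (m in chain$space$macro_labels) {
    h_true <- macro_centric_entropy_rate(chain, m)
    alphabet <- chain$space$micro_labels[[m]]
    for (T_len in T_grid) {
      w <- macro_window_segments(input, m, T_len, step)
      rows[[length(rows) + 1L]] <- if (length(w) == 0L)
        data.frame(macro = m, T = T_len, theoretical = h_true,
                   estimate = NA_real_, se = NA_real_, n_windows = 0L,
                   seed = if (is.null(seed)) NA_integer_ else seed)
      else {
        est <- macro_centric_entropy_estimate(w, alphabet, macro = m)
        data.frame(macro = m, T = T_len, theoretical = h_true,
                   estimate = est$value, se = est$se,
                   n_windows = est$n_windows,
                   seed = if (is.null(seed)) NA_integer_ else seed)
      }
    }
  }
  do.call(rbind, rows)
}

is_trajectory_file <- function(path) {
  hdr <- tolower(readLines(path, n = 1L))
  all(c("day", "macro", "micro") %in%
        trimws(strsplit(hdr, "[,\t]")[[1L]]))
}

#' Regime-shift detection report for a symbol stream
#'
#' Computes the sliding-window entropy series of a micro-symbol stream,
#' runs change-point detection, and (when a reference chain is given)
#' classifies each segment's mean entropy against the chain's analytic
#' macro-centric entropy rates.
#'
#' @param symbols character vector of micro symbols, a `ddm_trajectory`
#'   (its `micro` column is used), or a CSV path (trajectory file or
#'   single `symbol` column).
#' @param T_len sliding window length in days.
#' @param step window advance.
#' @param method change-point method, `"cusum"` or `"binseg"`.
#' @param alpha permutation significance level.
#' @param seed integer seed for permutation calibration.
#' @param chain optional reference chain for regime classification.
#' @return list of class `ddm_detection`: `entropy_series`,
#'   `changepoints` (a `change_point_report`), `segment_regime`
#'   (character, or `NULL` without a reference chain), `T`, `step`.
#' @export
run_detect <- function(symbols, T_len = 15L, step = 1L,
                       method = c("cusum", "binseg"), alpha = 0.05,
                       seed = NULL, chain = NULL) {
  method <- match.arg(method)
  if (is.character(symbols) && length(symbols) == 1L &&
      file.exists(symbols)) {
    symbols <- if (is_trajectory_file(symbols))
      read_trajectory(symbols)$micro
    else utils::read.csv(symbols)[[1L]]
  }
  if (inherits(symbols, "ddm_trajectory")) symbols <- symbols$micro
  es <- sliding_entropy_series(as.character(symbols), T_len, step)
  cp <- detect_changepoints(es, method = method, alpha = alpha, seed = seed)
  regime <- NULL
  if (!is.null(chain)) {
    ref <- vapply(chain$space$macro_labels,
                  function(m) macro_centric_entropy_rate(chain, m), 0)
    regime <- classify_regime(cp$segment_means, ref)
  }
  structure(list(entropy_series = es, changepoints = cp,
                 segment_regime = regime, T = T_len, step = step),
            class = "ddm_detection")
}

#' @export
print.ddm_detection <- function(x, ...) {
  cat("Sliding-window entropy (T =", x$T, "days,", nrow(x$entropy_series),
      "windows)\n")
  print(x$changepoints)
  if (!is.null(x$segment_regime))
    cat("  segment regimes:", paste(x$segment_regime, collapse = " -> "),
        "\n")
  invisible(x)
}

#' Plot an entropy series with detected change points
#'
#' @param x a `ddm_detection` (or `entropy_series`).
#' @param ... passed to [plot()].
#' @export
plot.ddm_detection <- function(x, ...) {
  es <- x$entropy_series
  plot(es$window_start, es$value, type = "l",
       xlab = "window start (day)", ylab = "entropy rate (bits/day)", ...)
  if (length(x$changepoints$change_days))
    graphics::abline(v = x$changepoints$change_days, lty = 2, col = 2)
  invisible(x)
}
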