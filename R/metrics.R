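#' Stationary distribution of a chain
#'
#' Solves the left fixed point pi = pi P of the daily transition matrix,
#' i.e. the long-run occupancy of each flattened (macro, micro) state.
#' Irreducibility is checked first on the directed graph of positive
#' transitions; a chain with more than one closed communicating class has
#' no unique stationary distribution and is rejected. The default solver
#' is a dense linear solve of the balance equations with the
#' normalization constraint appended; power iteration is available as an
#' independent route and as a fallback for near-singular systems.
#'
#' @param chain a [two_scale_chain()].
#' @param method `"solve"` (linear system, default) or `"power"`
#'   (iterate pi <- pi P to a 1e-13 fixed point).
#' @return object of class `stationary_distribution`: numeric vector of
#'   probabilities named by flattened state, with attributes `level`
#'   (`"flat"`) and `labels`.
#' @examples
#' sp <- state_space("M", c("a", "b"))
#' ch <- two_scale_chain(matrix(0.5, 2, 2), sp)
#' stationary_distribution(ch)
#' @export
stationary_distribution <- function(chain, method = c("solve", "power")) {
  stopifnot(inherits(chain, "two_scale_chain"))
  method <- match.arg(method)
  check_irreducible(chain$P)
  pi <- switch(method,
               solve = stationary_solve(chain$P),
               power = stationary_power(chain$P))
  new_stationary(pi, level = "flat", labels = colnames(chain$P))
}

new_stationary <- function(values, level, labels) {
  values <- as.numeric(values)
  names(values) <- labels
  structure(values, level = level, labels = labels,
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, digits = 4, ...) {
  cat("Stationary distribution (", attr(x, "level"), " level)\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

stationary_solve <- function(P) {
  n <- nrow(P)
  # pi (P - I) = 0 with sum(pi) = 1: overdetermined, solved by qr
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(pi) || any(pi < -1e-8) || max(abs(pi %*% P - pi)) > 1e-9)
    pi <- stationary_power(P)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

stationary_power <- function(P, tol = 1e-13, max_iter = 1e6) {
  n <- nrow(P)
  pi <- rep(1 / n, n)
  # strictly positive lazy mixture has the same fixed point and always
  # converges, even for periodic chains
  Q <- 0.5 * P + 0.5 * diag(n)
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi %*% Q)
    if (sum(abs(nxt - pi)) < tol) return(nxt / sum(nxt))
    pi <- nxt
  }
  pi / sum(pi)
}

check_irreducible <- function(P, tol = 0) {
  g <- igraph::graph_from_adjacency_matrix(P > tol, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    sizes <- table(comp$membership)
    stop("chain is reducible: ", comp$no,
         " communicating classes (sizes ",
         paste(sizes, collapse = ", "), "); states of class 1: ",
         paste(colnames(P)[comp$membership == 1][seq_len(min(5, sizes[1]))],
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Macro-state marginal of a flattened stationary distribution
#'
#' First-order marker: the long-run fraction of days spent in each
#' clinical macro-state, obtained by summing the flattened stationary
#' probabilities over each macro-state's micro-states.
#'
#' @param pi a flat-level [stationary_distribution()].
#' @param space the [state_space()] the distribution is aligned to.
#' @return a macro-level `stationary_distribution`.
#' @export
macro_marginal <- function(pi, space) {
  stopifnot(inherits(pi, "stationary_distribution"),
            inherits(space, "ddm_state_space"))
  if (!identical(attr(pi, "level"), "flat"))
    stop("macro_marginal() needs a flat-level distribution, got level '",
         attr(pi, "level"), "'", call. = FALSE)
  if (length(pi) != space$n_flat)
    stop("distribution length does not match state space", call. = FALSE)
  vals <- vapply(space$macro_labels,
                 function(m) sum(pi[space$macro_of == m]), 0)
  new_stationary(vals, level = "macro", labels = space$macro_labels)
}

#' Entropy rate of a stationary Markov chain
#'
#' Second-order marker: the average per-day Shannon information of the
#' chain, H = -sum_i pi_i sum_j P_ij log2 P_ij, in bits/day, with the
#' convention 0 log 0 = 0. Bounded by log2(number of states).
#'
#' @param chain a [two_scale_chain()].
#' @param pi its stationary distribution; computed if `NULL`.
#' @return entropy rate in bits/day.
#' @examples
#' sp <- state_space("M", c("a", "b"))
#' entropy_rate(two_scale_chain(matrix(0.5, 2, 2), sp))  # fair coin: 1 bit
#' @export
entropy_rate <- function(chain, pi = NULL) {
  stopifnot(inherits(chain, "two_scale_chain"))
  if (is.null(pi)) pi <- stationary_distribution(chain)
  if (length(pi) != nrow(chain$P))
    stop("stationary distribution does not match chain dimension",
         call. = FALSE)
  matrix_entropy_rate(chain$P, as.numeric(pi))
}

# H = -sum_i pi_i sum_j P_ij log2 P_ij, 0 log 0 = 0
matrix_entropy_rate <- function(P, pi) {
  L <- ifelse(P > 0, P * log2(P), 0)
  max(0, -sum(pi * rowSums(L)))
}

#' Conditional micro-state chain of one macro-state
#'
#' Extracts the micro-state dynamics of a single macro-state taken in
#' isolation: the within-macro block of the flattened transition matrix
#' is cut out and each row renormalized to sum 1, removing the (small)
#' leak mass toward other macro-states. This is the process governing
#' daily behaviour while the patient remains in that clinical regime.
#'
#' @param chain a [two_scale_chain()].
#' @param macro macro-state label.
#' @param pi_source how the block's stationary weights are obtained:
#'   `"block"` (default) solves the renormalized block's own fixed point;
#'   `"global"` instead conditions the full chain's stationary vector on
#'   the macro-state. The two agree when cross-macro leakage is zero and
#'   differ only slightly for strongly lumped chains.
#' @return list with `P` (micro x micro stochastic matrix), `pi`
#'   (micro-level `stationary_distribution`), `macro`, and `leak` (per-row
#'   probability mass that pointed outside the macro-state before
#'   renormalization).
#' @export
conditional_micro_chain <- function(chain, macro,
                                    pi_source = c("block", "global")) {
  stopifnot(inherits(chain, "two_scale_chain"))
  pi_source <- match.arg(pi_source)
  if (!macro %in% chain$space$macro_labels)
    stop("unknown macro-state: ", macro, call. = FALSE)
  idx <- macro_block_index(chain$space, macro)
  B <- chain$P[idx, idx, drop = FALSE]
  rs <- rowSums(B)
  if (any(rs == 0))
    stop("micro-state ", rownames(B)[which(rs == 0)[1L]],
         " is unreachable within macro-state ", macro, call. = FALSE)
  Pb <- B / rs
  micro <- chain$space$micro_labels[[macro]]
  dimnames(Pb) <- list(micro, micro)
  if (pi_source == "block") {
    check_irreducible(Pb)
    pib <- stationary_solve(Pb)
  } else {
    pig <- as.numeric(stationary_distribution(chain))[idx]
    pib <- pig / sum(pig)
  }
  list(P = Pb,
       pi = new_stationary(pib, level = "micro", labels = micro),
       macro = macro, leak = 1 - rs / rowSums(chain$P[idx, , drop = FALSE]))
}

#' Macro-centric entropy rate
#'
#' Third-order marker: the entropy rate of the micro-state dynamics of a
#' single macro-state taken in isolation,
#' H_M = -sum_i ptilde_i sum_j Ptilde_ij log2 Ptilde_ij (bits/day),
#' where Ptilde is the renormalized within-macro block and ptilde its
#' stationary distribution. It captures how tightly or loosely daily
#' behaviour is regulated within one clinical regime, and so
#' discriminates regimes that global occupancy and global entropy rate
#' blur together.
#'
#' @inheritParams conditional_micro_chain
#' @return entropy rate in bits/day, bounded by log2(number of
#'   micro-states of `macro`).
#' @examples
#' ch <- example_psychosis_chain()
#' macro_centric_entropy_rate(ch, "D")  # stable regime: low variability
#' @export
macro_centric_entropy_rate <- function(chain, macro,
                                       pi_source = c("block", "global")) {
  cond <- conditional_micro_chain(chain, macro, pi_source = pi_source)
  matrix_entropy_rate(cond$P, as.numeric(cond$pi))
}

#' Mixing time of a chain
#'
#' The smallest number of days t such that, from the worst starting
#' state, the distribution of the chain after t days is within `epsilon`
#' total-variation distance of the stationary distribution. A prolonged
#' mixing time is a candidate proxy for lack of behavioural flexibility.
#'
#' @param chain a [two_scale_chain()].
#' @param epsilon total-variation threshold in (0, 1); default 0.25, the
#'   standard convention.
#' @param max_t hard cap on the number of days examined (default 1e5).
#' @return integer number of days.
#' @export
mixing_time <- function(chain, epsilon = 0.25, max_t = 1e5) {
  stopifnot(inherits(chain, "two_scale_chain"),
            epsilon > 0, epsilon < 1)
  pi <- as.numeric(stationary_distribution(chain))
  Pt <- chain$P
  for (t in seq_len(max_t)) {
    tv <- max(0.5 * rowSums(abs(Pt - matrix(pi, nrow(Pt), length(pi),
                                            byrow = TRUE))))
    if (tv <= epsilon) return(as.integer(t))
    Pt <- Pt %*% chain$P
  }
  stop("mixing time exceeds cap of ", max_t,
       " days (chain periodic or nearly so)", call. = FALSE)
}

#' Mean recurrence time of a state
#'
#' Expected number of days between successive visits to a state; for a
#' positive-recurrent chain this is 1 / pi_state. The recurrence time of
#' a low-complexity state quantifies inertia: how long, on average,
#' before the system falls back into that pattern.
#'
#' @param pi a [stationary_distribution()] at any level.
#' @param state a label of that level.
#' @return days.
#' @export
mean_recurrence_time <- function(pi, state) {
  stopifnot(inherits(pi, "stationary_distribution"))
  p <- unclass(pi)[state]
  if (is.na(p)) stop("unknown state: ", state, call. = FALSE)
  if (p <= 0) stop("state ", state, " has zero stationary mass",
                   call. = FALSE)
  unname(1 / p)
}
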