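#' Build a two-time-scale chain from a raw transition matrix
#'
#' Validates a nonnegative square matrix of daily transition weights over
#' the flattened (macro, micro) states and row-normalizes it into a
#' stochastic matrix. Published or hand-entered matrices often carry
#' rounding (or worse) in their rows, so rows are always divided by their
#' sums; the original row sums are kept in a normalization report and a
#' warning is emitted for every row deviating from 1 by more than
#' `warn_tol`.
#'
#' @param raw_matrix nonnegative square numeric matrix, one row per
#'   flattened state, rows in the macro-major order of `space`.
#' @param space a [state_space()] whose flattened size matches the matrix
#'   dimension. Alternatively `NULL`, in which case dimnames of
#'   `raw_matrix` are used as flat labels of a single-macro space.
#' @param warn_tol warn when a row's original sum deviates from 1 by more
#'   than this fraction (default 0.01).
#'
#' @return An object of class `two_scale_chain`: list with `P` (row
#'   stochastic matrix, dimnames = flat labels), `space`, and
#'   `normalization` (data frame: `state`, `original_sum`, `flagged`).
#' @examples
#' sp <- state_space("M", c("a", "b"))
#' ch <- two_scale_chain(matrix(c(1, 1, 3, 1), 2, byrow = TRUE), sp,
#'                       warn_tol = Inf)
#' ch$P
#' @export
two_scale_chain <- function(raw_matrix, space, warn_tol = 0.01) {
  P <- as.matrix(raw_matrix)
  if (nrow(P) != ncol(P))
    stop("transition matrix must be square, got ", nrow(P), "x", ncol(P),
         call. = FALSE)
  if (!is.numeric(P) || anyNA(P))
    stop("transition matrix must be numeric with no missing values",
         call. = FALSE)
  if (any(P < 0))
    stop("negative transition weight at [",
         paste(which(P < 0, arr.ind = TRUE)[1L, ], collapse = ","), "]",
         call. = FALSE)
  if (is.null(space)) {
    labs <- rownames(P)
    if (is.null(labs)) labs <- paste0("s", seq_len(nrow(P)))
    space <- state_space("S", labs)
    space$flat_labels <- labs           # single pseudo-macro wrapper
    space$macro_of <- rep("S", nrow(P))
  }
  stopifnot(inherits(space, "ddm_state_space"))
  if (space$n_flat != nrow(P))
    stop("matrix dimension ", nrow(P), " does not match flattened state",
         " space size ", space$n_flat, call. = FALSE)
  sums <- rowSums(P)
  if (any(sums == 0))
    stop("all-zero row for state ",
         space$flat_labels[which(sums == 0)[1L]], call. = FALSE)
  flagged <- abs(sums - 1) > warn_tol
  if (any(flagged))
    warning(sum(flagged), " row(s) deviate from sum 1 by more than ",
            warn_tol, " (worst: ",
            space$flat_labels[which.max(abs(sums - 1))], " = ",
            signif(max(sums[flagged]), 5), "); rows renormalized",
            call. = FALSE)
  P <- P / sums
  dimnames(P) <- list(space$flat_labels, space$flat_labels)
  structure(
    list(P = P, space = space,
         normalization = data.frame(state = space$flat_labels,
                                    original_sum = unname(sums),
                                    flagged = unname(flagged))),
    class = "two_scale_chain")
}

#' @export
print.two_scale_chain <- function(x, ...) {
  cat("Two-time-scale Markov chain:", x$space$n_flat, "flattened states (",
      length(x$space$macro_labels), "macro-states )\n")
  nf <- sum(x$normalization$flagged)
  if (nf > 0)
    cat("  ", nf, "input row(s) renormalized (original sum off by > tol)\n")
  invisible(x)
}

#' Read a transition matrix from delimited text
#'
#' Expects a header row and first column of flattened state labels (e.g.
#' `AR`, `AW`, ..., `EF`). The field separator is sniffed from the header
#' (comma or tab); surrounding whitespace is tolerated. Macro/micro
#' structure is inferred from the labels when `space` is not supplied:
#' the first character is taken as the macro label and the remainder as
#' the micro symbol.
#'
#' @param path file path.
#' @param space optional [state_space()]; inferred from labels otherwise.
#' @param warn_tol passed to [two_scale_chain()].
#' @return a `two_scale_chain`.
#' @export
read_chain <- function(path, space = NULL, warn_tol = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, strip.white = TRUE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop("malformed matrix file: ", nrow(M), " rows but ", ncol(M),
         " columns (truncated file?)", call. = FALSE)
  if (!all(rownames(M) == colnames(M)))
    stop("row labels do not match column labels", call. = FALSE)
  if (!is.numeric(M) || anyNA(M)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric entry near row ", rownames(M)[bad[1L, 1L]],
         call. = FALSE)
  }
  if (is.null(space)) space <- infer_space_from_labels(rownames(M))
  two_scale_chain(M, space, warn_tol = warn_tol)
}

# "AR","AW",...  ->  macro = first character, micro = rest
infer_space_from_labels <- function(labels) {
  macro <- substr(labels, 1L, 1L)
  micro <- substring(labels, 2L)
  macs <- unique(macro)
  state_space(macs, lapply(macs, function(m) micro[macro == m]))
}

#' Write a chain's transition matrix as delimited text
#'
#' @param chain a `two_scale_chain`.
#' @param path output file.
#' @param digits decimal places (default 6).
#' @param sep field separator.
#' @export
write_chain <- function(chain, path, digits = 6, sep = ",") {
  stopifnot(inherits(chain, "two_scale_chain"))
  M <- formatC(chain$P, digits = digits, format = "f")
  lines <- c(paste(c("", colnames(chain$P)), collapse = sep),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(rownames(chain$P)[i], M[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 20-state psychosis-trajectory example chain
#'
#' Loads the illustrative transition matrix shipped with the package: a
#' hypothetical patient trajectory over five clinical macro-states
#' (acute A, persistent B, residual C, stable D, prodromal E), each with
#' four daily behavioural micro-states (regulated routine R, withdrawn W,
#' no-regular-usage N, fragmented F), one transition per day. As
#' published, several rows do not sum to 1; they are renormalized on load
#' and the deviations recorded in the chain's `normalization` report (a
#' warning is suppressed here because the deviation is a known property
#' of this matrix, not of your data).
#'
#' @return a `two_scale_chain` over 20 flattened states.
#' @examples
#' ch <- example_psychosis_chain()
#' dim(ch$P)
#' @export
example_psychosis_chain <- function() {
  path <- system.file("extdata", "psychosis_transition_matrix.csv",
                      package = "ddmarker", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, "e173b8ec84a244cbfada5741255f1160"))
    stop("packaged example matrix is corrupted (checksum mismatch)",
         call. = FALSE)
  suppressWarnings(read_chain(path))
}
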