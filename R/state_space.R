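#' Two-level state space for a macro/micro chain
#'
#' Defines the hierarchy of slow clinical macro-states (e.g. acute,
#' stable) and fast behavioural micro-states observed daily (e.g.
#' regulated routine, withdrawn). Micro-state alphabets may differ per
#' macro-state (ragged), although the packaged example uses four micro
#' symbols throughout. Flattened states are ordered macro-major:
#' all micro-states of the first macro, then the second, and so on.
#'
#' @param macro_labels character vector of unique macro-state names.
#' @param micro_labels either a character vector (same micro alphabet for
#'   every macro) or a list of character vectors, one per macro-state.
#'
#' @return An object of class `ddm_state_space` with elements
#'   `macro_labels`, `micro_labels` (list, one vector per macro),
#'   `flat_labels` (e.g. `"AR"`, `"AW"`, ...), `n_flat`, and `macro_of`
#'   (macro label of each flattened state).
#' @examples
#' sp <- state_space(c("A", "B"), c("R", "W"))
#' sp$flat_labels
#' @export
state_space <- function(macro_labels, micro_labels) {
  macro_labels <- as.character(macro_labels)
  if (anyDuplicated(macro_labels))
    stop("macro labels must be unique", call. = FALSE)
  if (!is.list(micro_labels))
    micro_labels <- rep(list(as.character(micro_labels)), length(macro_labels))
  if (length(micro_labels) != length(macro_labels))
    stop("need one micro alphabet per macro-state", call. = FALSE)
  micro_labels <- lapply(micro_labels, as.character)
  for (m in micro_labels)
    if (length(m) < 1L || anyDuplicated(m))
      stop("micro labels must be non-empty and unique within a macro-state",
           call. = FALSE)
  names(micro_labels) <- macro_labels
  flat <- unlist(lapply(seq_along(macro_labels), function(i)
    paste0(macro_labels[i], micro_labels[[i]])), use.names = FALSE)
  if (anyDuplicated(flat))
    stop("flattened labels collide; choose distinguishable label sets",
         call. = FALSE)
  macro_of <- rep(macro_labels, vapply(micro_labels, length, 1L))
  structure(
    list(macro_labels = macro_labels, micro_labels = micro_labels,
         flat_labels = flat, n_flat = length(flat), macro_of = macro_of),
    class = "ddm_state_space")
}

#' Flattened index of a (macro, micro) pair
#'
#' @param space a [state_space()].
#' @param macro,micro labels of the pair.
#' @return 1-based index into the flattened ordering.
#' @export
flat_index <- function(space, macro, micro) {
  stopifnot(inherits(space, "ddm_state_space"))
  i <- match(macro, space$macro_labels)
  if (is.na(i)) stop("unknown macro-state: ", macro, call. = FALSE)
  j <- match(micro, space$micro_labels[[i]])
  if (is.na(j)) stop("unknown micro-state '", micro, "' in macro-state ",
                     macro, call. = FALSE)
  offset <- if (i > 1L)
    sum(vapply(space$micro_labels[seq_len(i - 1L)], length, 1L)) else 0L
  offset + j
}

#' @export
print.ddm_state_space <- function(x, ...) {
  cat("Two-level state space:", length(x$macro_labels), "macro-states,",
      x$n_flat, "flattened states\n")
  for (m in x$macro_labels)
    cat("  ", m, ": ", paste(x$micro_labels[[m]], collapse = " "), "\n",
        sep = "")
  invisible(x)
}

# indices of a macro's flattened states
macro_block_index <- function(space, macro) {
  which(space$macro_of == macro)
}
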