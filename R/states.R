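# Binary state bookkeeping shared by the simulator, the TPM builder and the
# Phi engine. Convention (documented everywhere user-facing): node 1 is the
# least-significant bit, so state index = 1 + sum(state * 2^(node - 1)).

#' Enumerate all binary states of an n-node system
#'
#' Rows are ordered by state index with node 1 as the least-significant bit:
#' (0,0,0), (1,0,0), (0,1,0), (1,1,0), ... for `n = 3`.
#'
#' @param n Number of nodes.
#' @return A `2^n` by `n` integer matrix of 0/1 values.
#' @export
#' @examples
#' all_states(2)
all_states <- function(n) {
  stopifnot(n >= 1)
  key <- paste0("bits", n)
  if (is.null(.cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(0:1), n)))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    .cache[[key]] <- m
  }
  .cache[[key]]
}

#' Index of a binary state under the package's state ordering
#'
#' @param state Integer 0/1 vector.
#' @return 1-based row/column index into a TPM ordered as [all_states()].
#' @export
#' @examples
#' state_index(c(1, 0, 0))  # 2
state_index <- function(state) {
  check_binary_state(state)
  1L + as.integer(sum(state * 2^(seq_along(state) - 1L)))
}

#' @rdname state_index
#' @export
state_label <- function(state) paste0(state, collapse = "")

check_binary_state <- function(state) {
  if (!is.numeric(state) || length(state) < 1 || anyNA(state) ||
      !all(state %in% c(0, 1))) {
    stop("`state` must be a vector of 0/1 values", call. = FALSE)
  }
  invisible(state)
}

# Labels "000", "100", ... for all 2^n states.
state_labels <- function(n) apply(all_states(n), 1, paste0, collapse = "")

# Parse "101" or c(1,0,1) into an integer vector.
parse_state <- function(state) {
  if (is.character(state) && length(state) == 1) {
    state <- as.integer(strsplit(state, "")[[1]])
  }
  check_binary_state(state)
  as.integer(state)
}
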