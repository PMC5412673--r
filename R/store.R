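#' Exemplar stores: the urn model of meaning-signal memory
#'
#' An exemplar store is an agent's entire linguistic memory: an unstructured
#' multiset of meaning-signal tokens, represented as a dense non-negative
#' integer matrix with one row per meaning ("urn") and one column per signal
#' ("ball colour"). `N[m, s]` counts the stored tokens associating meaning
#' `m` with signal `s`. All learning, punishment, inhibition, and forgetting
#' operators act by adding or removing single tokens.
#'
#' @param n_meanings Number of meanings (rows), a positive integer.
#' @param n_signals Number of signals (columns), a positive integer.
#' @param scheme Initialization scheme: `"empty"` (no tokens; agents
#'   bootstrap through the uniform innovation fallback of
#'   [production_weights()]) or `"one_per_pair"` (exactly one token of every
#'   meaning-signal association, the initialization used by closed-group
#'   reinforcement models to avoid lock-in).
#'
#' @return An object of class `exemplar_store`: a list with element `counts`
#'   (integer matrix, meanings x signals).
#' @examples
#' s <- exemplar_store(5, 5, "one_per_pair")
#' total_exemplars(s)  # 25
#' @export
exemplar_store <- function(n_meanings, n_signals,
                           scheme = c("empty", "one_per_pair")) {
  scheme <- match.arg(scheme)
  if (length(n_meanings) != 1L || is.na(n_meanings) || n_meanings < 1 ||
      length(n_signals) != 1L || is.na(n_signals) || n_signals < 1) {
    stop("`n_meanings` and `n_signals` must be positive integers.",
         call. = FALSE)
  }
  n_meanings <- as.integer(n_meanings)
  n_signals <- as.integer(n_signals)
  fill <- if (scheme == "one_per_pair") 1L else 0L
  counts <- matrix(fill, nrow = n_meanings, ncol = n_signals)
  new_exemplar_store(counts)
}

new_exemplar_store <- function(counts) {
  structure(list(counts = counts), class = "exemplar_store")
}

#' Construct an exemplar store from a count matrix
#'
#' @param counts Non-negative integer matrix (meanings x signals).
#' @return An `exemplar_store`.
#' @export
as_exemplar_store <- function(counts) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be a non-negative integer matrix.", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  new_exemplar_store(counts)
}

#' @export
print.exemplar_store <- function(x, ...) {
  cat(sprintf("<exemplar_store: %d meanings x %d signals, %d tokens>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @export
as.matrix.exemplar_store <- function(x, ...) x$counts

#' @rdname exemplar_store
#' @param store An `exemplar_store`.
#' @export
total_exemplars <- function(store) sum(store$counts)

#' @rdname exemplar_store
#' @export
n_meanings <- function(store) nrow(store$counts)

#' @rdname exemplar_store
#' @export
n_signals <- function(store) ncol(store$counts)

check_indices <- function(store, m = NULL, s = NULL) {
  if (!is.null(m) &&
      (length(m) != 1L || is.na(m) || m < 1 || m > nrow(store$counts))) {
    stop("meaning index out of range.", call. = FALSE)
  }
  if (!is.null(s) &&
      (length(s) != 1L || is.na(s) || s < 1 || s > ncol(store$counts))) {
    stop("signal index out of range.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Store a single exemplar
#'
#' Adds one token associating meaning `m` with signal `s`. Memory limits are
#' not enforced here; callers apply [enforce_memory_limit()] after (and any
#' lateral inhibition between) the add.
#'
#' @param store An `exemplar_store`.
#' @param m,s Meaning and signal indices (1-based).
#' @return The updated store.
#' @export
add_exemplar <- function(store, m, s) {
  check_indices(store, m, s)
  store$counts[m, s] <- store$counts[m, s] + 1L
  store
}

#' Delete a single exemplar (simple deletion / punishment)
#'
#' Removes one token of the association `(m, s)` if any is stored. Counts
#' floor at zero: deleting from an empty cell is a no-op, signalled as a
#' condition of class `signalurn_noop_removal` so callers can log it.
#'
#' @inheritParams add_exemplar
#' @return The updated store.
#' @export
remove_exemplar <- function(store, m, s) {
  check_indices(store, m, s)
  if (store$counts[m, s] > 0L) {
    store$counts[m, s] <- store$counts[m, s] - 1L
  } else {
    cond <- structure(
      class = c("signalurn_noop_removal", "condition"),
      list(message = sprintf("removal from empty cell (%d, %d) ignored", m, s),
           call = sys.call(-1)))
    signalCondition(cond)
  }
  store
}

#' Enforce a memory limit by random forgetting
#'
#' When a newly stored exemplar pushes the store past its capacity, one older
#' token is forgotten: a token is drawn uniformly from all stored tokens
#' excluding one instance of the just-stored (protected) association, and
#' deleted. The store never exceeds the limit after a completed update.
#'
#' @param store An `exemplar_store` whose total is at most `limit + 1`.
#' @param limit Maximum number of stored tokens (positive integer).
#' @param protected Length-2 integer vector `c(m, s)`: the token stored by the
#'   update that triggered enforcement; one instance of it is shielded from
#'   deletion.
#' @return The updated store.
#' @export
enforce_memory_limit <- function(store, limit, protected) {
  if (length(limit) != 1L || is.na(limit) || limit < 1) {
    stop("`limit` must be a positive integer.", call. = FALSE)
  }
  total <- sum(store$counts)
  if (total <= limit) return(store)
  if (total > limit + 1) {
    stop("store total exceeds limit + 1; bulk insertions violate the ",
         "single-token update contract.", call. = FALSE)
  }
  m <- protected[[1L]]; s <- protected[[2L]]
  check_indices(store, m, s)
  if (store$counts[m, s] < 1L) {
    stop("`protected` must name a stored token.", call. = FALSE)
  }
  w <- as.numeric(store$counts)
  pl <- (s - 1L) * nrow(store$counts) + m
  w[pl] <- w[pl] - 1
  k <- invcdf_raw(w)
  store$counts[[k]] <- store$counts[[k]] - 1L
  store
}

#' Lateral inhibition around a newly stored exemplar
#'
#' Deletes tokens that compete with a focal association. Anti-homonymy
#' competitors share the focal signal but differ in meaning (same column,
#' other rows); anti-synonymy competitors share the focal meaning but differ
#' in signal (same row, other columns). Strengths:
#' \describe{
#'   \item{minimal}{one competing token is deleted, drawn uniformly over all
#'     competing tokens (types with more tokens are proportionally more
#'     likely to lose one);}
#'   \item{broad}{one token is deleted from every competing type with a
#'     positive count;}
#'   \item{maximal}{all competing tokens are deleted (guarantees one-to-one
#'     mappings; provided for completeness).}
#' }
#' With `kind = "both"`, the anti-homonymy pass runs first, then the
#' anti-synonymy pass, each independently.
#'
#' @param store An `exemplar_store`.
#' @param focal Length-2 integer vector `c(m, s)`: the just-stored token.
#' @param kind `"anti_homonymy"`, `"anti_synonymy"`, or `"both"`.
#' @param strength `"minimal"`, `"broad"`, or `"maximal"`.
#' @return The updated store.
#' @export
apply_lateral_inhibition <- function(store, focal,
                                     kind = c("anti_homonymy",
                                              "anti_synonymy", "both"),
                                     strength = c("minimal", "broad",
                                                  "maximal")) {
  kind <- match.arg(kind)
  strength <- match.arg(strength)
  m <- focal[[1L]]; s <- focal[[2L]]
  check_indices(store, m, s)
  if (kind %in% c("anti_homonymy", "both")) {
    store <- inhibit_pass(store, rows = setdiff(seq_len(nrow(store$counts)), m),
                          cols = s, strength = strength)
  }
  if (kind %in% c("anti_synonymy", "both")) {
    store <- inhibit_pass(store, rows = m,
                          cols = setdiff(seq_len(ncol(store$counts)), s),
                          strength = strength)
  }
  store
}

# One inhibition pass over the competitor cells given by rows x cols (one of
# the two is a scalar). Cells are visited in ascending index order.
inhibit_pass <- function(store, rows, cols, strength) {
  vals <- store$counts[rows, cols]
  if (strength == "minimal") {
    if (sum(vals) > 0) {
      k <- invcdf_raw(vals)
      if (length(rows) > 1L) {
        store$counts[rows[k], cols] <- store$counts[rows[k], cols] - 1L
      } else {
        store$counts[rows, cols[k]] <- store$counts[rows, cols[k]] - 1L
      }
    }
  } else if (strength == "broad") {
    store$counts[rows, cols] <- pmax(vals - 1L, 0L)
  } else {
    store$counts[rows, cols] <- 0L
  }
  store
}
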