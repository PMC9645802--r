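#' Flat-multimap: a fixed-shape contiguous multimap
#'
#' A multimap from small nonnegative integer keys to value sequences, stored
#' as exactly two contiguous arrays: `a2ab`, an offset table with one entry
#' per key plus a terminator, and `ab2c`, the concatenated values.  The values
#' of key `a` occupy `ab2c[a2ab[a] .. a2ab[a+1]-1]` (0-based offsets, as the
#' container contract is usually stated).  Compared with a list-of-vectors
#' layout this needs a constant number of allocations, keeps lookups O(1)
#' offset arithmetic, and stores values contiguously; in exchange the size and
#' shape are fixed at construction.
#'
#' All fixed-shape key-to-values tables in the simulator (tetrahedron
#' neighbourhoods, dependency edges, state-index reverse maps) use this
#' container.
#'
#' @param keys integer vector of keys (0-based key space), one per value.
#' @param values vector of values, parallel to `keys`.  Any atomic type.
#' @param n_keys size of the key space; keys must lie in `0 .. n_keys-1`.
#'   Defaults to `max(keys)+1`.
#' @return An object of class `flat_multimap` with fields `a2ab` (integer,
#'   length `n_keys+1`, 0-based offsets) and `ab2c` (values, grouped by key,
#'   order of insertion preserved within a key).
#' @examples
#' m <- flat_multimap(keys = c(0, 0, 0, 2), values = c("a", "b", "c", "d"))
#' fmm_lookup(m, 0)  # "a" "b" "c"
#' fmm_lookup(m, 1)  # empty
#' @export
flat_multimap <- function(keys, values, n_keys = NULL) {
  stopifnot(length(keys) == length(values))
  keys <- as.integer(keys)
  if (length(keys) && (anyNA(keys) || min(keys) < 0L)) {
    stop("flat_multimap keys must be nonnegative integers", call. = FALSE)
  }
  if (is.null(n_keys)) n_keys <- if (length(keys)) max(keys) + 1L else 0L
  n_keys <- as.integer(n_keys)
  if (length(keys) && max(keys) >= n_keys) {
    stop(sprintf("flat_multimap key %d outside declared key space [0, %d)",
                 max(keys), n_keys), call. = FALSE)
  }
  ord <- order(keys)                       # stable: preserves insertion order
  counts <- tabulate(keys + 1L, nbins = n_keys)
  structure(
    list(a2ab = c(0L, cumsum(counts)), ab2c = values[ord]),
    class = "flat_multimap", n_keys = n_keys
  )
}

#' Look up the value range of a key
#'
#' @param map a [flat_multimap()].
#' @param key a single key: either a plain nonnegative integer (0-based) or an
#'   [entity_id()] (whose integer value is used directly).
#' @return The values stored under `key` (possibly empty), as a contiguous
#'   slice of `ab2c`.
#' @export
fmm_lookup <- function(map, key) {
  stopifnot(inherits(map, "flat_multimap"))
  if (inherits(key, "entity_id")) key <- id_value(key)
  key <- as.integer(key)
  if (length(key) != 1L || is.na(key) || key < 0L || key >= attr(map, "n_keys")) {
    stop(sprintf("flat_multimap key out of range [0, %d)", attr(map, "n_keys")),
         call. = FALSE)
  }
  lo <- map$a2ab[key + 1L]
  hi <- map$a2ab[key + 2L]
  if (lo == hi) return(map$ab2c[0L])
  map$ab2c[(lo + 1L):hi]
}

# Internal fast path: ranges for a vector of 1-based keys, no checks.
fmm_range1 <- function(map, key1) {
  c(map$a2ab[key1] + 1L, map$a2ab[key1 + 1L])
}

#' @export
print.flat_multimap <- function(x, ...) {
  cat(sprintf("<flat_multimap> %d keys, %d values\n",
              attr(x, "n_keys"), length(x$ab2c)))
  invisible(x)
}

#' @export
length.flat_multimap <- function(x) attr(x, "n_keys")
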