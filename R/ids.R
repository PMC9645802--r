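#' Vocabulary-typed entity identifiers
#'
#' Simulation entities (tetrahedra, triangles, vertices, species, kinetic
#' processes, ranks) are indexed by plain integers internally, but the public
#' interfaces accept and return *typed* ids: integer vectors carrying a `kind`
#' attribute.  Passing an id of one kind where another is expected is an error,
#' surfaced immediately rather than as a silent mis-indexing.  This mirrors the
#' "vocabulary type" discipline of strongly typed simulators, adapted to R's
#' dynamic setting: the check happens at call time instead of compile time.
#'
#' Ids are 1-based (R convention).  Raw integers appear only at I/O boundaries
#' (mesh files use their own numbering, converted on read/write).
#'
#' @param value nonnegative integer vector.
#' @param kind one of `"tet"`, `"tet_global"`, `"tri"`, `"vertex"`,
#'   `"species"`, `"kproc"`, `"rank"`.
#' @return An integer vector of class `entity_id` with a `kind` attribute.
#' @examples
#' t1 <- entity_id(3, "tet")
#' id_value(t1)
#' @export
entity_id <- function(value, kind) {
  kind <- match.arg(kind, ID_KINDS)
  value <- as.integer(value)
  if (any(is.na(value)) || any(value < 0L)) {
    stop("entity ids must be nonnegative integers", call. = FALSE)
  }
  structure(value, class = "entity_id", kind = kind)
}

ID_KINDS <- c("tet", "tet_global", "tri", "vertex", "species", "kproc", "rank")

#' @rdname entity_id
#' @param x an `entity_id`.
#' @export
id_kind <- function(x) attr(x, "kind")

#' @rdname entity_id
#' @export
id_value <- function(x) as.integer(unclass(x))

#' @export
print.entity_id <- function(x, ...) {
  cat(sprintf("<%s id> %s\n", id_kind(x), paste(id_value(x), collapse = " ")))
  invisible(x)
}

#' @export
format.entity_id <- function(x, ...) sprintf("%s:%d", id_kind(x), id_value(x))

# Internal guard used by public signatures that take typed ids.  Accepts a
# plain integer only when allow_raw is TRUE (convenience paths).
assert_id <- function(x, kind, what = deparse(substitute(x)), allow_raw = FALSE) {
  if (inherits(x, "entity_id")) {
    if (!identical(id_kind(x), kind)) {
      stop(sprintf("'%s' is a %s id, expected a %s id", what, id_kind(x), kind),
           call. = FALSE)
    }
    return(id_value(x))
  }
  if (allow_raw && is.numeric(x)) return(as.integer(x))
  stop(sprintf("'%s' must be an entity_id of kind '%s' (see entity_id())",
               what, kind), call. = FALSE)
}
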