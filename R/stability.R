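# Formal concept analysis of the feature-by-technique presence/absence table.

#' Formal context of features versus selection techniques
#'
#' A binary incidence relation between objects (features) and attributes
#' (selection techniques). Row sums are the stability degrees: the number
#' of techniques whose top set contains each feature.
#'
#' @param objects,attributes unique name vectors.
#' @param incidence binary matrix, objects in rows.
#' @return An object of class `formal_context`.
#' @export
formal_context <- function(objects, attributes, incidence) {
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  stopifnot(is.matrix(incidence),
            nrow(incidence) == length(objects),
            ncol(incidence) == length(attributes))
  if (anyDuplicated(objects)) stop("duplicate objects", call. = FALSE)
  if (anyDuplicated(attributes)) stop("duplicate attributes", call. = FALSE)
  if (!all(incidence %in% c(0, 1))) stop("incidence must be binary", call. = FALSE)
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(objects, attributes)
  structure(list(objects = objects, attributes = attributes, incidence = incidence),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("formal_context: %d objects x %d attributes, %d incidences\n",
              length(x$objects), length(x$attributes), sum(x$incidence)))
  invisible(x)
}

#' Build the presence/absence context from per-technique top sets
#'
#' Objects are the union of all top sets in lexicographic order (a feature
#' selected by no technique never enters the context); attributes are the
#' technique ids; `incidence[f, m] = 1` iff feature f is in technique m's
#' top set.
#'
#' @param top_sets named list, one feature-id vector per technique.
#' @return A [formal_context].
#' @examples
#' build_context(list(A = c("x", "y"), B = "y"))$incidence
#' @export
build_context <- function(top_sets) {
  stopifnot(is.list(top_sets), length(top_sets) >= 1)
  ids <- names(top_sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("top_sets must be named by technique", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate method ids", call. = FALSE)
  if (any(lengths(top_sets) == 0)) stop("empty top set(s): ",
                                        paste(ids[lengths(top_sets) == 0], collapse = ", "),
                                        call. = FALSE)
  objects <- sort(unique(unlist(top_sets)))
  inc <- vapply(top_sets, function(s) as.integer(objects %in% s),
                integer(length(objects)))
  if (length(objects) == 1L) inc <- matrix(inc, nrow = 1)
  formal_context(objects, ids, inc)
}

#' Stability degree of each feature
#'
#' @param context a [formal_context].
#' @return Named integer vector: for each object, the number of attributes
#'   (techniques) it is incident with.
#' @export
stability_degrees <- function(context) {
  stopifnot(inherits(context, "formal_context"))
  stats::setNames(as.integer(rowSums(context$incidence)), context$objects)
}

#' Consensus selection of stable features
#'
#' Features whose stability degree (number of selecting techniques) is at
#' least k, ordered by descending degree then feature id. `k = 1` gives the
#' union of all top sets, `k = ncol` their intersection.
#'
#' @param context a [formal_context].
#' @param k minimum number of techniques, `1 <= k <=` attribute count.
#' @return Character vector of feature ids.
#' @export
consensus_select <- function(context, k = 6) {
  stopifnot(inherits(context, "formal_context"))
  if (k < 1 || k > length(context$attributes)) {
    stop(sprintf("k must lie in [1, %d]", length(context$attributes)), call. = FALSE)
  }
  deg <- stability_degrees(context)
  sel <- deg[deg >= k]
  names(sel)[order(-sel, names(sel))]
}

# closure operator on attribute index sets: B -> (B')' as plain indices
attr_closure <- function(inc, b_idx) {
  if (length(b_idx) == 0) {
    extent <- seq_len(nrow(inc))
  } else {
    extent <- unname(which(rowSums(inc[, b_idx, drop = FALSE]) == length(b_idx)))
  }
  if (length(extent) == 0) return(list(intent = seq_len(ncol(inc)), extent = integer(0)))
  intent <- unname(which(colSums(inc[extent, , drop = FALSE]) == length(extent)))
  list(intent = intent, extent = extent)
}

#' Enumerate all formal concepts (NextClosure)
#'
#' Enumerates every concept of the context by Ganter's NextClosure
#' algorithm: closed attribute sets are visited in lectic order, so each
#' concept is produced exactly once and the enumeration is provably
#' complete. The sub-concept partial order (extent containment) is returned
#' as the cover relation (transitive reduction).
#'
#' @param context a non-empty [formal_context].
#' @param order also build the cover relation (default `TRUE`; skipping it
#'   is cheaper when only the concept set is needed).
#' @return An object of class `concept_lattice`: `concepts` (list of
#'   `extent`/`intent` character vectors), `extents`/`intents` (index
#'   lists), and `cover` (two-column matrix of sub-concept -> super-concept
#'   cover edges, indices into `concepts`, ordered from smaller to larger
#'   extent).
#' @export
derive_concepts <- function(context, order = TRUE) {
  stopifnot(inherits(context, "formal_context"))
  inc <- context$incidence
  m <- ncol(inc)
  concepts <- list()
  cl <- attr_closure(inc, integer(0))
  a <- cl$intent
  concepts[[1]] <- cl
  repeat {
    nxt <- NULL
    for (i in rev(seq_len(m))) {
      if (i %in% a) next
      b <- c(a[a < i], i)
      cl <- attr_closure(inc, b)
      # lectic condition: no new element smaller than i
      new_small <- setdiff(cl$intent[cl$intent < i], a[a < i])
      if (length(new_small) == 0) {
        nxt <- cl
        break
      }
    }
    if (is.null(nxt)) break
    concepts[[length(concepts) + 1]] <- nxt
    a <- nxt$intent
  }
  extents <- lapply(concepts, `[[`, "extent")
  intents <- lapply(concepts, `[[`, "intent")
  n <- length(concepts)
  # order by extent size so the partial order runs bottom (smallest extent) up
  ord <- order(lengths(extents))
  extents <- extents[ord]; intents <- intents[ord]
  if (order && n > 1) {
    ext_mat <- matrix(0L, n, nrow(inc))
    for (i in seq_len(n)) ext_mat[i, extents[[i]]] <- 1L
    # leq[i, j]: extent_i strict subset of extent_j (no element of i outside j)
    leq <- (ext_mat %*% t(1L - ext_mat)) == 0L
    diag(leq) <- FALSE
    between <- (leq %*% leq) > 0           # some concept strictly between
    cov_idx <- which(leq & !between, arr.ind = TRUE)
    cover <- matrix(as.integer(cov_idx), ncol = 2,
                    dimnames = NULL)[order(cov_idx[, 1], cov_idx[, 2]), ,
                                     drop = FALSE]
  } else {
    cover <- matrix(integer(0), 0, 2)
  }
  structure(list(
    concepts = lapply(seq_len(n), function(i) list(
      extent = context$objects[extents[[i]]],
      intent = context$attributes[intents[[i]]])),
    extents = extents, intents = intents, cover = cover,
    objects = context$objects, attributes = context$attributes),
    class = "concept_lattice")
}

#' @export
print.concept_lattice <- function(x, ...) {
  st <- lattice_stats(x)
  cat(sprintf("concept_lattice: %d concepts, height %d\n", st$n_concepts, st$height))
  invisible(x)
}

#' Summary statistics of a concept lattice
#'
#' @param lattice a `concept_lattice`.
#' @return A list: `n_concepts`, `height` (length in edges of the longest
#'   chain in the cover relation), `extent_sizes`, `intent_sizes`.
#' @export
lattice_stats <- function(lattice) {
  stopifnot(inherits(lattice, "concept_lattice"))
  n <- length(lattice$extents)
  height <- rep(0L, n)
  if (nrow(lattice$cover) > 0) {
    # concepts are ordered by extent size, so cover edges go from lower to
    # higher index and one sweep suffices
    for (e in seq_len(nrow(lattice$cover))) {
      i <- lattice$cover[e, 1]; j <- lattice$cover[e, 2]
      height[j] <- max(height[j], height[i] + 1L)
    }
  }
  list(n_concepts = n, height = max(height),
       extent_sizes = lengths(lattice$extents),
       intent_sizes = lengths(lattice$intents))
}

#' Export the lattice cover relation as GraphML
#'
#' Nodes are concepts (attributes: extent and intent sizes, intent label);
#' directed edges follow the cover relation from sub- to super-concept.
#' Written with igraph for use in external graph viewers.
#'
#' @param lattice a `concept_lattice`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lattice_graphml <- function(lattice, path) {
  stopifnot(inherits(lattice, "concept_lattice"))
  n <- length(lattice$extents)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "extent_size", value = lengths(lattice$extents))
  g <- igraph::set_vertex_attr(g, "intent_size", value = lengths(lattice$intents))
  g <- igraph::set_vertex_attr(g, "intent", value = vapply(
    lattice$concepts, function(cc) paste(cc$intent, collapse = "|"), character(1)))
  if (nrow(lattice$cover) > 0) {
    g <- igraph::add_edges(g, t(lattice$cover))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Context from a published rank table
#'
#' Converts a features-by-techniques table of ranks (NA where a feature was
#' absent from a technique's ranking) into a presence/absence context:
#' `incidence[f, m] = 1` iff the feature's rank under technique m is within
#' that technique's retained top-set size.
#'
#' @param ranks numeric matrix or data frame of ranks, feature ids as row
#'   names, technique ids as column names.
#' @param top_sizes named integer vector of retained top-set sizes, one per
#'   technique column.
#' @return A [formal_context] (features selected by no technique are dropped).
#' @export
rank_table_context <- function(ranks, top_sizes) {
  ranks <- as.matrix(ranks)
  stopifnot(!is.null(rownames(ranks)), !is.null(colnames(ranks)))
  if (!all(colnames(ranks) %in% names(top_sizes))) {
    stop("top_sizes must cover every technique column", call. = FALSE)
  }
  inc <- matrix(0L, nrow(ranks), ncol(ranks), dimnames = dimnames(ranks))
  for (m in colnames(ranks)) {
    inc[, m] <- as.integer(!is.na(ranks[, m]) & ranks[, m] <= top_sizes[[m]])
  }
  keep <- rowSums(inc) > 0
  formal_context(rownames(ranks)[keep], colnames(ranks), inc[keep, , drop = FALSE])
}
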