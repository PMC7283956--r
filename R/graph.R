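# Molecular associations network (MAN): typed node registry, nine relation
# types, undirected edge set and a deterministic adjacency index.

NODE_TYPES <- c("drug", "protein", "disease", "lncRNA", "miRNA")

# Each relation constrains the (ordered-as-written) endpoint types; columns
# of a two-column edge-list file follow this order.
RELATION_ENDPOINTS <- list(
  "drug-target"     = c("drug", "protein"),
  "drug-disease"    = c("drug", "disease"),
  "protein-disease" = c("protein", "disease"),
  "lncRNA-target"   = c("lncRNA", "protein"),
  "lncRNA-disease"  = c("lncRNA", "disease"),
  "miRNA-target"    = c("miRNA", "protein"),
  "miRNA-disease"   = c("miRNA", "disease"),
  "miRNA-lncRNA"    = c("miRNA", "lncRNA"),
  "protein-protein" = c("protein", "protein")
)

#' The nine association types of the molecular associations network
#'
#' @return character vector of the nine relation labels. Each label fixes
#'   the unordered pair of endpoint node types (for example `"drug-target"`
#'   joins a drug to a protein); `"protein-protein"` is the only relation
#'   whose two endpoints share a type.
#' @examples
#' relation_types()
#' @export
relation_types <- function() {
  names(RELATION_ENDPOINTS)
}

#' Node types of the molecular associations network
#'
#' @return character vector of the five molecule classes.
#' @export
node_types <- function() {
  NODE_TYPES
}

# "<type>:<raw_id>" namespacing keeps identifiers from different source
# databases distinct even when the raw strings collide.
make_node_id <- function(type, raw_id) {
  paste0(type, ":", raw_id)
}

node_type_of <- function(id) {
  sub(":.*$", "", id)
}

#' Load a typed association edge list
#'
#' Reads a tab-separated edge-list file. Two-column files (`src`, `dst`)
#' require `relation`; the columns are namespaced with the endpoint types
#' the relation declares, in the order the relation label is written.
#' Three-column files carry the relation label in column 3 and `relation`
#' may be omitted. Lines starting with `#` are comments. Duplicate rows
#' within a file are collapsed, keeping first-occurrence order.
#'
#' @param path path to a TSV edge list.
#' @param relation one of [relation_types()], or `NULL` for 3-column files.
#' @return data.frame with columns `u`, `v` (namespaced node ids) and
#'   `relation`.
#' @export
load_edge_list <- function(path, relation = NULL) {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(u = character(), v = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(!(ncols %in% c(2L, 3L)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of %s: expected 2 or 3 columns, got %d",
                 line_no[bad[1L]], path, ncols[bad[1L]]), call. = FALSE)
  }
  rel <- if (all(ncols == 3L)) {
    vapply(parts, `[[`, character(1L), 3L)
  } else if (all(ncols == 2L)) {
    if (is.null(relation)) {
      stop("two-column edge list requires an explicit 'relation'",
           call. = FALSE)
    }
    rep(relation, length(parts))
  } else {
    stop(sprintf("mixed 2- and 3-column rows in %s (first at line %d)",
                 path, line_no[which(ncols != ncols[1L])[1L]]), call. = FALSE)
  }
  unknown <- !(rel %in% names(RELATION_ENDPOINTS))
  if (any(unknown)) {
    stop(sprintf("unknown relation type '%s' at line %d of %s",
                 rel[unknown][1L], line_no[unknown][1L], path), call. = FALSE)
  }
  src <- vapply(parts, `[[`, character(1L), 1L)
  dst <- vapply(parts, `[[`, character(1L), 2L)
  if (any(src == "" | dst == "")) {
    i <- which(src == "" | dst == "")[1L]
    stop(sprintf("empty node id at line %d of %s", line_no[i], path),
         call. = FALSE)
  }
  types <- RELATION_ENDPOINTS[rel]
  # ids may already be namespaced (canonical 3-column export); validate those
  namespace_col <- function(raw, pos) {
    expected <- vapply(types, `[[`, character(1L), pos)
    pre <- grepl(":", raw, fixed = TRUE)
    out <- ifelse(pre, raw, make_node_id(expected, raw))
    mismatch <- node_type_of(out) != expected
    if (any(mismatch)) {
      i <- which(mismatch)[1L]
      stop(sprintf(
        "line %d of %s: node '%s' has type '%s' but relation '%s' requires '%s'",
        line_no[i], path, out[i], node_type_of(out[i]), rel[i], expected[i]),
        call. = FALSE)
    }
    out
  }
  edges <- data.frame(u = namespace_col(src, 1L),
                      v = namespace_col(dst, 2L),
                      relation = rel, stringsAsFactors = FALSE)
  edges[!duplicated(canonical_edge_key(edges)), , drop = FALSE]
}

# Unordered (u, v, relation) key used for deduplication.
canonical_edge_key <- function(edges) {
  lo <- pmin(edges$u, edges$v)
  hi <- pmax(edges$u, edges$v)
  paste(lo, hi, edges$relation, sep = "\r")
}

#' Assemble a molecular associations network from edge lists
#'
#' Builds the undirected typed multigraph: the node set is the union of all
#' edge endpoints, duplicate `(u, v, relation)` triples across inputs are
#' collapsed, and a lexicographically sorted adjacency index over the
#' underlying simple graph is precomputed for the random walker. Self-loops
#' (legal only for protein-protein) stay in the edge set but are excluded
#' from adjacency, where a uniform walk stepping onto itself would add no
#' co-occurrence information.
#'
#' @param edge_lists a single edge data.frame (as returned by
#'   [load_edge_list()]) or a list of them.
#' @return an object of class `man_graph` with components `nodes`
#'   (data.frame `id`, `type`), `edges` (data.frame `u`, `v`, `relation`)
#'   and `adjacency` (named list of sorted neighbor ids).
#' @export
assemble_man <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edges <- if (length(edge_lists) == 0L) {
    data.frame(u = character(), v = character(), relation = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, edge_lists)
  }
  validate_edge_types(edges)
  edges <- edges[!duplicated(canonical_edge_key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$u, edges$v)))
  nodes <- data.frame(id = ids, type = node_type_of(ids),
                      stringsAsFactors = FALSE)
  g <- structure(
    list(nodes = nodes, edges = edges,
         adjacency = build_adjacency(ids, edges)),
    class = "man_graph")
  g
}

validate_edge_types <- function(edges) {
  if (nrow(edges) == 0L) return(invisible(TRUE))
  tu <- node_type_of(edges$u)
  tv <- node_type_of(edges$v)
  expected <- RELATION_ENDPOINTS[edges$relation]
  ok <- mapply(function(a, b, exp) {
    setequal(c(a, b), exp) ||
      (exp[1L] == exp[2L] && a == exp[1L] && b == exp[1L])
  }, tu, tv, expected)
  self <- edges$u == edges$v & edges$relation != "protein-protein"
  if (any(!ok | self)) {
    i <- which(!ok | self)[1L]
    stop(sprintf(
      "edge (%s, %s) violates relation '%s' endpoint constraint",
      edges$u[i], edges$v[i], edges$relation[i]), call. = FALSE)
  }
  invisible(TRUE)
}

# Adjacency over the simple graph: duplicate node pairs under different
# relation types collapse to one neighbor entry; self-loops dropped;
# neighbor lists sorted lexicographically so seeded walks are reproducible.
build_adjacency <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character()
  keep <- edges$u != edges$v
  if (any(keep)) {
    e <- edges[keep, , drop = FALSE]
    pair_key <- paste(pmin(e$u, e$v), pmax(e$u, e$v), sep = "\r")
    e <- e[!duplicated(pair_key), , drop = FALSE]
    nb <- split(c(e$v, e$u), c(e$u, e$v))
    for (id in names(nb)) adj[[id]] <- sort(nb[[id]])
  }
  adj
}

#' Neighbors of a node in the walked (simple) graph
#'
#' @param g a `man_graph`.
#' @param v a namespaced node id present in `g`.
#' @return sorted character vector of neighbor ids (deduplicated across
#'   relation types, self-loops excluded).
#' @export
man_neighbors <- function(g, v) {
  stopifnot(inherits(g, "man_graph"))
  if (!v %in% g$nodes$id) {
    stop("unknown node: ", v, call. = FALSE)
  }
  g$adjacency[[v]]
}

#' Summarize a molecular associations network
#'
#' @param g a `man_graph`.
#' @return list with `n_nodes`, `n_edges`, `node_counts` (named by the five
#'   node types) and `edge_counts` (named by the nine relation types).
#' @export
summarize_man <- function(g) {
  stopifnot(inherits(g, "man_graph"))
  node_counts <- vapply(NODE_TYPES, function(t) sum(g$nodes$type == t),
                        integer(1L))
  edge_counts <- vapply(names(RELATION_ENDPOINTS),
                        function(r) sum(g$edges$relation == r), integer(1L))
  list(n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
       node_counts = node_counts, edge_counts = edge_counts)
}

#' @export
print.man_graph <- function(x, ...) {
  s <- summarize_man(x)
  cat(sprintf("Molecular associations network: %d nodes, %d edges\n",
              s$n_nodes, s$n_edges))
  cat("  nodes:", paste(sprintf("%s=%d", names(s$node_counts),
                                s$node_counts), collapse = ", "), "\n")
  nz <- s$edge_counts[s$edge_counts > 0L]
  if (length(nz)) {
    cat("  edges:", paste(sprintf("%s=%d", names(nz), nz),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a network as a canonical three-column edge list
#'
#' Written rows are `u`, `v`, `relation` with namespaced ids; reloading
#' with [load_edge_list()] and [assemble_man()] reproduces the graph.
#'
#' @param g a `man_graph`.
#' @param path output TSV path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "man_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the network summary as JSON
#'
#' @param g a `man_graph`.
#' @param path output JSON path.
#' @export
write_graph_summary <- function(g, path) {
  s <- summarize_man(g)
  jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Remove specific drug-target edges (used for leakage-safe per-fold
# embeddings); pairs is a data.frame with columns drug, protein.
remove_dti_edges <- function(g, pairs) {
  stopifnot(inherits(g, "man_graph"))
  if (nrow(pairs) == 0L) return(g)
  drop_key <- paste(pmin(pairs$drug, pairs$protein),
                    pmax(pairs$drug, pairs$protein), "drug-target",
                    sep = "\r")
  keep <- !(canonical_edge_key(g$edges) %in% drop_key)
  edges <- g$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  # node set is kept: isolated molecules still get (length-1) walks
  structure(
    list(nodes = g$nodes, edges = edges,
         adjacency = build_adjacency(g$nodes$id, edges)),
    class = "man_graph")
}
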