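# Structure-graph ontology: parsing, traversal, and the two-level
# (leaf / parent) decomposition that drives region-by-region registration.

#' Construct a structure graph from a node table
#'
#' @param df data.frame with columns `id`, `parent_id` (NA for the root),
#'   and optionally `acronym`, `name`, `color` (hex string).
#' @return an object of class `structure_graph` with a `nodes` list keyed by
#'   id, each node holding `id`, `acronym`, `name`, `parent`, `children`,
#'   `color`.
#' @export
structure_graph <- function(df) {
  if (!all(c("id", "parent_id") %in% names(df)))
    af_stop("structure graph needs 'id' and 'parent_id' columns")
  ids <- as.integer(df$id)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    af_stop("duplicate structure id %d", dup)
  }
  if (any(is.na(ids)) || any(ids <= 0)) af_stop("structure ids must be positive integers")
  parents <- suppressWarnings(as.integer(df$parent_id))
  root <- ids[is.na(parents)]
  if (length(root) != 1L)
    af_stop("structure graph must have exactly one root, found %d", length(root))
  orphan <- !is.na(parents) & !(parents %in% ids)
  if (any(orphan))
    af_stop("node %d references missing parent %d",
            ids[orphan][1], parents[orphan][1])
  nodes <- vector("list", length(ids))
  names(nodes) <- as.character(ids)
  for (i in seq_along(ids)) {
    nodes[[i]] <- list(
      id = ids[i],
      acronym = if ("acronym" %in% names(df)) as.character(df$acronym[i]) else as.character(ids[i]),
      name = if ("name" %in% names(df)) as.character(df$name[i]) else as.character(ids[i]),
      parent = if (is.na(parents[i])) NA_integer_ else parents[i],
      children = integer(0),
      color = if ("color" %in% names(df)) as.character(df$color[i]) else "#808080")
  }
  for (i in seq_along(ids)) {
    p <- parents[i]
    if (!is.na(p)) {
      key <- as.character(p)
      nodes[[key]]$children <- c(nodes[[key]]$children, ids[i])
    }
  }
  g <- structure(list(nodes = nodes, root = root), class = "structure_graph")
  # cycle check: every node must reach the root
  for (id in ids) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) af_stop("cycle detected at structure id %d", id)
      seen <- c(seen, cur)
      cur <- g$nodes[[as.character(cur)]]$parent
    }
    if (seen[length(seen)] != root) af_stop("node %d does not reach the root", id)
  }
  g
}

#' Load a structure graph from JSON
#'
#' Accepts either the AIBS structure-graph dialect (nested nodes under a
#' top-level `msg` list, children inline) or a flat list/array of records with
#' `id` and `parent_structure_id`/`parent_id` fields.
#'
#' @param path path to a JSON ontology file.
#' @return a `structure_graph`.
#' @export
load_structure_graph <- function(path) {
  doc <- jsonlite::read_json(path)
  rows <- list()
  add_node <- function(node, parent_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.integer(node$id),
      parent_id = if (is.null(parent_id)) NA_integer_ else as.integer(parent_id),
      acronym = as.character(node$acronym %||% node$id),
      name = as.character(node$name %||% node$id),
      color = as.character(node$color_hex_triplet %||% node$color %||% "808080"),
      stringsAsFactors = FALSE)
    for (ch in node$children %||% list()) add_node(ch, node$id)
  }
  if (!is.null(doc$msg)) {
    for (n in doc$msg) add_node(n, n$parent_structure_id %||% NULL)
  } else if (is.list(doc) && length(doc) > 0 && !is.null(doc[[1]]$id)) {
    for (n in doc) {
      pid <- n$parent_structure_id %||% n$parent_id %||% NULL
      if (!is.null(n$children)) add_node(n, pid) else {
        rows[[length(rows) + 1L]] <- data.frame(
          id = as.integer(n$id),
          parent_id = if (is.null(pid)) NA_integer_ else as.integer(pid),
          acronym = as.character(n$acronym %||% n$id),
          name = as.character(n$name %||% n$id),
          color = as.character(n$color_hex_triplet %||% n$color %||% "808080"),
          stringsAsFactors = FALSE)
      }
    }
  } else af_stop("unrecognized ontology document in %s", path)
  structure_graph(do.call(rbind, rows))
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("structure_graph: %d nodes, root %d, %d leaves\n",
              length(x$nodes), x$root, length(graph_leaves(x))))
  invisible(x)
}

graph_ids <- function(graph) as.integer(names(graph$nodes))

#' Leaf ids (nodes without children) of a structure graph
#' @param graph a `structure_graph`.
#' @export
graph_leaves <- function(graph) {
  ids <- graph_ids(graph)
  ids[vapply(graph$nodes, function(n) length(n$children) == 0L, logical(1))]
}

check_id <- function(graph, id) {
  if (!as.character(id) %in% names(graph$nodes))
    af_stop("unknown structure id %s", id)
  invisible(TRUE)
}

#' Transitive descendants of a node
#'
#' @param graph a `structure_graph`.
#' @param id region id present in the graph.
#' @return sorted integer vector of descendant ids, excluding `id` itself.
#' @export
descendants <- function(graph, id) {
  check_id(graph, id)
  out <- integer(0)
  queue <- graph$nodes[[as.character(id)]]$children
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    out <- c(out, cur)
    queue <- c(queue, graph$nodes[[as.character(cur)]]$children)
  }
  sort(out)
}

#' Chain of ancestors from a node's parent up to the root
#' @param graph a `structure_graph`.
#' @param id region id.
#' @export
ancestors <- function(graph, id) {
  check_id(graph, id)
  out <- integer(0)
  cur <- graph$nodes[[as.character(id)]]$parent
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- graph$nodes[[as.character(cur)]]$parent
  }
  out
}

#' Voxel count per label id in an annotation volume
#' @noRd
label_counts <- function(ann) {
  v <- as.vector(ann$data)
  v <- v[v != 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Descendant-aggregated voxel support of a region in an annotation
#' @noRd
region_support <- function(counts, graph, id) {
  ids <- c(id, descendants(graph, id))
  sum(counts[as.character(ids)], na.rm = TRUE)
}

#' Leaves annotated in both annotation volumes
#'
#' A leaf is directly comparable between two annotation versions when a
#' non-empty set of voxels carries its exact label in both volumes. Labels
#' present in a volume but absent from the graph are reported with a warning
#' and otherwise ignored.
#'
#' @param graph a `structure_graph`.
#' @param annA,annB [labeled_volume()]s using ids from `graph`.
#' @return sorted integer vector of comparable leaf ids.
#' @export
comparable_leaves <- function(graph, annA, annB) {
  ca <- label_counts(annA)
  cb <- label_counts(annB)
  known <- as.character(graph_ids(graph))
  stray <- setdiff(union(names(ca), names(cb)), known)
  if (length(stray))
    af_warn("labels not in structure graph: %s", paste(stray, collapse = ", "))
  leaves <- graph_leaves(graph)
  keep <- vapply(leaves, function(id) {
    k <- as.character(id)
    isTRUE(ca[k] > 0) && isTRUE(cb[k] > 0)
  }, logical(1))
  sort(leaves[keep])
}

#' Two-level (leaf / parent) registration assignment
#'
#' Leaves annotated in both volumes are registered at leaf level. Every other
#' leaf with voxel support in either volume is assigned, by walking strictly
#' rootward from its parent, to the first ancestor whose descendant-aggregated
#' support (the ancestor's own voxels count too) is non-empty in both volumes.
#'
#' @param graph a `structure_graph`.
#' @param annA,annB [labeled_volume()]s.
#' @return object of class `level_assignment`: list with `leaf_ids` (integer
#'   vector) and `parent_map` (named integer vector, leaf id -> parent id).
#' @export
assign_levels <- function(graph, annA, annB) {
  ca <- label_counts(annA)
  cb <- label_counts(annB)
  shared <- comparable_leaves(graph, annA, annB)
  leaves <- sort(graph_leaves(graph))
  parent_map <- integer(0)
  for (id in setdiff(leaves, shared)) {
    k <- as.character(id)
    if (!isTRUE(ca[k] > 0) && !isTRUE(cb[k] > 0)) next  # no support anywhere
    assigned <- NA_integer_
    for (anc in ancestors(graph, id)) {
      if (region_support(ca, graph, anc) > 0 && region_support(cb, graph, anc) > 0) {
        assigned <- anc
        break
      }
    }
    if (is.na(assigned))
      af_stop("no ancestor of region %d has support in both volumes", id)
    parent_map[k] <- assigned
  }
  structure(list(leaf_ids = shared, parent_map = parent_map),
            class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat(sprintf("level_assignment: %d leaf-level regions, %d parent-mapped\n",
              length(x$leaf_ids), length(x$parent_map)))
  invisible(x)
}

#' Binary mask of a region in an annotation volume
#'
#' @param ann a [labeled_volume()].
#' @param graph a `structure_graph`.
#' @param id region id.
#' @param include_descendants also include voxels labeled with any descendant.
#' @return logical 3D array on the grid of `ann`.
#' @export
region_mask <- function(ann, graph, id, include_descendants = FALSE) {
  check_id(graph, id)
  ids <- if (include_descendants) c(id, descendants(graph, id)) else id
  array(ann$data %in% ids, dim(ann$data))
}
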