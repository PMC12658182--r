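# Newick serialization of clone trees with edge-gain annotations.

.nwk_sanitize <- function(x) gsub("[\\s;:,()\\[\\]']", "_", x, perl = TRUE)

#' Write a clone tree as Newick
#'
#' Node labels are the clone ids attached at each node (joined by `+`) or
#' `ancN` for inferred ancestors; when `annotations = TRUE` the events gained
#' on the edge into each node are appended in a comment block
#' `[&events=e1|e2]`, which standard Newick readers skip or strip. Children
#' are ordered lexicographically by label, so output is deterministic.
#'
#' @param tree A `clone_tree`.
#' @param path Optional file path (`.nwk`); the string is returned either
#'   way.
#' @param annotations Include `[&events=...]` comment blocks. Default `TRUE`.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, annotations = TRUE) {
  stopifnot(inherits(tree, "clone_tree"))
  lab <- setNames(.nwk_sanitize(tree$nodes$label), tree$nodes$node_id)
  edge_events <- setNames(tree$edges$events, tree$edges$child)
  rec <- function(nd) {
    ch <- tree$edges$child[tree$edges$parent == nd]
    ch <- ch[order(lab[ch])]
    core <- if (length(ch)) {
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab[[nd]])
    } else {
      lab[[nd]]
    }
    ann <- ""
    if (annotations && nd %in% names(edge_events) && length(edge_events[[nd]])) {
      ann <- sprintf("[&events=%s]", paste(edge_events[[nd]], collapse = "|"))
    }
    paste0(core, ann)
  }
  nwk <- paste0(rec(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Strip Newick comment blocks
#'
#' Removes `[...]` comment blocks (as used by [write_newick()] for edge
#' annotations) so the string can be handed to any plain Newick parser.
#'
#' @param nwk A Newick string.
#' @return The string without comments.
#' @export
strip_newick_comments <- function(nwk) gsub("\\[[^]]*\\]", "", nwk)

#' Write a clone tree as Graphviz DOT
#'
#' @param tree A `clone_tree`.
#' @param path Optional output path.
#' @return The DOT source, invisibly when `path` is given.
#' @export
write_dot <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  lab <- setNames(tree$nodes$label, tree$nodes$node_id)
  lines <- c("digraph clone_tree {", "  node [shape=box];")
  for (i in seq_len(nrow(tree$nodes))) {
    lines <- c(lines, sprintf('  "%s";', lab[[tree$nodes$node_id[i]]]))
  }
  for (i in seq_len(nrow(tree$edges))) {
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              lab[[tree$edges$parent[i]]], lab[[tree$edges$child[i]]],
                              paste(tree$edges$events[[i]], collapse = "\\n")))
  }
  lines <- c(lines, "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Serialize a clone tree as JSON
#'
#' Full tree with node labels, attached clone ids and edge event
#' annotations.
#'
#' @param tree A `clone_tree`.
#' @param path Optional output path.
#' @return The JSON string, invisibly when `path` is given.
#' @export
write_tree_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  lab <- setNames(tree$nodes$label, tree$nodes$node_id)
  payload <- list(
    root = unname(lab[[tree$root]]),
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      list(label = tree$nodes$label[i],
           clones = as.list(tree$nodes$clone_ids[[i]]),
           events_path = as.list(tree$nodes$events_path[[i]]))
    }),
    edges = lapply(seq_len(nrow(tree$edges)), function(i) {
      list(parent = unname(lab[[tree$edges$parent[i]]]),
           child = unname(lab[[tree$edges$child[i]]]),
           events = as.list(tree$edges$events[[i]]))
    })
  )
  out <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(as.character(out)))
  }
  as.character(out)
}
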