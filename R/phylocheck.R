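# Perfect-phylogeny check over clone genotypes and clone-tree construction.
#
# Under the no-new-mutation model every event arises once and is never lost,
# so the sets of clones carrying any two events must be nested or disjoint
# (a laminar family). When they are, the containment order of carrier sets
# *is* the tree: each distinct carrier set becomes a node, an event labels
# the edge into the node where it is gained, and each clone attaches at the
# node whose root path carries exactly its genotype.

# crossing test: returns NULL or c(i, j) column indices of a crossing pair
.find_crossing <- function(M) {
  cs <- colSums(M)
  keep <- which(cs > 0)
  if (length(keep) < 2) return(NULL)
  Mk <- M[, keep, drop = FALSE]
  csk <- cs[keep]
  C11 <- crossprod(Mk)              # shared carriers
  D <- csk - C11                    # carriers of i not j (column-recycled)
  bad <- C11 > 0 & D > 0 & t(D) > 0
  if (!any(bad)) return(NULL)
  hit <- which(bad, arr.ind = TRUE)[1, ]
  keep[sort(hit)]
}

#' Check that clone genotypes admit a perfect phylogeny
#'
#' Succeeds iff the event-carrier sets over the clones form a laminar family
#' (nested or disjoint for every event pair). On success returns the rooted
#' clone tree whose edges are labelled with gained events, rooted at the
#' event-free ancestor; on failure returns an incompatibility certificate
#' naming two events with crossing carrier sets.
#'
#' @param clones Logical matrix of genotypes (rows = clones, columns named by
#'   event id). Rownames are used as clone ids (defaults `C1..Ck`).
#' @param collapse Collapse ancestor nodes that have one child and no
#'   attached clone into the child edge, so internal nodes mark true
#'   branch points (or clones). Default `TRUE`.
#' @return On success a `clone_tree`; on failure an object of class
#'   `phylo_incompatibility` with element `certificate` = the two crossing
#'   event ids. Use [is_compatible()] to discriminate.
#' @export
check_phylogeny <- function(clones, collapse = TRUE) {
  clones <- as.matrix(clones)
  storage.mode(clones) <- "logical"
  if (is.null(rownames(clones))) rownames(clones) <- paste0("C", seq_len(nrow(clones)))
  cross <- .find_crossing(clones)
  if (!is.null(cross)) {
    return(structure(list(certificate = colnames(clones)[cross]),
                     class = "phylo_incompatibility"))
  }
  build_clone_tree(clones, collapse = collapse)
}

#' @export
print.phylo_incompatibility <- function(x, ...) {
  cat(sprintf("<phylo_incompatibility> crossing carrier sets: %s x %s\n",
              x$certificate[1], x$certificate[2]))
  invisible(x)
}

#' Is a phylogeny check result compatible?
#'
#' @param x Result of [check_phylogeny()].
#' @return `TRUE` for a `clone_tree`, `FALSE` for an incompatibility.
#' @export
is_compatible <- function(x) inherits(x, "clone_tree")

# Build the containment tree from a laminar genotype matrix.
# Returns a clone_tree: list(nodes, edges, root).
build_clone_tree <- function(clones, collapse = TRUE) {
  clones <- as.matrix(clones)
  storage.mode(clones) <- "logical"
  if (is.null(rownames(clones))) rownames(clones) <- paste0("C", seq_len(nrow(clones)))
  cids <- rownames(clones)
  eids <- colnames(clones)
  carried <- which(colSums(clones) > 0)

  # group events by identical carrier sets; each class is one tree node
  ckey <- vapply(carried, function(j) genotype_key(clones[, j]), character(1))
  classes <- split(carried, ckey)
  sizes <- vapply(classes, function(js) sum(clones[, js[1]]), integer(1))
  ord <- order(-sizes, names(classes))
  classes <- classes[ord]; sizes <- sizes[ord]
  ckeys <- names(classes)
  ncls <- length(classes)

  carrier_sets <- lapply(classes, function(js) which(clones[, js[1]]))

  # parent of class i = the smallest strict superset (unique under laminarity;
  # equal-size containment would mean an identical carrier set, i.e. the same
  # class, so strict supersets are exactly the larger containing classes)
  parent <- integer(ncls)  # 0 = root
  for (i in seq_len(ncls)) {
    parent[i] <- 0L
    best <- Inf
    for (j in seq_len(ncls)) {
      if (j == i || sizes[j] <= sizes[i]) next
      if (sizes[j] < best && all(carrier_sets[[i]] %in% carrier_sets[[j]])) {
        parent[i] <- j; best <- sizes[j]
      }
    }
  }

  # attach clones: deepest class containing the clone (classes containing a
  # clone form a chain); event-free clones sit at the root
  attach_at <- integer(length(cids))  # 0 = root
  for (c in seq_along(cids)) {
    containing <- which(vapply(carrier_sets, function(s) c %in% s, logical(1)))
    if (length(containing) == 0) { attach_at[c] <- 0L; next }
    attach_at[c] <- containing[which.min(sizes[containing])]
  }

  node_id <- c("root", paste0("n", seq_len(ncls)))
  nodes <- tibble(
    node_id = node_id,
    clone_ids = c(list(cids[attach_at == 0L]),
                  lapply(seq_len(ncls), function(i) cids[attach_at == i])),
    events_path = c(list(character(0)), lapply(seq_len(ncls), function(i) {
      path <- character(0); j <- i
      while (j != 0L) { path <- c(sort(eids[classes[[j]]]), path); j <- parent[j] }
      path
    }))
  )
  edges <- tibble(
    parent = node_id[parent + 1L],
    child = node_id[seq_len(ncls) + 1L],
    events = unname(lapply(classes, function(js) sort(eids[js])))
  )

  tree <- structure(list(nodes = nodes, edges = edges, root = "root",
                         events = eids, genotypes = clones),
                    class = "clone_tree")
  if (collapse) tree <- .collapse_unary(tree)
  .relabel_tree(tree)
}

# merge ancestor nodes with exactly one child and no attached clones into the
# child edge (event labels concatenate root-to-leaf)
.collapse_unary <- function(tree) {
  repeat {
    kids <- table(tree$edges$parent)
    nclones <- vapply(tree$nodes$clone_ids, length, integer(1))
    names(nclones) <- tree$nodes$node_id
    drop <- NULL
    for (nd in tree$nodes$node_id) {
      if (nd == tree$root) next
      if (nclones[[nd]] == 0 && !is.na(kids[nd]) && kids[nd] == 1) { drop <- nd; break }
    }
    if (is.null(drop)) break
    ein <- which(tree$edges$child == drop)
    eout <- which(tree$edges$parent == drop)
    tree$edges$events[[eout]] <- c(tree$edges$events[[ein]], tree$edges$events[[eout]])
    tree$edges$parent[eout] <- tree$edges$parent[ein]
    tree$edges <- tree$edges[-ein, , drop = FALSE]
    tree$nodes <- tree$nodes[tree$nodes$node_id != drop, , drop = FALSE]
  }
  tree
}

# deterministic node labels: clone ids joined by '+', or anc1..ancN for
# inferred ancestors, numbered in depth-first lexicographic order
.relabel_tree <- function(tree) {
  lab <- character(nrow(tree$nodes))
  names(lab) <- tree$nodes$node_id
  for (i in seq_len(nrow(tree$nodes))) {
    ids <- tree$nodes$clone_ids[[i]]
    lab[i] <- if (length(ids)) paste(sort(ids), collapse = "+") else NA_character_
  }
  # depth-first order from root, children sorted by (label, node_id)
  counter <- 0L
  visit <- function(nd) {
    if (is.na(lab[[nd]])) {
      counter <<- counter + 1L
      lab[[nd]] <<- if (nd == tree$root) "root" else paste0("anc", counter)
    }
    ch <- tree$edges$child[tree$edges$parent == nd]
    for (c in ch[order(ifelse(is.na(lab[ch]), ch, lab[ch]))]) visit(c)
  }
  if (is.na(lab[[tree$root]])) { } # root labelled in visit
  visit(tree$root)
  tree$nodes$label <- unname(lab[tree$nodes$node_id])
  tree
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d nodes, %d edges, %d events, root '%s'\n",
              nrow(x$nodes), nrow(x$edges), length(x$events),
              x$nodes$label[x$nodes$node_id == x$root]))
  invisible(x)
}

#' Edge table of a clone tree
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return Tibble with one row per edge: parent and child labels and the
#'   events gained on the edge (pipe-separated).
#' @export
tidy.clone_tree <- function(x, ...) {
  lab <- setNames(x$nodes$label, x$nodes$node_id)
  tibble(
    parent = unname(lab[x$edges$parent]),
    child = unname(lab[x$edges$child]),
    events = vapply(x$edges$events, paste, character(1), collapse = "|"),
    n_events = vapply(x$edges$events, length, integer(1))
  )
}
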