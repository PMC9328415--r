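# Structure-changing operations. reroot() and prune_leaves() modify the tree
# in place (trees have reference semantics); extract_tree_with() copies.

# find the unique node (leaf or internal) carrying a label
.node_by_label <- function(root, label) {
  hits <- list()
  it <- .stack_new(root)
  while (!is.null(u <- .stack_pop_push_children(it))) {
    if (!is.null(u$label) && identical(u$label, label))
      hits[[length(hits) + 1L]] <- u
  }
  if (length(hits) == 0L)
    stop_lookup(sprintf("no node with label \"%s\"", label))
  if (length(hits) > 1L)
    stop_lookup(sprintf("label \"%s\" is not unique (%d nodes)", label,
                        length(hits)))
  hits[[1L]]
}

# NULL-aware branch-length addition: absent + absent stays absent, otherwise
# absent counts 0
.add_len <- function(a, b) {
  if (is.null(a) && is.null(b)) return(NULL)
  (if (is.null(a)) 0 else a) + (if (is.null(b)) 0 else b)
}

.remove_child <- function(parent, child) {
  keep <- !vapply(parent$children, identical, logical(1), y = child)
  parent$children <- parent$children[keep]
}

.replace_child <- function(parent, old, new) {
  for (i in seq_along(parent$children)) {
    if (identical(parent$children[[i]], old)) {
      parent$children[[i]] <- new
      return(invisible(NULL))
    }
  }
  stop_structure("child not found under parent")
}

# merge a unifurcation: u has exactly one child; u disappears, its edge length
# is added onto the child's
.suppress_one <- function(u, tr) {
  k <- u$children[[1L]]
  k$edge_length <- .add_len(u$edge_length, k$edge_length)
  p <- u$parent
  if (is.null(p)) {
    k$parent <- NULL
    u$children <- list()
    tr$root <- k
  } else {
    .replace_child(p, u, k)
    k$parent <- p
    u$parent <- NULL
    u$children <- list()
  }
}

#' Remove unifurcations
#'
#' Deletes every internal node with exactly one child, adding its edge length
#' onto its child's, repeatedly until none remain (a root left with a single
#' child is replaced by that child). Root-to-leaf distances and the leaf set
#' are unchanged. Operates in place.
#'
#' @param tree A `treekit_tree`.
#' @return `tree`, invisibly.
#' @export
suppress_unifurcations <- function(tree) {
  nodes <- .postorder_nodes(tree$root)
  for (u in nodes) {
    if (length(u$children) == 1L && !identical(u, tree$root))
      .suppress_one(u, tree)
  }
  while (length(tree$root$children) == 1L)
    .suppress_one(tree$root, tree)
  invisible(tree)
}

#' Reroot a tree
#'
#' Makes `node` the new root by reversing every edge on the path from `node`
#' to the old root, preserving each edge's length; the old root's stored root
#' edge (if any) moves to the new root, so the total branch length is exactly
#' conserved, and leaf-to-leaf patristic distances are invariant. If
#' `length_along_edge` is given, a new root node is first created on `node`'s
#' parent edge, splitting it with `length_along_edge` on `node`'s side and
#' the remainder on the old-parent side. An old root left with a single child
#' afterwards is suppressed. Operates in place.
#'
#' @param tree A `treekit_tree`.
#' @param node A `tree_node` belonging to `tree`, or a leaf label.
#' @param length_along_edge Optional split point; requires `node` to have a
#'   parent edge with a stored length, and `0 <= length_along_edge <=` that
#'   length.
#' @return `tree`, invisibly.
#' @export
reroot <- function(tree, node, length_along_edge = NULL) {
  if (is.character(node)) node <- .node_by_label(tree$root, node)
  # membership check
  u <- node
  while (!is.null(u$parent)) u <- u$parent
  if (!identical(u, tree$root))
    stop_structure("`node` does not belong to `tree`")

  if (!is.null(length_along_edge)) {
    if (is.null(node$parent))
      stop_invalid_value("`length_along_edge` requires `node` to have a parent")
    el <- node$edge_length
    if (is.null(el))
      stop_invalid_value("`node`'s parent edge has no stored length to split")
    if (!is.numeric(length_along_edge) || length(length_along_edge) != 1L ||
        is.na(length_along_edge) || length_along_edge < 0 ||
        length_along_edge > el)
      stop_invalid_value(sprintf(
        "`length_along_edge` must lie in [0, %g]", el))
    w <- .bare_node()
    p <- node$parent
    .replace_child(p, node, w)
    w$parent <- p
    w$edge_length <- el - length_along_edge
    w$children <- list(node)
    node$parent <- w
    node$edge_length <- length_along_edge
    node <- w
  }

  old_root <- tree$root
  if (identical(node, old_root)) return(invisible(tree))

  path <- list()
  u <- node
  while (!is.null(u)) {
    path[[length(path) + 1L]] <- u
    u <- u$parent
  }
  k <- length(path)
  lens <- lapply(path, function(x) x$edge_length)
  root_edge <- old_root$edge_length

  for (i in seq_len(k - 1L)) .remove_child(path[[i + 1L]], path[[i]])
  for (i in seq_len(k - 1L)) {
    child <- path[[i + 1L]]
    par <- path[[i]]
    par$children[[length(par$children) + 1L]] <- child
    child$parent <- par
    child$edge_length <- lens[[i]]   # reversed edge keeps its length
  }
  node$parent <- NULL
  node$edge_length <- root_edge
  tree$root <- node

  if (length(old_root$children) == 1L) {
    .suppress_one(old_root, tree)
  } else if (length(old_root$children) == 0L && is.null(old_root$label)) {
    # a childless, unlabeled former root carries no information
    .remove_child(old_root$parent, old_root)
  }
  invisible(tree)
}

#' Extract the subtree induced on a set of leaves
#'
#' Returns a new tree containing exactly the named leaves: the minimal
#' spanning topology of the original tree restricted to them, with
#' unifurcations suppressed and edge lengths summed along collapsed paths,
#' so pairwise patristic distances among the retained leaves are exactly
#' those of the original tree. The original tree is untouched.
#'
#' @param tree A `treekit_tree`.
#' @param leaf_labels Character vector of leaf labels to keep (must exist and
#'   be unique among leaves).
#' @return A new `treekit_tree`.
#' @export
extract_tree_with <- function(tree, leaf_labels) {
  root <- .as_root(tree)
  keep_leaves <- .leaf_lookup(root, unique(leaf_labels))
  marked <- list()
  for (lf in keep_leaves) {
    u <- lf
    while (!is.null(u) && is.null(u$.kp)) {
      u$.kp <- TRUE
      marked[[length(marked) + 1L]] <- u
      u <- u$parent
    }
  }
  on.exit(for (u in marked) rm(".kp", envir = u))

  copy_of <- function(u) {
    v <- .bare_node()
    v$label <- u$label
    v$edge_length <- u$edge_length
    v$attributes <- u$attributes
    v
  }
  new_root <- copy_of(root)
  stack_src <- list(root)
  stack_dst <- list(new_root)
  while (length(stack_src)) {
    n <- length(stack_src)
    u <- stack_src[[n]]; v <- stack_dst[[n]]
    stack_src[[n]] <- NULL; stack_dst[[n]] <- NULL
    for (kchild in u$children) {
      if (is.null(kchild$.kp)) next
      vc <- copy_of(kchild)
      vc$parent <- v
      v$children[[length(v$children) + 1L]] <- vc
      stack_src[[length(stack_src) + 1L]] <- kchild
      stack_dst[[length(stack_dst) + 1L]] <- vc
    }
  }
  out <- tree(new_root, is_rooted = if (is_treekit_tree(tree)) tree$is_rooted else TRUE)
  suppress_unifurcations(out)
  out
}

#' Prune leaves from a tree
#'
#' Removes the named leaves in place, deletes internal nodes left with no
#' leaf descendants, and suppresses the resulting unifurcations. This is the
#' complement of [extract_tree_with()] on the leaf set.
#'
#' @param tree A `treekit_tree`.
#' @param leaf_labels Character vector of leaf labels to remove; pruning
#'   every leaf is an error.
#' @return `tree`, invisibly.
#' @export
prune_leaves <- function(tree, leaf_labels) {
  leaf_labels <- unique(leaf_labels)
  if (length(leaf_labels) == 0L) return(invisible(tree))
  targets <- .leaf_lookup(tree$root, leaf_labels)
  n_leaves <- num_nodes(tree)[["leaves"]]
  if (length(targets) >= n_leaves)
    stop_structure("cannot prune every leaf of the tree")
  for (lf in targets) {
    u <- lf
    repeat {
      p <- u$parent
      if (is.null(p)) break  # unreachable: not all leaves are pruned
      .remove_child(p, u)
      u$parent <- NULL
      if (length(p$children) > 0L) break
      u <- p  # parent lost all its leaf descendants; remove it too
    }
  }
  suppress_unifurcations(tree)
  invisible(tree)
}
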