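#' Create a tree node
#'
#' A node is one vertex of a tree. It carries an optional `label`, an optional
#' non-negative `edge_length` (the length of the branch connecting it to its
#' parent; units are whatever the source data used), a reference to its parent,
#' an ordered list of children, and a free-form attribute list used to retain
#' annotations such as Newick comments. Nodes have reference semantics: they
#' are environments, so `add_child()` and `detach_node()` modify them in place.
#'
#' @param label Optional character scalar. `NULL` means unlabeled.
#' @param edge_length Optional non-negative numeric scalar. `NULL` means the
#'   branch length is missing (distinct from zero: missing lengths round-trip
#'   as absent, but count as 0 in all distance computations).
#' @return A `tree_node` object: a parentless, childless node.
#' @examples
#' a <- new_node("A", 1.0)
#' is_leaf(a)
#' @seealso [add_child()], [detach_node()], [tree()]
#' @export
new_node <- function(label = NULL, edge_length = NULL) {
  if (!is.null(label)) {
    if (!is.character(label) || length(label) != 1L || is.na(label))
      stop_invalid_value("`label` must be NULL or a single character string")
  }
  if (!is.null(edge_length)) {
    if (!is.numeric(edge_length) || length(edge_length) != 1L ||
        is.na(edge_length))
      stop_invalid_value("`edge_length` must be NULL or a single number")
    edge_length <- as.numeric(edge_length)
    if (edge_length < 0)
      stop_invalid_value(sprintf("`edge_length` must be >= 0, got %g",
                                 edge_length))
  }
  u <- new.env(parent = emptyenv(), size = 8L)
  u$label <- label
  u$edge_length <- edge_length
  u$parent <- NULL
  u$children <- list()
  u$attributes <- list()
  class(u) <- "tree_node"
  u
}

# Bare node for hot loops (parser, generator): skips validation and class cost
# is the same, but avoids argument checks.
.bare_node <- function() {
  u <- new.env(parent = emptyenv(), size = 8L)
  u$label <- NULL
  u$edge_length <- NULL
  u$parent <- NULL
  u$children <- list()
  u$attributes <- list()
  class(u) <- "tree_node"
  u
}

is_tree_node <- function(x) inherits(x, "tree_node")

#' Node predicates and accessors
#'
#' @param node A `tree_node`.
#' @return `is_leaf()`: `TRUE` if the node has no children. `is_root_node()`:
#'   `TRUE` if it has no parent. `num_children()`: integer child count.
#'   `node_label()`, `node_edge_length()`: the stored field (`NULL` if absent).
#'   `node_children()`: the ordered list of child nodes. `node_parent()`: the
#'   parent node or `NULL`.
#' @export
is_leaf <- function(node) length(node$children) == 0L

#' @rdname is_leaf
#' @export
is_root_node <- function(node) is.null(node$parent)

#' @rdname is_leaf
#' @export
num_children <- function(node) length(node$children)

#' @rdname is_leaf
#' @export
node_label <- function(node) node$label

#' @rdname is_leaf
#' @export
node_edge_length <- function(node) node$edge_length

#' @rdname is_leaf
#' @export
node_children <- function(node) node$children

#' @rdname is_leaf
#' @export
node_parent <- function(node) node$parent

.is_ancestor_of <- function(anc, node) {
  u <- node
  while (!is.null(u)) {
    if (identical(u, anc)) return(TRUE)
    u <- u$parent
  }
  FALSE
}

#' Attach a child node
#'
#' Appends `child` to `parent`'s ordered child list and sets `child`'s parent
#' link, in place. Children keep insertion order in every traversal and in
#' Newick output.
#'
#' @param parent,child `tree_node` objects. `child` must currently have no
#'   parent and must not be an ancestor of `parent` (no cycles).
#' @return `parent`, invisibly.
#' @export
add_child <- function(parent, child) {
  if (!is_tree_node(parent) || !is_tree_node(child))
    stop_invalid_value("`parent` and `child` must be tree_node objects")
  if (!is.null(child$parent))
    stop_structure("`child` already has a parent; detach_node() it first")
  if (.is_ancestor_of(child, parent))
    stop_structure("attaching `child` would create a cycle (it is an ancestor of `parent`)")
  parent$children[[length(parent$children) + 1L]] <- child
  child$parent <- parent
  invisible(parent)
}

#' Detach a node from its parent
#'
#' Removes `node` from its parent's child list and clears its parent link, in
#' place. The node (with its whole subtree) becomes a free-standing root and is
#' returned; the remaining tree stays valid.
#'
#' @param node A `tree_node` with a parent. Detaching a root is an error.
#' @return `node`, now parentless.
#' @export
detach_node <- function(node) {
  p <- node$parent
  if (is.null(p))
    stop_structure("cannot detach a root node (it has no parent)")
  keep <- !vapply(p$children, identical, logical(1), y = node)
  p$children <- p$children[keep]
  node$parent <- NULL
  node
}

#' Wrap a root node as a tree
#'
#' The tree is the traversal/manipulation handle: a root node plus a
#' rootedness flag (taken from `[&R]`/`[&U]` hints when parsing; trees are
#' rooted by default). Like nodes, trees have reference semantics.
#'
#' @param root A `tree_node` with no parent.
#' @param is_rooted Logical flag, default `TRUE`.
#' @return A `treekit_tree` object.
#' @examples
#' tr <- tree(new_node("A"))
#' num_nodes(tr)
#' @export
tree <- function(root, is_rooted = TRUE) {
  if (!is_tree_node(root))
    stop_invalid_value("`root` must be a tree_node")
  if (!is.null(root$parent))
    stop_structure("`root` must not have a parent")
  t <- new.env(parent = emptyenv(), size = 4L)
  t$root <- root
  t$is_rooted <- isTRUE(is_rooted)
  class(t) <- "treekit_tree"
  t
}

is_treekit_tree <- function(x) inherits(x, "treekit_tree")

.as_root <- function(x) {
  if (is_treekit_tree(x)) x$root
  else if (is_tree_node(x)) x
  else stop_invalid_value("expected a treekit_tree or tree_node")
}

#' Count nodes
#'
#' Full iterative traversal counting all nodes, leaves, and internal nodes.
#'
#' @param tree A `treekit_tree` (or a bare `tree_node` treated as a root).
#' @return Named integer vector with elements `total`, `leaves`, `internal`;
#'   `total == leaves + internal` always.
#' @export
num_nodes <- function(tree) {
  total <- 0L; leaves <- 0L
  it <- .stack_new(.as_root(tree))
  while (!is.null(u <- .stack_pop_push_children(it))) {
    total <- total + 1L
    if (length(u$children) == 0L) leaves <- leaves + 1L
  }
  c(total = total, leaves = leaves, internal = total - leaves)
}

#' @export
print.tree_node <- function(x, ...) {
  lab <- if (is.null(x$label)) "<unlabeled>" else x$label
  len <- if (is.null(x$edge_length)) "missing" else format(x$edge_length)
  cat(sprintf("<tree_node %s: edge_length=%s, children=%d%s>\n",
              lab, len, length(x$children),
              if (is.null(x$parent)) ", root" else ""))
  invisible(x)
}

#' @export
print.treekit_tree <- function(x, ...) {
  n <- num_nodes(x)
  cat(sprintf("<treekit_tree: %d nodes (%d leaves, %d internal), %s>\n",
              n[["total"]], n[["leaves"]], n[["internal"]],
              if (x$is_rooted) "rooted" else "unrooted"))
  invisible(x)
}

# ---- structural validation (used by tests and after manipulations) ----

#' Check structural invariants of a tree
#'
#' Scans the whole tree and verifies that parent/child links are mutually
#' consistent, that the root is parentless, and that every node is reached
#' exactly once (connected, acyclic). Errors with a structure condition on the
#' first violation.
#'
#' @param tree A `treekit_tree`.
#' @return `TRUE`, invisibly, if all invariants hold.
#' @export
validate_tree <- function(tree) {
  root <- .as_root(tree)
  if (!is.null(root$parent)) stop_structure("root has a parent")
  n_claimed <- 0L
  it <- .stack_new(root)
  while (!is.null(u <- .stack_pop_push_children(it))) {
    n_claimed <- n_claimed + 1L
    for (k in u$children) {
      if (!identical(k$parent, u))
        stop_structure("child whose parent link does not point back")
    }
    if (n_claimed > 10e7) stop_structure("traversal did not terminate")
  }
  invisible(TRUE)
}

# ---- equality for testing: label-preserving isomorphism ----

# Canonical keys for every node of a tree, computed in one postorder pass and
# stored in a temporary `.ck` field on each node (the caller removes them).
# Keys encode leaf labels, topology, and edge lengths rounded to 12 significant
# digits (ordering aid only; the tolerance comparison happens pairwise).
.assign_canon_keys <- function(root) {
  nodes <- .postorder_nodes(root)
  for (u in nodes) {
    len_tag <- if (is.null(u$edge_length)) "" else
      paste0(":", formatC(u$edge_length, digits = 12, format = "g"))
    if (length(u$children) == 0L) {
      u$.ck <- paste0(if (is.null(u$label)) "\x01" else u$label, len_tag)
    } else {
      ck <- sort(vapply(u$children, function(k) k$.ck, character(1)))
      u$.ck <- paste0("(", paste(ck, collapse = ","), ")",
                      if (is.null(u$label)) "" else u$label, len_tag)
    }
  }
  nodes
}

#' Compare two trees up to label-preserving isomorphism
#'
#' Two trees are considered equal when there is a correspondence between their
#' nodes preserving labels and topology (child order is ignored) under which
#' corresponding edge lengths agree within relative tolerance `tol` (an absent
#' length only matches an absent length). This is the equality used throughout
#' the test suite; it is an explicit comparison, never object identity.
#'
#' @param a,b Trees (or root nodes).
#' @param tol Relative tolerance on edge lengths (default `1e-9`).
#' @return Logical scalar.
#' @export
trees_isomorphic <- function(a, b, tol = 1e-9) {
  ra <- .as_root(a); rb <- .as_root(b)
  na <- .assign_canon_keys(ra)
  nb <- .assign_canon_keys(rb)
  on.exit({
    for (u in na) if (exists(".ck", envir = u)) rm(".ck", envir = u)
    for (u in nb) if (exists(".ck", envir = u)) rm(".ck", envir = u)
  }, add = TRUE)
  eq_len <- function(x, y) {
    if (is.null(x) && is.null(y)) return(TRUE)
    if (is.null(x) || is.null(y)) return(FALSE)
    abs(x - y) <= tol * max(1, abs(x), abs(y))
  }
  walk <- list(list(ra, rb))
  while (length(walk)) {
    pr <- walk[[length(walk)]]; walk[[length(walk)]] <- NULL
    u <- pr[[1]]; v <- pr[[2]]
    if (!identical(u$label, v$label)) return(FALSE)
    if (!eq_len(u$edge_length, v$edge_length)) return(FALSE)
    cu <- u$children; cv <- v$children
    if (length(cu) != length(cv)) return(FALSE)
    if (length(cu)) {
      ku <- vapply(cu, function(k) k$.ck, character(1))
      kv <- vapply(cv, function(k) k$.ck, character(1))
      if (!identical(sort(ku), sort(kv))) return(FALSE)
      ou <- order(ku); ov <- order(kv)
      for (j in seq_along(ou))
        walk[[length(walk) + 1L]] <- list(cu[[ou[j]]], cv[[ov[j]]])
    }
  }
  TRUE
}

# ---- shared iterative stack helpers ----

.stack_new <- function(root) {
  e <- new.env(parent = emptyenv())
  e$s <- vector("list", 64L)
  e$s[[1L]] <- root
  e$top <- 1L
  e
}

# pop a node, push its children in reverse (so they pop in stored order)
.stack_pop_push_children <- function(e) {
  if (e$top == 0L) return(NULL)
  u <- e$s[[e$top]]
  e$top <- e$top - 1L
  ch <- u$children
  nc <- length(ch)
  if (nc) {
    need <- e$top + nc
    if (need > length(e$s)) length(e$s) <- max(need, 2L * length(e$s))
    for (j in nc:1) {
      e$top <- e$top + 1L
      e$s[[e$top]] <- ch[[j]]
    }
  }
  u
}
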