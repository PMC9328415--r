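# Iterative traversal engines. Everything here is recursion-free: a
# caterpillar tree with 10^5 internal nodes must traverse without touching R's
# call-stack limit, and the lazy iterators must be able to hand back the first
# few nodes of a million-leaf tree without visiting the rest.

# ---- eager list builders (internal workhorses for statistics etc.) ----

.preorder_nodes <- function(root) {
  out <- vector("list", 256L)
  n <- 0L
  it <- .stack_new(root)
  while (!is.null(u <- .stack_pop_push_children(it))) {
    n <- n + 1L
    if (n > length(out)) length(out) <- 2L * length(out)
    out[[n]] <- u
  }
  length(out) <- n
  out
}

.postorder_nodes <- function(root) {
  # preorder with children pushed in stored order, then reversed, equals
  # postorder with children expanded in stored order
  out <- vector("list", 256L)
  n <- 0L
  s <- vector("list", 64L)
  s[[1L]] <- root
  top <- 1L
  while (top > 0L) {
    u <- s[[top]]; top <- top - 1L
    n <- n + 1L
    if (n > length(out)) length(out) <- 2L * length(out)
    out[[n]] <- u
    ch <- u$children
    nc <- length(ch)
    if (nc) {
      if (top + nc > length(s)) length(s) <- max(top + nc, 2L * length(s))
      for (j in 1:nc) {          # stored order: pops right-to-left
        top <- top + 1L
        s[[top]] <- ch[[j]]
      }
    }
  }
  length(out) <- n
  out[n:1]
}

.levelorder_nodes <- function(root) {
  q <- vector("list", 256L)
  q[[1L]] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    u <- q[[head]]; head <- head + 1L
    ch <- u$children
    nc <- length(ch)
    if (nc) {
      if (tail + nc > length(q)) length(q) <- max(tail + nc, 2L * length(q))
      for (j in 1:nc) {
        tail <- tail + 1L
        q[[tail]] <- ch[[j]]
      }
    }
  }
  length(q) <- tail
  q
}

.inorder_nodes <- function(root) {
  # strictly binary (unary chains allowed: child before node); explicit
  # (node, state) stack, state 0 = expand left, 1 = emit node then right
  out <- vector("list", 256L); n <- 0L
  s_node <- vector("list", 64L); s_state <- integer(64L)
  s_node[[1L]] <- root; s_state[1L] <- 0L
  top <- 1L
  emit <- function(u) {
    n <<- n + 1L
    if (n > length(out)) length(out) <<- 2L * length(out)
    out[[n]] <<- u
  }
  while (top > 0L) {
    u <- s_node[[top]]; st <- s_state[top]
    nc <- length(u$children)
    if (nc > 2L)
      stop_topology(sprintf(
        "in-order traversal requires a binary tree; node %s has %d children",
        if (is.null(u$label)) "<unlabeled>" else u$label, nc))
    if (st == 0L) {
      s_state[top] <- 1L
      if (nc >= 1L) {
        top <- top + 1L
        if (top > length(s_node)) {
          length(s_node) <- 2L * length(s_node)
          length(s_state) <- length(s_node)
        }
        s_node[[top]] <- u$children[[1L]]
        s_state[top] <- 0L
      }
    } else {
      top <- top - 1L
      emit(u)
      if (nc == 2L) {
        top <- top + 1L
        if (top > length(s_node)) {
          length(s_node) <- 2L * length(s_node)
          length(s_state) <- length(s_node)
        }
        s_node[[top]] <- u$children[[2L]]
        s_state[top] <- 0L
      }
    }
  }
  length(out) <- n
  out
}

# weighted distance from root for every node, in preorder; missing lengths = 0
.preorder_depths <- function(root) {
  nodes <- .preorder_nodes(root)
  n <- length(nodes)
  depth <- numeric(n)
  for (i in seq_len(n)) nodes[[i]]$.rk <- i
  on.exit(for (u in nodes) rm(".rk", envir = u), add = TRUE)
  for (i in seq_len(n)) {
    u <- nodes[[i]]
    p <- u$parent
    if (is.null(p) || is.null(p$.rk)) {
      depth[i] <- 0  # the root's own stored edge lies above the root
    } else {
      el <- u$edge_length
      depth[i] <- depth[p$.rk] + if (is.null(el)) 0 else el
    }
  }
  list(nodes = nodes, depth = depth)
}

.rootdist_nodes <- function(root, ascending = TRUE) {
  pd <- .preorder_depths(root)
  ord <- order(if (ascending) pd$depth else -pd$depth)  # stable: preorder ties
  pd$nodes[ord]
}

.leaf_nodes <- function(root) {
  nodes <- .preorder_nodes(root)
  nodes[vapply(nodes, function(u) length(u$children) == 0L, logical(1))]
}

# ---- lazy iterators ----

.make_iterator <- function(step, order) {
  structure(step, class = "tree_iterator", order = order)
}

#' @export
print.tree_iterator <- function(x, ...) {
  cat(sprintf("<tree_iterator: %s order; call next_node() or as.list()>\n",
              attr(x, "order")))
  invisible(x)
}

#' Advance a traversal iterator
#'
#' @param it A `tree_iterator` as returned by the `traverse_*()` functions.
#' @return The next `tree_node`, or `NULL` when the traversal is exhausted.
#' @export
next_node <- function(it) it()

#' Collect the remaining nodes of an iterator into a list
#'
#' @param x A `tree_iterator`.
#' @param ... Unused.
#' @return List of `tree_node` objects in traversal order.
#' @export
as.list.tree_iterator <- function(x, ...) {
  out <- vector("list", 256L)
  n <- 0L
  while (!is.null(u <- x())) {
    n <- n + 1L
    if (n > length(out)) length(out) <- 2L * length(out)
    out[[n]] <- u
  }
  length(out) <- n
  out
}

#' Traverse the nodes of a tree
#'
#' Each `traverse_*()` function returns a lazy iterator over the nodes of the
#' tree; call [next_node()] repeatedly (or [as.list()] to drain it). Laziness
#' matters at scale: taking the first handful of nodes of a huge tree does
#' work proportional to the visited frontier only. All traversals are
#' iterative, so arbitrarily deep (caterpillar) trees are safe.
#'
#' Orders:
#' \describe{
#'   \item{pre-order}{node before its descendants, children in stored order.}
#'   \item{post-order}{node after all its descendants.}
#'   \item{in-order}{binary trees only: left subtree, node, right subtree
#'     (unary chains visit child before node); multifurcations raise an
#'     unsupported-topology error.}
#'   \item{level-order}{non-decreasing topological depth, left-to-right.}
#'   \item{root-distance order}{by weighted distance from the root (sum of
#'     edge lengths, missing lengths count 0), ascending or descending, ties
#'     broken by pre-order rank.}
#'   \item{leaves}{only the leaves, in the order pre-order reaches them.}
#' }
#'
#' @param tree A `treekit_tree` (or bare root `tree_node`).
#' @param ascending For `traverse_rootdistorder()`: smallest distance first?
#' @return A `tree_iterator`.
#' @examples
#' tr <- read_tree_newick("((A:1,B:3)X:1,C:1)R;")
#' vapply(as.list(traverse_preorder(tr)),
#'        function(u) u$label, character(1))
#' @export
traverse_preorder <- function(tree) {
  st <- .stack_new(.as_root(tree))
  .make_iterator(function() .stack_pop_push_children(st), "pre")
}

#' @rdname traverse_preorder
#' @export
traverse_postorder <- function(tree) {
  # lazy: descend to the leftmost unvisited leaf, emit on the way back up
  root <- .as_root(tree)
  s_node <- vector("list", 64L); s_child <- integer(64L)
  s_node[[1L]] <- root; s_child[1L] <- 0L
  top <- 1L
  step <- function() {
    while (top > 0L) {
      u <- s_node[[top]]
      ci <- s_child[top] + 1L
      if (ci <= length(u$children)) {
        s_child[top] <<- ci
        top <<- top + 1L
        if (top > length(s_node)) {
          length(s_node) <<- 2L * length(s_node)
          length(s_child) <<- length(s_node)
        }
        s_node[[top]] <<- u$children[[ci]]
        s_child[top] <<- 0L
      } else {
        top <<- top - 1L
        return(u)
      }
    }
    NULL
  }
  .make_iterator(step, "post")
}

#' @rdname traverse_preorder
#' @export
traverse_inorder <- function(tree) {
  nodes <- .inorder_nodes(.as_root(tree))  # topology check is eager
  i <- 0L
  .make_iterator(function() {
    if (i >= length(nodes)) return(NULL)
    i <<- i + 1L
    nodes[[i]]
  }, "in")
}

#' @rdname traverse_preorder
#' @export
traverse_levelorder <- function(tree) {
  q <- new.env(parent = emptyenv())
  q$buf <- vector("list", 64L)
  q$buf[[1L]] <- .as_root(tree)
  q$head <- 1L; q$tail <- 1L
  step <- function() {
    if (q$head > q$tail) return(NULL)
    u <- q$buf[[q$head]]
    q$head <- q$head + 1L
    ch <- u$children
    nc <- length(ch)
    if (nc) {
      if (q$tail + nc > length(q$buf))
        length(q$buf) <- max(q$tail + nc, 2L * length(q$buf))
      for (j in 1:nc) {
        q$tail <- q$tail + 1L
        q$buf[[q$tail]] <- ch[[j]]
      }
    }
    u
  }
  .make_iterator(step, "level")
}

#' @rdname traverse_preorder
#' @export
traverse_rootdistorder <- function(tree, ascending = TRUE) {
  nodes <- .rootdist_nodes(.as_root(tree), ascending = ascending)
  i <- 0L
  .make_iterator(function() {
    if (i >= length(nodes)) return(NULL)
    i <<- i + 1L
    nodes[[i]]
  }, if (ascending) "root-distance (ascending)" else "root-distance (descending)")
}

#' @rdname traverse_preorder
#' @export
traverse_leaves <- function(tree) {
  st <- .stack_new(.as_root(tree))
  step <- function() {
    while (!is.null(u <- .stack_pop_push_children(st))) {
      if (length(u$children) == 0L) return(u)
    }
    NULL
  }
  .make_iterator(step, "leaves")
}
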