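# Summary statistics. Missing edge lengths count as 0 wherever path sums are
# needed (height, patristic distances, gamma) but are EXCLUDED from
# avg_branch_length averages: an absent length is not evidence of a zero-length
# branch, while path arithmetic has to stay total.

#' Leaf labels of a tree
#'
#' @param tree A `treekit_tree`.
#' @return Character vector of leaf labels in pre-order; unlabeled leaves
#'   appear as `NA`.
#' @export
leaf_labels <- function(tree) {
  vapply(.leaf_nodes(.as_root(tree)),
         function(u) if (is.null(u$label)) NA_character_ else u$label,
         character(1))
}

# label -> leaf node lookup; errors on unknown labels and on ambiguity among
# the requested labels (leaf-label uniqueness is only enforced where labels
# are used as keys)
.leaf_lookup <- function(root, labels) {
  leaves <- .leaf_nodes(root)
  all_labs <- vapply(leaves, function(u)
    if (is.null(u$label)) NA_character_ else u$label, character(1))
  idx <- match(labels, all_labs)
  missing <- labels[is.na(idx)]
  if (length(missing))
    stop_lookup(sprintf("no leaf with label(s): %s",
                        paste(missing, collapse = ", ")))
  dup <- labels[labels %in% all_labs[duplicated(all_labs)]]
  if (length(dup))
    stop_lookup(sprintf("leaf label(s) not unique: %s",
                        paste(unique(dup), collapse = ", ")))
  leaves[idx]
}

#' Tree height
#'
#' The maximum over leaves of the root-to-leaf sum of edge lengths (missing
#' lengths count 0; the root's own stored edge, which lies above the root,
#' does not contribute).
#'
#' @param tree A `treekit_tree`.
#' @return Non-negative numeric scalar.
#' @examples
#' tree_height(read_tree_newick("((A:1,B:3)X:1,C:1)R;"))  # 4
#' @export
tree_height <- function(tree) {
  pd <- .preorder_depths(.as_root(tree))
  is_lf <- vapply(pd$nodes, function(u) length(u$children) == 0L, logical(1))
  max(pd$depth[is_lf])
}

#' Average branch length
#'
#' Arithmetic mean of the stored edge lengths of a class of branches:
#' `"all"`, `"internal"` (branches whose child end is an internal node,
#' including a stored root edge), or `"leaf"` (terminal branches). Branches
#' with no stored length are excluded from the mean.
#'
#' @param tree A `treekit_tree`.
#' @param which One of `"all"`, `"internal"`, `"leaf"`.
#' @return Numeric scalar; erroring when no branch of the class has a stored
#'   length.
#' @export
avg_branch_length <- function(tree, which = c("all", "internal", "leaf")) {
  which <- match.arg(which)
  nodes <- .preorder_nodes(.as_root(tree))
  vals <- numeric(0)
  for (u in nodes) {
    el <- u$edge_length
    if (is.null(el)) next
    child_is_leaf <- length(u$children) == 0L
    keep <- switch(which,
                   all = TRUE,
                   internal = !child_is_leaf,
                   leaf = child_is_leaf)
    if (keep) vals <- c(vals, el)
  }
  if (!length(vals))
    stop_undefined(sprintf(
      "no %s branch with a stored length; average is undefined", which))
  mean(vals)
}

# walk up from `node` to the root, returning list(nodes=, dist=) cumulative
# edge-length sums (missing = 0), starting at node itself with distance 0
.path_to_root <- function(node) {
  nodes <- list(node)
  dist <- 0
  u <- node
  d <- 0
  while (!is.null(u$parent)) {
    el <- u$edge_length
    d <- d + if (is.null(el)) 0 else el
    u <- u$parent
    nodes[[length(nodes) + 1L]] <- u
    dist <- c(dist, d)
  }
  list(nodes = nodes, dist = dist)
}

#' Patristic distance between two nodes
#'
#' Sum of edge lengths on the unique path between `u` and `v` (through their
#' most recent common ancestor); missing lengths count 0.
#'
#' @param tree A `treekit_tree` containing both nodes.
#' @param u,v `tree_node` objects, or leaf labels.
#' @return Non-negative numeric scalar.
#' @export
distance_between <- function(tree, u, v) {
  root <- .as_root(tree)
  resolve <- function(x) {
    if (is.character(x)) .leaf_lookup(root, x)[[1L]] else x
  }
  u <- resolve(u); v <- resolve(v)
  pu <- .path_to_root(u)
  pv <- .path_to_root(v)
  if (!identical(pu$nodes[[length(pu$nodes)]], root) ||
      !identical(pv$nodes[[length(pv$nodes)]], root))
    stop_structure("both nodes must belong to `tree`")
  if (identical(u, v)) return(0)
  # find the first node of v's path that lies on u's path
  for (j in seq_along(pv$nodes)) {
    for (i in seq_along(pu$nodes)) {
      if (identical(pv$nodes[[j]], pu$nodes[[i]]))
        return(pu$dist[i] + pv$dist[j])
    }
  }
  stop_structure("nodes do not share an ancestor")  # unreachable on valid trees
}

#' Most recent common ancestor of a set of leaves
#'
#' The deepest node that is an ancestor of (or equal to) every named leaf.
#'
#' @param tree A `treekit_tree`.
#' @param labels Character vector of leaf labels (at least one).
#' @return The MRCA `tree_node`.
#' @examples
#' tr <- read_tree_newick("((A,B)X,C)R;")
#' node_label(mrca(tr, c("A", "B")))  # "X"
#' @export
mrca <- function(tree, labels) {
  root <- .as_root(tree)
  if (!is.character(labels) || length(labels) < 1L)
    stop_invalid_value("`labels` must be a character vector of length >= 1")
  leaves <- .leaf_lookup(root, unique(labels))
  anc <- leaves[[1L]]
  if (length(leaves) > 1L) {
    for (b in leaves[-1L]) anc <- .pairwise_mrca(anc, b)
  }
  anc
}

.pairwise_mrca <- function(a, b) {
  pa <- .path_to_root(a)
  for (u in pa$nodes) u$.mk <- TRUE
  on.exit(for (u in pa$nodes) if (exists(".mk", envir = u)) rm(".mk", envir = u))
  u <- b
  while (!is.null(u)) {
    if (!is.null(u$.mk)) return(u)
    u <- u$parent
  }
  stop_structure("nodes do not share an ancestor")
}

#' All-pairs leaf distance matrix
#'
#' Patristic distances between every pair of leaves, computed in one
#' post-order pass that joins the leaf sets of each internal node's children
#' (never one MRCA query per pair), so the cost is the size of the output,
#' O(n^2), plus one traversal.
#'
#' @param tree A `treekit_tree` whose leaf labels are unique.
#' @return A symmetric numeric matrix with leaf labels as `dimnames`, zero
#'   diagonal; leaf order is the order post-order first reaches each leaf.
#' @examples
#' distance_matrix(read_tree_newick("(A:1,B:2);"))
#' @export
distance_matrix <- function(tree) {
  root <- .as_root(tree)
  leaves <- .leaf_nodes(root)
  labs <- vapply(leaves, function(u)
    if (is.null(u$label)) NA_character_ else u$label, character(1))
  if (anyNA(labs))
    stop_lookup("all leaves must be labeled to build a distance matrix")
  if (anyDuplicated(labs))
    stop_lookup(sprintf("duplicate leaf label(s): %s",
                        paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  n <- length(leaves)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  nodes <- .postorder_nodes(root)
  next_idx <- 0L
  on.exit(for (u in nodes) if (exists(".dm", envir = u)) rm(".dm", envir = u))
  for (u in nodes) {
    if (length(u$children) == 0L) {
      next_idx <- next_idx + 1L
      u$.dm <- list(idx = match(if (is.null(u$label)) NA else u$label, labs),
                    d = 0)
    } else {
      groups <- lapply(u$children, function(k) {
        g <- k$.dm
        rm(".dm", envir = k)
        el <- k$edge_length
        g$d <- g$d + if (is.null(el)) 0 else el
        g
      })
      if (length(groups) > 1L) {
        for (a in 1:(length(groups) - 1L)) {
          for (b in (a + 1L):length(groups)) {
            ga <- groups[[a]]; gb <- groups[[b]]
            block <- outer(ga$d, gb$d, `+`)
            D[ga$idx, gb$idx] <- block
            D[gb$idx, ga$idx] <- t(block)
          }
        }
      }
      u$.dm <- list(idx = unlist(lapply(groups, `[[`, "idx")),
                    d = unlist(lapply(groups, `[[`, "d")))
    }
  }
  D
}

#' Treeness
#'
#' The proportion of total tree length found on internal branches: sum of
#' internal-branch lengths divided by the sum of all stored branch lengths.
#' An internal branch is one whose child end is an internal node; a stored
#' root edge counts as internal (it is not a terminal branch).
#'
#' @param tree A `treekit_tree` with positive total branch length.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' treeness(read_tree_newick("((A:1,B:3)X:2,C:6)R;"))  # 2/12
#' @export
treeness <- function(tree) {
  nodes <- .preorder_nodes(.as_root(tree))
  tot <- 0; internal <- 0
  for (u in nodes) {
    el <- u$edge_length
    if (is.null(el)) next
    tot <- tot + el
    if (length(u$children) > 0L) internal <- internal + el
  }
  if (tot <= 0)
    stop_undefined("total stored branch length is zero; treeness is undefined")
  internal / tot
}

#' Total branch length
#'
#' Sum of all stored edge lengths (including a stored root edge); missing
#' lengths contribute 0.
#'
#' @param tree A `treekit_tree`.
#' @return Numeric scalar.
#' @export
total_branch_length <- function(tree) {
  nodes <- .preorder_nodes(.as_root(tree))
  tot <- 0
  for (u in nodes) {
    el <- u$edge_length
    if (!is.null(el)) tot <- tot + el
  }
  tot
}

#' Gamma statistic of an ultrametric tree
#'
#' Standardized summary of the internode intervals of an ultrametric tree,
#' measuring whether branching events concentrate early (negative) or late
#' (positive) relative to the pure-birth expectation. With `n` leaves, let
#' `g_k` (k = 2..n) be the time during which the tree has exactly `k`
#' lineages (`g_n` ends at the tips) and `T = sum_j j*g_j`. Then
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{k=2}^{i} k g_k -
#'   T/2}{T\sqrt{1/(12(n-2))}}}{gamma = (mean of partial sums - T/2) /
#'   (T*sqrt(1/(12(n-2))))}
#' Under a pure-birth process the statistic is approximately standard normal.
#' A node with `c > 2` children is treated as `c - 1` coincident binary
#' branching events (zero-length internode intervals).
#'
#' @param tree An ultrametric `treekit_tree` (leaf depths within `tol`
#'   relative to the height) with at least 3 leaves.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @param details If `TRUE`, return a list with `n`, `g` (named `g2`..`gn`),
#'   `T`, and `gamma` instead of the bare number.
#' @return Numeric scalar (or list when `details = TRUE`).
#' @export
gamma_statistic <- function(tree, tol = 1e-6, details = FALSE) {
  root <- .as_root(tree)
  pd <- .preorder_depths(root)
  is_lf <- vapply(pd$nodes, function(u) length(u$children) == 0L, logical(1))
  n <- sum(is_lf)
  if (n < 3L)
    stop_undefined(sprintf(
      "the gamma statistic needs >= 3 leaves, got %d", n))
  h <- max(pd$depth[is_lf])
  dev <- max(abs(pd$depth[is_lf] - h))
  if (h <= 0)
    stop_undefined("tree height is zero; gamma is undefined")
  if (dev > tol * h)
    stop_invalid_value(sprintf(
      "tree is not ultrametric: max leaf-depth deviation %g exceeds %g * height",
      dev, tol))
  # branching events: an internal node with c children is c-1 binary events
  nch <- vapply(pd$nodes, function(u) length(u$children), integer(1))
  ev <- rep(pd$depth[!is_lf], pmax(nch[!is_lf] - 1L, 0L))
  ev <- sort(ev)                       # e_1 .. e_{n-1}
  g <- c(diff(ev), h - ev[n - 1L])     # g_2 .. g_n
  jg <- (2:n) * g
  T_tot <- sum(jg)
  cums <- cumsum(jg)                   # cums[i-1] = sum_{k=2..i} k*g_k
  gamma <- (mean(cums[1:(n - 2L)]) - T_tot / 2) /
    (T_tot * sqrt(1 / (12 * (n - 2L))))
  if (details)
    list(n = n, g = stats::setNames(g, paste0("g", 2:n)), T = T_tot,
         gamma = gamma)
  else gamma
}

#' Minimum distance to a leaf, for every node
#'
#' One post-order pass: a leaf maps to 0, and an internal node maps to the
#' minimum over its children of the child's value plus the child's edge
#' length. The root's value is therefore the minimum root-to-leaf patristic
#' distance.
#'
#' @param tree A `treekit_tree`.
#' @return Numeric vector in post-order (the root is the last element), with
#'   node labels as names (`""` when unlabeled) and the list of visited nodes
#'   in attribute `"nodes"`.
#' @examples
#' d <- min_leaf_distances(read_tree_newick("((A:1,B:3)X:1,C:5)R;"))
#' unname(d[length(d)])  # 2: the root's minimum leaf distance
#' @export
min_leaf_distances <- function(tree) {
  nodes <- .postorder_nodes(.as_root(tree))
  n <- length(nodes)
  val <- numeric(n)
  for (i in seq_len(n)) nodes[[i]]$.ml <- i
  on.exit(for (u in nodes) rm(".ml", envir = u))
  for (i in seq_len(n)) {
    u <- nodes[[i]]
    if (length(u$children) == 0L) {
      val[i] <- 0
    } else {
      best <- Inf
      for (k in u$children) {
        el <- k$edge_length
        cand <- val[k$.ml] + if (is.null(el)) 0 else el
        if (cand < best) best <- cand
      }
      val[i] <- best
    }
  }
  names(val) <- vapply(nodes, function(u)
    if (is.null(u$label)) "" else u$label, character(1))
  attr(val, "nodes") <- nodes
  val
}
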