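# Independent oracles: small recursive reference implementations used to
# check the package's iterative algorithms. They deliberately share no code
# with the package internals.

# -- recursive traversal definitions (safe only for small trees) --

oracle_preorder <- function(u) {
  out <- list(u)
  for (k in node_children(u)) out <- c(out, oracle_preorder(k))
  out
}

oracle_postorder <- function(u) {
  out <- list()
  for (k in node_children(u)) out <- c(out, oracle_postorder(k))
  c(out, list(u))
}

oracle_inorder <- function(u) {
  ch <- node_children(u)
  if (length(ch) == 0L) return(list(u))
  if (length(ch) == 1L) return(c(oracle_inorder(ch[[1]]), list(u)))
  stopifnot(length(ch) == 2L)
  c(oracle_inorder(ch[[1]]), list(u), oracle_inorder(ch[[2]]))
}

oracle_levelorder <- function(root) {
  out <- list()
  level <- list(root)
  while (length(level)) {
    out <- c(out, level)
    nxt <- list()
    for (u in level) nxt <- c(nxt, node_children(u))
    level <- nxt
  }
  out
}

# -- per-node reference quantities via explicit upward walks --

oracle_depth <- function(u) {
  d <- 0
  while (!is.null(node_parent(u))) {
    el <- node_edge_length(u)
    d <- d + if (is.null(el)) 0 else el
    u <- node_parent(u)
  }
  d
}

oracle_topo_depth <- function(u) {
  d <- 0L
  while (!is.null(node_parent(u))) {
    d <- d + 1L
    u <- node_parent(u)
  }
  d
}

oracle_ancestors <- function(u) {
  out <- list(u)
  while (!is.null(node_parent(u))) {
    u <- node_parent(u)
    out <- c(out, list(u))
  }
  out
}

# deepest element (by topological depth) of the intersection of ancestor sets
oracle_mrca <- function(nodes) {
  common <- oracle_ancestors(nodes[[1]])
  for (v in nodes[-1]) {
    anc_v <- oracle_ancestors(v)
    common <- Filter(function(a)
      any(vapply(anc_v, identical, logical(1), y = a)), common)
  }
  depths <- vapply(common, oracle_topo_depth, integer(1))
  common[[which.max(depths)]]
}

oracle_distance <- function(u, v) {
  m <- oracle_mrca(list(u, v))
  oracle_depth(u) + oracle_depth(v) - 2 * oracle_depth(m)
}

# minimum root-to-leaf distance by enumerating full leaf paths
oracle_min_leaf_dist <- function(root) {
  leaves <- Filter(is_leaf, oracle_preorder(root))
  min(vapply(leaves, oracle_depth, numeric(1)))
}

# -- direct-formula gamma with explicit double loops --

oracle_gamma <- function(tr) {
  nodes <- oracle_preorder(if (inherits(tr, "treekit_tree")) tr$root else tr)
  leaves <- Filter(is_leaf, nodes)
  internals <- Filter(function(u) !is_leaf(u), nodes)
  n <- length(leaves)
  h <- max(vapply(leaves, oracle_depth, numeric(1)))
  ev <- numeric(0)
  for (u in internals) {
    d <- oracle_depth(u)
    for (r in seq_len(length(node_children(u)) - 1L)) ev <- c(ev, d)
  }
  ev <- sort(ev)
  g <- numeric(n + 1L)   # g[k] is g_k, k = 2..n
  for (k in 2:n) {
    g[k] <- if (k < n) ev[k] - ev[k - 1L] else h - ev[n - 1L]
  }
  T_tot <- 0
  for (j in 2:n) T_tot <- T_tot + j * g[j]
  outer_sum <- 0
  for (i in 2:(n - 1L)) {
    inner <- 0
    for (k in 2:i) inner <- inner + k * g[k]
    outer_sum <- outer_sum + inner
  }
  (outer_sum / (n - 2L) - T_tot / 2) / (T_tot * sqrt(1 / (12 * (n - 2L))))
}

# -- simple recursive Newick writer (independent of write_tree_newick) --

oracle_newick <- function(u) {
  lab <- node_label(u)
  if (is.null(lab)) lab <- ""
  if (grepl("[](),:;'[:space:]]", lab))
    lab <- paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  el <- node_edge_length(u)
  suffix <- paste0(lab, if (is.null(el)) "" else paste0(":", format(el, digits = 17)))
  ch <- node_children(u)
  if (length(ch) == 0L) return(suffix)
  paste0("(", paste(vapply(ch, oracle_newick, character(1)), collapse = ","),
         ")", suffix)
}

# -- minimal NeXML emitter (tests only) --

oracle_nexml <- function(tr) {
  root <- tr$root
  nodes <- oracle_preorder(root)
  ids <- paste0("n", seq_along(nodes))
  id_of <- function(u) ids[which(vapply(nodes, identical, logical(1), y = u))]
  node_xml <- vapply(seq_along(nodes), function(i) {
    u <- nodes[[i]]
    lab <- node_label(u)
    sprintf("<node id=\"%s\"%s/>", ids[i],
            if (is.null(lab)) "" else sprintf(" label=\"%s\"", lab))
  }, character(1))
  edge_xml <- unlist(lapply(seq_along(nodes), function(i) {
    u <- nodes[[i]]
    p <- node_parent(u)
    if (is.null(p)) return(character(0))
    el <- node_edge_length(u)
    sprintf("<edge source=\"%s\" target=\"%s\"%s/>", id_of(p), ids[i],
            if (is.null(el)) "" else
              sprintf(" length=\"%s\"", format(el, digits = 17)))
  }))
  paste0("<nexml xmlns=\"http://www.nexml.org/2009\"><trees><tree id=\"t1\">",
         paste(node_xml, collapse = ""), paste(edge_xml, collapse = ""),
         "</tree></trees></nexml>")
}

# -- exhaustive enumeration of rooted tree shapes (unordered children) --

# all_tree_shapes(n): every rooted tree with exactly n nodes, as nested lists
# (a shape is a list of child shapes), deduplicated up to child order.
all_tree_shapes <- local({
  memo <- list()
  shape_key <- function(s) {
    if (length(s) == 0L) return("o")
    paste0("(", paste(sort(vapply(s, shape_key, character(1))),
                      collapse = ","), ")")
  }
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 1L) {
      res <- list(list())
    } else {
      res <- list()
      seen <- character(0)
      # compositions of n-1 children-subtree sizes
      compositions <- function(m) {
        if (m == 0L) return(list(integer(0)))
        out <- list()
        for (first in seq_len(m)) {
          for (rest in compositions(m - first))
            out[[length(out) + 1L]] <- c(first, rest)
        }
        out
      }
      for (comp in compositions(n - 1L)) {
        parts <- lapply(comp, gen)
        idx <- rep(1L, length(comp))
        repeat {
          children <- lapply(seq_along(comp), function(i) parts[[i]][[idx[i]]])
          k <- shape_key(children)
          if (!k %in% seen) {
            seen <- c(seen, k)
            res[[length(res) + 1L]] <- children
          }
          j <- length(idx)
          while (j >= 1L) {
            idx[j] <- idx[j] + 1L
            if (idx[j] <= length(parts[[j]])) break
            idx[j] <- 1L
            j <- j - 1L
          }
          if (j < 1L) break
        }
      }
    }
    memo[[key]] <<- res
    res
  }
  function(n) gen(n)
})

# build a treekit tree from a shape, labeling every node and giving each
# non-root node edge length drawn deterministically
build_shape <- function(shape) {
  counter <- 0L
  build <- function(s) {
    counter <<- counter + 1L
    u <- new_node(paste0("n", counter), if (counter == 1L) NULL
                  else counter / 7)
    for (cs in s) add_child(u, build(cs))
    u
  }
  tree(build(shape))
}

# shuffle every node's child order in place (for invariance tests)
shuffle_children <- function(tr) {
  it <- traverse_preorder(tr)
  while (!is.null(u <- next_node(it))) {
    ch <- node_children(u)
    if (length(ch) > 1L) u$children <- ch[sample.int(length(ch))]
  }
  invisible(tr)
}

# random fixture tree across all three models
random_fixture <- function(n, seed, model = NULL) {
  models <- c("yule", "coalescent", "random_attachment")
  if (is.null(model)) model <- models[(seed %% 3L) + 1L]
  generate_tree(n, model = model, seed = seed)
}

label_vec <- function(nodes) {
  vapply(nodes, function(u) {
    l <- node_label(u)
    if (is.null(l)) NA_character_ else l
  }, character(1))
}
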