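# the worked 5-node example used throughout: ((A,B)X,C)R
ex_tree <- function() read_tree_newick("((A,B)X,C)R;")

labels_of <- function(it) label_vec(as.list(it))

test_that("each order matches its hand-expanded definition on the example", {
  expect_identical(labels_of(traverse_preorder(ex_tree())),
                   c("R", "X", "A", "B", "C"))
  expect_identical(labels_of(traverse_postorder(ex_tree())),
                   c("A", "B", "X", "C", "R"))
  expect_identical(labels_of(traverse_inorder(ex_tree())),
                   c("A", "X", "B", "R", "C"))
  expect_identical(labels_of(traverse_levelorder(ex_tree())),
                   c("R", "X", "C", "A", "B"))
  expect_identical(labels_of(traverse_leaves(ex_tree())), c("A", "B", "C"))
  # weighted root-distance: R(0), X(1), C(1) tie broken by preorder, A(2), B(4)
  tr <- read_tree_newick("((A:1,B:3)X:1,C:1)R;")
  expect_identical(labels_of(traverse_rootdistorder(tr)),
                   c("R", "X", "C", "A", "B"))
  expect_identical(labels_of(traverse_rootdistorder(tr, ascending = FALSE)),
                   c("B", "A", "X", "C", "R"))
})

test_that("single-node trees traverse to themselves in every order", {
  solo <- tree(new_node("only"))
  for (f in list(traverse_preorder, traverse_postorder, traverse_inorder,
                 traverse_levelorder, traverse_rootdistorder, traverse_leaves))
    expect_identical(labels_of(f(solo)), "only")
})

test_that("order contracts hold exhaustively on all trees with <= 7 nodes", {
  shapes <- unlist(lapply(1:7, all_tree_shapes), recursive = FALSE)
  # Wedderburn counts for rooted trees on 1..7 nodes
  expect_identical(vapply(1:7, function(n) length(all_tree_shapes(n)),
                          integer(1)), c(1L, 1L, 2L, 4L, 9L, 20L, 48L))
  for (shape in shapes) {
    tr <- build_shape(shape)
    n_all <- num_nodes(tr)[["total"]]

    pre <- as.list(traverse_preorder(tr))
    post <- as.list(traverse_postorder(tr))
    lev <- as.list(traverse_levelorder(tr))
    rd <- as.list(traverse_rootdistorder(tr))
    expect_identical(label_vec(pre), label_vec(oracle_preorder(tr$root)))
    expect_identical(label_vec(post), label_vec(oracle_postorder(tr$root)))
    expect_identical(label_vec(lev), label_vec(oracle_levelorder(tr$root)))
    for (seq in list(pre, post, lev, rd)) {
      expect_identical(length(seq), n_all)          # every node exactly once
      expect_identical(anyDuplicated(label_vec(seq)), 0L)
    }
    binary <- all(vapply(pre, function(u) num_children(u) <= 2L, logical(1)))
    if (binary) {
      expect_identical(label_vec(as.list(traverse_inorder(tr))),
                       label_vec(oracle_inorder(tr$root)))
    } else {
      expect_error(traverse_inorder(tr),
                   class = "treekit_unsupported_topology")
    }
  }
})

test_that("preorder parents precede children; postorder reverses preorder with flipped children", {
  for (seed in 1:6) {
    tr <- random_fixture(30, seed)
    pre <- as.list(traverse_preorder(tr))
    rank <- seq_along(pre)
    names(rank) <- label_vec(pre)  # all generator nodes are unlabeled internals
    pos <- integer(0)
    for (i in seq_along(pre)) pre[[i]]$.pos <- i
    for (u in pre) {
      for (k in node_children(u)) expect_lt(u$.pos, k$.pos)
    }
    for (u in pre) rm(".pos", envir = u)

    post <- as.list(traverse_postorder(tr))
    # reverse the stored child order everywhere, take preorder, reverse it
    shuffle <- function(u) {
      u$children <- rev(u$children)
      for (k in u$children) shuffle(k)
    }
    shuffle(tr$root)
    pre_flipped <- as.list(traverse_preorder(tr))
    expect_true(all(mapply(identical, post, rev(pre_flipped))))
  }
})

test_that("level-order depth sequence is non-decreasing; caterpillar levels", {
  for (seed in 1:4) {
    tr <- random_fixture(40, seed)
    depths <- vapply(as.list(traverse_levelorder(tr)), oracle_topo_depth,
                     integer(1))
    expect_true(all(diff(depths) >= 0L))
  }
  # caterpillar: one internal node per level except the deepest
  n <- 12L
  root <- new_node("i1")
  cur <- root
  for (i in 2:n) {
    add_child(cur, new_node(paste0("leaf", i - 1L), 1))
    nxt <- new_node(paste0("i", i), 1)
    add_child(cur, nxt)
    cur <- nxt
  }
  cat_tree <- tree(root)
  depths <- vapply(as.list(traverse_levelorder(cat_tree)), oracle_topo_depth,
                   integer(1))
  per_level <- table(depths)
  internal_per_level <- vapply(split(
    as.list(traverse_levelorder(cat_tree)), depths),
    function(nodes) sum(!vapply(nodes, is_leaf, logical(1))), integer(1))
  expect_true(all(internal_per_level[-length(internal_per_level)] == 1L))
  expect_identical(unname(internal_per_level[length(internal_per_level)]), 0L)
})

test_that("root-distance order is monotone with stable preorder tie-breaks", {
  for (seed in 1:5) {
    tr <- generate_tree(50, "random_attachment", seed = seed)
    d <- vapply(as.list(traverse_rootdistorder(tr)), oracle_depth, numeric(1))
    expect_true(all(diff(d) >= -1e-12))
    d2 <- vapply(as.list(traverse_rootdistorder(tr, ascending = FALSE)),
                 oracle_depth, numeric(1))
    expect_true(all(diff(d2) <= 1e-12))
  }
  # all lengths absent: ordering degenerates to preorder rank
  tr <- read_tree_newick("((A,B)X,C)R;")
  expect_identical(labels_of(traverse_rootdistorder(tr)),
                   labels_of(traverse_preorder(tr)))
})

test_that("in-order rejects multifurcations, naming the offending node", {
  tr <- read_tree_newick("((A,B,C)X,D)R;")
  err <- tryCatch(traverse_inorder(tr), error = identity)
  expect_s3_class(err, "treekit_unsupported_topology")
  expect_match(conditionMessage(err), "X")
  # unary chains are allowed: child before node
  expect_identical(labels_of(traverse_inorder(read_tree_newick("((A)U,B)R;"))),
                   c("A", "U", "R", "B"))
})

test_that("traversals are iterative: a deep caterpillar does not overflow", {
  depth <- 100000L
  root <- new_node("top")
  cur <- root
  for (i in seq_len(depth)) {
    nxt <- new_node(NULL, 1)
    add <- cur$children
    cur$children <- c(add, list(nxt))  # direct link: keep construction O(n)
    nxt$parent <- cur
    cur <- nxt
  }
  cur$label <- "bottom"
  tr <- tree(root)
  n <- 0L
  it <- traverse_postorder(tr)
  while (!is.null(next_node(it))) n <- n + 1L
  expect_identical(n, depth + 1L)
  expect_identical(label_vec(as.list(traverse_leaves(tr))), "bottom")
})

test_that("iterators are lazy: first items of a large tree come back fast", {
  tr <- generate_tree(100000, "random_attachment", seed = 3)
  elapsed <- system.time({
    it <- traverse_preorder(tr)
    first10 <- vector("list", 10L)
    for (i in 1:10) first10[[i]] <- next_node(it)
  })[["elapsed"]]
  expect_lt(elapsed, 1.0)  # frontier work only, far below a full traversal
  expect_false(any(vapply(first10, is.null, logical(1))))
})
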