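test_that("height, average branch length and treeness match hand computations", {
  expect_identical(tree_height(read_tree_newick("((A:1,B:3)X:1,C:1)R;")), 4)
  expect_identical(tree_height(read_tree_newick("((A,B)X,C)R;")), 0)

  tr <- read_tree_newick("((A:1,B:3)X:2,C:6)R;")
  expect_identical(avg_branch_length(tr, "all"), 3)
  expect_identical(avg_branch_length(tr, "internal"), 2)
  expect_equal(avg_branch_length(tr, "leaf"), 10 / 3)
  expect_error(avg_branch_length(read_tree_newick("(A,B);"), "all"),
               class = "treekit_undefined_statistic")

  expect_equal(treeness(tr), 2 / 12)
  expect_identical(treeness(read_tree_newick("(A:1,B:2,C:3)R;")), 0)
  expect_error(treeness(read_tree_newick("(A,B);")),
               class = "treekit_undefined_statistic")
  # a stored root edge counts as internal
  expect_equal(treeness(read_tree_newick("(A:1,B:1)R:2;")), 0.5)
})

test_that("height equals the maximum of independently walked leaf depths", {
  for (seed in 1:6) {
    tr <- random_fixture(45, seed)
    leaves <- Filter(is_leaf, oracle_preorder(tr$root))
    expect_equal(tree_height(tr),
                 max(vapply(leaves, oracle_depth, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("patristic distances match the depth/MRCA identity and brute force", {
  tr <- read_tree_newick("((A:1,B:1)X:1,C:2)R;")
  expect_identical(distance_between(tr, "A", "A"), 0)
  expect_identical(distance_between(tr, "A", "B"), 2)
  expect_identical(distance_between(tr, "A", "C"), 4)

  for (seed in 1:4) {
    tr <- random_fixture(20, seed)
    leaves <- Filter(is_leaf, oracle_preorder(tr$root))
    for (i in seq_along(leaves)) {
      for (j in seq_len(i)) {
        expect_equal(distance_between(tr, leaves[[i]], leaves[[j]]),
                     oracle_distance(leaves[[i]], leaves[[j]]),
                     tolerance = 1e-12)
      }
    }
  }

  other <- read_tree_newick("(P,Q);")
  expect_error(distance_between(tr, node_children(other$root)[[1]],
                                Filter(is_leaf, oracle_preorder(tr$root))[[1]]),
               class = "treekit_structure_error")
})

test_that("mrca agrees with the ancestor-set oracle and is idempotent", {
  tr <- read_tree_newick("((A,B)X,C)R;")
  expect_identical(node_label(mrca(tr, "A")), "A")
  expect_identical(node_label(mrca(tr, c("A", "B"))), "X")
  expect_identical(node_label(mrca(tr, c("A", "C"))), "R")
  expect_error(mrca(tr, c("A", "ZZZ")), class = "treekit_lookup_error")

  for (seed in 1:4) {
    tr <- random_fixture(30, seed)
    labs <- leaf_labels(tr)
    leaves <- Filter(is_leaf, oracle_preorder(tr$root))
    names(leaves) <- label_vec(leaves)
    set.seed(seed)
    for (rep in 1:20) {
      pick <- sample(labs, sample(2:4, 1))
      got <- mrca(tr, pick)
      want <- oracle_mrca(leaves[pick])
      expect_true(identical(got, want))
      # adding a descendant of the MRCA never changes it
      sub_leaves <- label_vec(Filter(is_leaf, oracle_preorder(got)))
      extra <- sample(sub_leaves, 1)
      expect_true(identical(mrca(tr, c(pick, extra)), got))
    }
  }
})

test_that("distance_matrix equals brute-force per-pair distances", {
  D <- distance_matrix(read_tree_newick("(A:1,B:2);"))
  expect_identical(D["A", "B"], 3)
  expect_identical(unname(diag(D)), c(0, 0))

  for (seed in 1:6) {
    n <- c(2, 5, 13, 32, 50, 64)[seed]
    tr <- random_fixture(n, seed)
    D <- distance_matrix(tr)
    expect_identical(D, t(D))
    leaves <- Filter(is_leaf, oracle_preorder(tr$root))
    names(leaves) <- label_vec(leaves)
    for (a in rownames(D)) {
      for (b in colnames(D)) {
        expect_equal(D[a, b], oracle_distance(leaves[[a]], leaves[[b]]),
                     tolerance = 1e-9)
      }
    }
  }

  dup <- read_tree_newick("(A,(A,B));")
  expect_error(distance_matrix(dup), class = "treekit_lookup_error")
})

test_that("distance matrices satisfy the tree-metric axioms", {
  set.seed(7)
  for (seed in 1:3) {
    tr <- random_fixture(24, seed)
    D <- distance_matrix(tr)
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    labs <- rownames(D)
    # triangle inequality on all triples
    for (rep in 1:200) {
      ijk <- sample(labs, 3)
      expect_lte(D[ijk[1], ijk[3]],
                 D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
    }
    # four-point condition on random quadruples
    for (rep in 1:100) {
      q <- sample(labs, 4)
      s1 <- D[q[1], q[2]] + D[q[3], q[4]]
      s2 <- D[q[1], q[3]] + D[q[2], q[4]]
      s3 <- D[q[1], q[4]] + D[q[2], q[3]]
      sums <- sort(c(s1, s2, s3))
      expect_lte(sums[3] - sums[2], 1e-9 * max(1, sums[3]))
    }
  }
})

test_that("ultrametric trees obey d(x,y) = 2(h - depth(mrca))", {
  for (seed in 1:3) {
    tr <- generate_tree(30, "coalescent", seed = seed)
    D <- distance_matrix(tr)
    h <- tree_height(tr)
    labs <- rownames(D)
    set.seed(seed)
    for (rep in 1:50) {
      ab <- sample(labs, 2)
      m <- mrca(tr, ab)
      expect_equal(D[ab[1], ab[2]], 2 * (h - oracle_depth(m)),
                   tolerance = 1e-9)
    }
  }
})

test_that("distance matrix cross-checks against ape::cophenetic", {
  skip_if_not_installed("ape")
  for (seed in 1:3) {
    tr <- random_fixture(40, seed)
    D <- distance_matrix(tr)
    ph <- ape::read.tree(text = write_tree_newick(tr))
    C <- stats::cophenetic(ph)
    expect_equal(D[rownames(C), colnames(C)], C, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("gamma matches the direct-formula oracle and ape::gammaStat", {
  # 3-leaf tree, branching depths 0 and 0.5, height 1: gamma ~ -0.3464
  tr3 <- read_tree_newick("((A:0.5,B:0.5):0.5,C:1);")
  expect_equal(gamma_statistic(tr3), -0.25 / (2.5 * sqrt(1 / 12)),
               tolerance = 1e-12)
  d <- gamma_statistic(tr3, details = TRUE)
  expect_equal(unname(d$g), c(0.5, 0.5))
  expect_identical(d$T, 2.5)

  # equal internode weights make the numerator vanish: a 4-leaf tree where
  # cumulative sums average to exactly T/2
  # g2=1/2, g3=1/3, g4=1/4 -> j*g_j = 1 each; partial sums 1,2; mean 1.5 = T/2? T=3, T/2=1.5
  tr0 <- read_tree_newick(
    "(((A:0.25,B:0.25):0.333333333333333333,C:0.583333333333333333):0.5,D:1.083333333333333333);")
  expect_equal(gamma_statistic(tr0, tol = 1e-6), 0, tolerance = 1e-9)

  for (seed in 1:50) {
    tr <- generate_tree(sample(3:40, 1), "coalescent", seed = seed)
    expect_equal(gamma_statistic(tr), oracle_gamma(tr), tolerance = 1e-9)
  }
  skip_if_not_installed("ape")
  for (seed in 1:10) {
    tr <- generate_tree(25, "yule", seed = seed)
    ph <- ape::read.tree(text = write_tree_newick(tr))
    expect_equal(gamma_statistic(tr), ape::gammaStat(ph), tolerance = 1e-8)
  }
})

test_that("gamma rejects non-ultrametric input and tiny trees", {
  expect_error(gamma_statistic(read_tree_newick("((A:1,B:2):1,C:5);")),
               class = "treekit_invalid_value")
  err <- tryCatch(gamma_statistic(read_tree_newick("((A:1,B:2):1,C:5);")),
                  error = identity)
  expect_match(conditionMessage(err), "deviation")
  expect_error(gamma_statistic(read_tree_newick("(A:1,B:1);")),
               class = "treekit_undefined_statistic")
  # multifurcation = coincident binary events with zero-length intervals
  star <- read_tree_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(gamma_statistic(star), oracle_gamma(star), tolerance = 1e-12)
})

test_that("min_leaf_distances follows the post-order recursion", {
  m <- min_leaf_distances(read_tree_newick("((A:1,B:3)X:1,C:5)R;"))
  expect_identical(m[["X"]], 1)
  expect_identical(unname(m[length(m)]), 2)
  expect_true(all(m[c("A", "B", "C")] == 0))

  for (seed in 1:6) {
    tr <- random_fixture(40, seed)
    m <- min_leaf_distances(tr)
    expect_identical(length(m), unname(num_nodes(tr)[["total"]]))
    expect_equal(unname(m[length(m)]), oracle_min_leaf_dist(tr$root),
                 tolerance = 1e-12)
    leaves <- vapply(attr(m, "nodes"), is_leaf, logical(1))
    expect_true(all(m[leaves] == 0))
  }
})

test_that("statistics are invariant under child-order permutation", {
  for (seed in 1:3) {
    tr <- random_fixture(25, seed)
    h0 <- tree_height(tr); t0 <- treeness(tr); a0 <- avg_branch_length(tr)
    D0 <- distance_matrix(tr)
    set.seed(seed + 1000)
    shuffle_children(tr)
    expect_identical(tree_height(tr), h0)   # per-path sums are order-free
    expect_equal(treeness(tr), t0, tolerance = 1e-12)
    expect_equal(avg_branch_length(tr), a0, tolerance = 1e-12)
    D1 <- distance_matrix(tr)
    expect_equal(D1[rownames(D0), colnames(D0)], D0, tolerance = 0)
  }
})

test_that("treeness and the leaf-edge fraction sum to one exactly", {
  for (seed in 1:5) {
    tr <- random_fixture(30, seed)
    nodes <- oracle_preorder(tr$root)
    leaf_sum <- sum(vapply(Filter(is_leaf, nodes), function(u) {
      el <- node_edge_length(u); if (is.null(el)) 0 else el
    }, numeric(1)))
    expect_equal(treeness(tr) + leaf_sum / total_branch_length(tr), 1,
                 tolerance = 1e-12)
  }
})
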