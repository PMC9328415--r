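# Random binary tree generator. Three models, each exercising a different
# code path downstream: "yule" and "coalescent" are ultrametric (gamma, LTT
# plateaus), "random_attachment" is not (general patristic metrics). Trees
# are built as flat parent/length vectors first and materialized into nodes
# in one pass, so generation stays fast at 10^5-10^6 leaves.

.draw_lens <- function(k, law, rate, min, max, const) {
  switch(law,
         exponential = stats::rexp(k, rate),
         uniform = stats::runif(k, min, max),
         constant = rep(const, k))
}

# parent: integer vector (0 for root), brlen: numeric (NA = absent).
# Children attach in increasing node-id order; leaves get labels L1..Ln in
# preorder.
.materialize_tree <- function(parent, brlen) {
  n <- length(parent)
  nodes <- vector("list", n)
  for (i in seq_len(n)) nodes[[i]] <- .bare_node()
  root_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(brlen[i])) nodes[[i]]$edge_length <- brlen[i]
    p <- parent[i]
    if (p == 0L) {
      root_id <- i
    } else {
      pe <- nodes[[p]]
      pe$children[[length(pe$children) + 1L]] <- nodes[[i]]
      nodes[[i]]$parent <- pe
    }
  }
  tr <- tree(nodes[[root_id]])
  lab <- 0L
  it <- .stack_new(tr$root)
  while (!is.null(u <- .stack_pop_push_children(it))) {
    if (length(u$children) == 0L) {
      lab <- lab + 1L
      u$label <- paste0("L", lab)
    }
  }
  tr
}

.gen_yule <- function(n, rate) {
  if (n == 1L) return(.materialize_tree(0L, NA_real_))
  total <- 2L * n - 1L
  parent <- integer(total)
  t_start <- numeric(total)
  t_end <- rep(NA_real_, total)
  active <- integer(n)
  active[1L] <- 1L
  na <- 1L
  nid <- 1L
  t <- 0
  for (k in seq_len(n - 1L)) {
    t <- t + stats::rexp(1L, rate * na)
    pick <- if (na == 1L) 1L else sample.int(na, 1L)
    u <- active[pick]
    t_end[u] <- t
    a <- nid + 1L; b <- nid + 2L; nid <- b
    parent[a] <- u; parent[b] <- u
    t_start[a] <- t; t_start[b] <- t
    active[pick] <- a
    na <- na + 1L
    active[na] <- b
  }
  # observe the tree one full waiting time after the n-th tip appears, so
  # every internode interval g_k is an independent Exp(k * rate) draw
  t_final <- t + stats::rexp(1L, rate * n)
  t_end[active[seq_len(na)]] <- t_final
  brlen <- t_end - t_start
  brlen[1L] <- NA_real_   # no stem edge above the root
  .materialize_tree(parent, brlen)
}

.gen_coalescent <- function(n, rate) {
  if (n == 1L) return(.materialize_tree(0L, NA_real_))
  total <- 2L * n - 1L
  parent <- integer(total)
  btime <- numeric(total)          # time before the present (tips at 0)
  active <- seq_len(n)
  k <- n
  nid <- n
  t <- 0
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate * k * (k - 1L) / 2)
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    nid <- nid + 1L
    btime[nid] <- t
    parent[a] <- nid; parent[b] <- nid
    active[pick[1L]] <- nid
    active[pick[2L]] <- active[k]
    k <- k - 1L
  }
  brlen <- rep(NA_real_, total)
  has_p <- parent != 0L
  brlen[has_p] <- btime[parent[has_p]] - btime[has_p]
  .materialize_tree(parent, brlen)
}

.gen_random_attachment <- function(n, law, rate, min, max, const) {
  if (n == 1L) return(.materialize_tree(0L, NA_real_))
  total <- 2L * n - 1L
  parent <- integer(total)
  brlen <- rep(NA_real_, total)
  # start as a cherry: root 1, leaves 2 and 3
  parent[2L] <- 1L; parent[3L] <- 1L
  brlen[2:3] <- .draw_lens(2L, law, rate, min, max, const)
  edges <- integer(total)          # edge above each non-root node
  edges[1:2] <- c(2L, 3L)
  ne <- 2L
  nid <- 3L
  for (j in seq_len(n - 2L)) {
    c_id <- edges[sample.int(ne, 1L)]
    m <- nid + 1L; leaf <- nid + 2L; nid <- leaf
    parent[m] <- parent[c_id]
    parent[c_id] <- m
    parent[leaf] <- m
    u <- stats::runif(1L)
    brlen[m] <- u * brlen[c_id]
    brlen[c_id] <- (1 - u) * brlen[c_id]
    brlen[leaf] <- .draw_lens(1L, law, rate, min, max, const)
    edges[ne + 1L] <- m
    edges[ne + 2L] <- leaf
    ne <- ne + 2L
  }
  .materialize_tree(parent, brlen)
}

#' Generate a random binary tree
#'
#' Produces a strictly binary tree with exactly `n_leaves` leaves labeled
#' `L1..Ln` (in pre-order), under one of three models:
#' \describe{
#'   \item{yule}{forward-time pure-birth process at rate `rate`: every lineage
#'     splits independently, and the tree is observed one further exponential
#'     waiting time after the n-th tip appears, so all tips end at the same
#'     depth (ultrametric) and the internode intervals are independent
#'     `Exp(k * rate)` draws.}
#'   \item{coalescent}{Kingman-style pairwise merging backward in time with
#'     `Exp(rate * k(k-1)/2)` waiting times; ultrametric by construction.}
#'   \item{random_attachment}{each new leaf attaches at a uniform point on a
#'     uniformly chosen existing edge, with its pendant edge length drawn from
#'     `law`; non-ultrametric.}
#' }
#' The same `seed` (with the same parameters) reproduces a byte-identical
#' tree; the global random state is saved and restored around the call.
#'
#' @param n_leaves Number of leaves (>= 1).
#' @param model One of `"yule"`, `"coalescent"`, `"random_attachment"`.
#' @param law Branch-length law for `random_attachment` pendant edges:
#'   `"exponential"` (parameter `rate`), `"uniform"` (`min`, `max`), or
#'   `"constant"` (`const`).
#' @param rate Positive rate of the exponential law / birth / coalescence.
#' @param min,max Bounds of the uniform law (`0 <= min < max`).
#' @param const Value of the constant law (>= 0).
#' @param seed Optional integer seed.
#' @return A `treekit_tree` with `2 * n_leaves - 1` nodes.
#' @examples
#' tr <- generate_tree(100, model = "coalescent", seed = 42)
#' num_nodes(tr)
#' @export
generate_tree <- function(n_leaves,
                          model = c("yule", "coalescent", "random_attachment"),
                          law = c("exponential", "uniform", "constant"),
                          rate = 1, min = 0, max = 1, const = 1,
                          seed = NULL) {
  model <- match.arg(model)
  law <- match.arg(law)
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || is.na(n_leaves) ||
      n_leaves < 1L || n_leaves != floor(n_leaves))
    stop_invalid_value("`n_leaves` must be a positive integer")
  n_leaves <- as.integer(n_leaves)
  if (!is.numeric(rate) || rate <= 0)
    stop_invalid_value("`rate` must be > 0")
  if (law == "uniform" && (min < 0 || max <= min))
    stop_invalid_value("uniform law needs 0 <= min < max")
  if (law == "constant" && const < 0)
    stop_invalid_value("constant law needs const >= 0")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  switch(model,
         yule = .gen_yule(n_leaves, rate),
         coalescent = .gen_coalescent(n_leaves, rate),
         random_attachment = .gen_random_attachment(n_leaves, law, rate,
                                                    min, max, const))
}
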