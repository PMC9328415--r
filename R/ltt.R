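# Lineages-Through-Time. Time runs forward from the root at 0 (node depth),
# which stays well-defined for non-ultrametric trees; users of backward-time
# conventions can negate the axis. A stored root edge shifts the origin: the
# single root lineage then exists on [0, root_edge) before the first split,
# so the step-function integral always equals the total branch length.

#' Lineages-Through-Time series
#'
#' Computes the step function counting coexisting lineages against time. The
#' lineage count at time `t` is the number of branches spanning `t`; at a
#' branching node with `c` children the count rises by `c - 1`, and at a leaf
#' that ends strictly before the last tip it falls by 1 (non-ultrametric
#' trees). Simultaneous events are merged into a single point. Missing edge
#' lengths count 0.
#'
#' @param tree A `treekit_tree`.
#' @return An `ltt_series`: a data frame with columns `time` (strictly
#'   increasing; the step starts at each `time` value) and `lineages` (the
#'   count from that time until the next point), with attributes `t0`, `t_end`
#'   (maximum leaf depth, shifted by any stored root edge) and `n_leaves`.
#' @examples
#' ltt(read_tree_newick("((A:1,B:1):1,C:2);"))
#' @export
ltt <- function(tree) {
  root <- .as_root(tree)
  pd <- .preorder_depths(root)
  shift <- if (is.null(root$edge_length)) 0 else root$edge_length
  depth <- pd$depth + shift
  nch <- vapply(pd$nodes, function(u) length(u$children), integer(1))
  is_lf <- nch == 0L
  t_end <- max(depth[is_lf])

  ev_t <- depth[!is_lf]
  ev_d <- nch[!is_lf] - 1L
  # leaves dying strictly before the last tip reduce the count; tiny relative
  # tolerance absorbs float drift in separately-summed ultrametric depths
  dies <- is_lf & (depth < t_end - 1e-12 * max(t_end, 1))
  ev_t <- c(ev_t, depth[dies])
  ev_d <- c(ev_d, rep(-1L, sum(dies)))
  if (shift > 0) {
    ev_t <- c(0, ev_t)
    ev_d <- c(0L, ev_d)
  }

  ord <- order(ev_t)
  ev_t <- ev_t[ord]
  ev_d <- ev_d[ord]
  delta <- vapply(split(ev_d, match(ev_t, unique(ev_t))), sum, numeric(1))
  times <- unique(ev_t)
  counts <- 1 + cumsum(delta)   # one root lineage exists before any event

  out <- data.frame(time = times, lineages = as.integer(counts))
  structure(out,
            class = c("ltt_series", "data.frame"),
            t0 = 0,
            t_end = t_end,
            n_leaves = sum(is_lf))
}

#' @export
print.ltt_series <- function(x, ...) {
  cat(sprintf("<ltt_series: %d points, %d leaves, time [%g, %g]>\n",
              nrow(x), attr(x, "n_leaves"), attr(x, "t0"), attr(x, "t_end")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more points\n", nrow(x) - 10L))
  invisible(x)
}

# integral of the step function over [t0, t_end]
.ltt_area <- function(series) {
  t <- c(series$time, attr(series, "t_end"))
  sum(series$lineages * diff(t))
}

#' Plot a Lineages-Through-Time series
#'
#' Renders the step function with ggplot2: time on the horizontal axis,
#' lineage count on the vertical axis (optionally log-scaled by the axis, not
#' by transforming the data).
#'
#' @param series An `ltt_series` from [ltt()].
#' @param output_path Optional image path (any device ggplot2::ggsave
#'   understands: png, pdf, svg, ...). When `NULL` the plot object is
#'   returned without writing anything.
#' @param log_scale_counts Use a logarithmic count axis?
#' @param color Line color (default `"blue"`).
#' @param width,height Device size in inches when writing a file.
#' @return The ggplot object, invisibly when `output_path` is given.
#' @export
plot_ltt <- function(series, output_path = NULL, log_scale_counts = FALSE,
                     color = "blue", width = 7, height = 5) {
  if (!inherits(series, "ltt_series") || nrow(series) == 0L)
    stop_invalid_value("`series` must be a non-empty ltt_series")
  df <- as.data.frame(series)
  # extend the final plateau to t_end so the last step is visible
  df <- rbind(df, data.frame(time = attr(series, "t_end"),
                             lineages = df$lineages[nrow(df)]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$lineages)) +
    ggplot2::geom_step(color = color) +
    ggplot2::labs(x = "time from root", y = "lineages") +
    ggplot2::theme_minimal()
  if (log_scale_counts) p <- p + ggplot2::scale_y_log10()
  if (!is.null(output_path)) {
    tryCatch(ggplot2::ggsave(output_path, plot = p, width = width,
                             height = height),
             error = function(e) stop_io(sprintf(
               "cannot write plot to %s: %s", output_path,
               conditionMessage(e))))
    return(invisible(p))
  }
  p
}

#' @rdname plot_ltt
#' @param object An `ltt_series`.
#' @param ... Passed on to `plot_ltt()`.
#' @exportS3Method ggplot2::autoplot
autoplot.ltt_series <- function(object, ...) plot_ltt(object, ...)
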