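# NeXML reading: the structural subset (tree elements with node and edge
# children; labels, otu references, edge lengths). Anything else in the
# document is ignored; extra XML attributes on a node element are retained
# verbatim in the node's attribute list.

#' Read trees from a NeXML document
#'
#' Each `<tree>` element yields one tree: node identity comes from XML `id`
#' attributes, display labels from `label` (falling back to `otu`), edge
#' lengths from the edge `length` attribute (absent attribute means missing
#' length), and the unique node with no incoming edge is the root. Children
#' are attached in document order of the edge elements.
#'
#' @param source NeXML text or file path (gzip detected by magic bytes).
#' @return A list of `treekit_tree`, in document order.
#' @export
read_tree_nexml <- function(source) {
  text <- .source_text(source)
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop_parse(sprintf(
                    "not well-formed XML: %s", conditionMessage(e))))
  tree_els <- xml2::xml_find_all(doc, "//*[local-name()='tree']")
  out <- vector("list", length(tree_els))
  for (ti in seq_along(tree_els)) {
    tel <- tree_els[[ti]]
    node_els <- xml2::xml_find_all(tel, "./*[local-name()='node']")
    edge_els <- xml2::xml_find_all(tel, "./*[local-name()='edge']")
    ids <- xml2::xml_attr(node_els, "id")
    if (anyNA(ids)) stop_parse("NeXML node element without an id attribute")
    if (anyDuplicated(ids))
      stop_parse(sprintf("duplicate NeXML node id: %s",
                         ids[duplicated(ids)][1]))
    nodes <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      u <- .bare_node()
      lab <- xml2::xml_attr(node_els[[i]], "label")
      if (is.na(lab)) lab <- xml2::xml_attr(node_els[[i]], "otu")
      if (!is.na(lab)) u$label <- lab
      extra <- as.list(xml2::xml_attrs(node_els[[i]]))
      extra <- extra[setdiff(names(extra), c("id", "label", "otu"))]
      if (length(extra)) u$attributes <- extra
      nodes[[i]] <- u
    }
    names(nodes) <- ids
    for (eel in edge_els) {
      src <- xml2::xml_attr(eel, "source")
      tgt <- xml2::xml_attr(eel, "target")
      if (is.na(src) || is.na(tgt))
        stop_parse("NeXML edge element lacks source/target")
      if (is.null(nodes[[src]]))
        stop_parse(sprintf("NeXML edge references undeclared node: %s", src))
      if (is.null(nodes[[tgt]]))
        stop_parse(sprintf("NeXML edge references undeclared node: %s", tgt))
      p <- nodes[[src]]; k <- nodes[[tgt]]
      if (!is.null(k$parent))
        stop_parse(sprintf("NeXML node %s has more than one incoming edge",
                           tgt))
      len <- xml2::xml_attr(eel, "length")
      if (!is.na(len)) {
        lv <- suppressWarnings(as.numeric(len))
        if (is.na(lv))
          stop_parse(sprintf("NeXML edge length is not a number: \"%s\"", len))
        k$edge_length <- lv
      }
      p$children[[length(p$children) + 1L]] <- k
      k$parent <- p
    }
    roots <- nodes[vapply(nodes, function(u) is.null(u$parent), logical(1))]
    if (length(roots) != 1L)
      stop_parse(sprintf(
        "NeXML tree must have exactly one parentless node, found %d",
        length(roots)))
    tr <- tree(roots[[1]])
    if (num_nodes(tr)[["total"]] != length(nodes))
      stop_parse("NeXML edges do not connect all declared nodes into one tree")
    out[[ti]] <- tr
  }
  out
}
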