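# NEXUS reading: the TREES block only (named Newick trees plus an optional
# TRANSLATE token table). Statements are located by splitting on ';' in the
# masked text, so ';' inside quoted labels or [comments] never breaks one.

.unmask_text <- function(piece, masked) {
  if (grepl("\x02", piece, fixed = TRUE)) {
    for (ph in unique(regmatches(piece, gregexpr("\x02[0-9]+\x03", piece))[[1]])) {
      id <- as.integer(gsub("[\x02\x03]", "", ph))
      lab <- paste0("'", gsub("'", "''", masked$quotes[id], fixed = TRUE), "'")
      piece <- gsub(ph, lab, piece, fixed = TRUE)
    }
  }
  if (grepl("\x04", piece, fixed = TRUE)) {
    for (ph in unique(regmatches(piece, gregexpr("\x04[0-9]+\x05", piece))[[1]])) {
      id <- as.integer(gsub("[\x04\x05]", "", ph))
      piece <- gsub(ph, paste0("[", masked$comments[id], "]"), piece,
                    fixed = TRUE)
    }
  }
  piece
}

# Strip one level of quoting from a NEXUS name token.
.unquote_name <- function(x) {
  x <- trimws(x)
  if (grepl("^'.*'$", x))
    x <- gsub("''", "'", substr(x, 2L, nchar(x) - 1L), fixed = TRUE)
  x
}

#' Read trees from a NEXUS document
#'
#' Parses the `TREES` block of a NEXUS file (or literal string, or gzipped
#' file): every `TREE <name> = [rooting-hint] <newick>;` statement becomes one
#' tree, in file order, and `TRANSLATE` tokens are substituted by their taxon
#' labels before the trees are returned.
#'
#' @param source NEXUS text or file path (gzip detected by magic bytes).
#' @return A `nexus_document`: a list with `trees` (named list of
#'   `treekit_tree`, in file order) and `translate` (named character vector,
#'   possibly empty).
#' @examples
#' doc <- read_tree_nexus(paste(
#'   "#NEXUS", "BEGIN TREES;",
#'   "  TRANSLATE 1 Alpha, 2 Beta;",
#'   "  TREE T1 = (1:1,2:2);", "END;", sep = "\n"))
#' names(doc$trees)
#' @export
read_tree_nexus <- function(source) {
  text <- .source_text(source)
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
    stop_parse("not a NEXUS document (missing #NEXUS header)")
  masked <- .mask_special(text)
  s <- masked$text

  beg <- regexpr("begin\\s+trees\\s*;", s, ignore.case = TRUE, perl = TRUE)
  if (beg == -1L)
    stop_parse("no TREES block found")
  body_start <- beg + attr(beg, "match.length")
  rest <- substr(s, body_start, nchar(s))
  endm <- regexpr("\\bend\\s*;|\\bendblock\\s*;", rest,
                  ignore.case = TRUE, perl = TRUE)
  if (endm == -1L)
    stop_parse("unterminated TREES block (no END;)")
  body <- substr(rest, 1L, endm - 1L)

  stmts <- strsplit(body, ";", fixed = TRUE)[[1]]
  stmts <- stmts[nzchar(trimws(stmts))]

  translate <- character(0)
  tree_names <- character(0)
  trees <- list()

  for (st in stmts) {
    st_trim <- trimws(st)
    if (grepl("^translate\\b", st_trim, ignore.case = TRUE)) {
      tbl <- sub("^translate\\s*", "", st_trim, ignore.case = TRUE)
      entries <- strsplit(tbl, ",", fixed = TRUE)[[1]]
      for (en in entries) {
        en <- trimws(en)
        if (!nzchar(en)) next
        sp <- regexpr("\\s+", en)
        if (sp == -1L)
          stop_parse(sprintf("malformed TRANSLATE entry: \"%s\"",
                             .unmask_text(en, masked)))
        tok <- .unquote_name(.unmask_text(substr(en, 1L, sp - 1L), masked))
        lab <- .unquote_name(.unmask_text(
          substr(en, sp + attr(sp, "match.length"), nchar(en)), masked))
        translate[tok] <- lab
      }
    } else if (grepl("^u?tree\\b", st_trim, ignore.case = TRUE)) {
      rhs <- sub("^u?tree\\s+", "", st_trim, ignore.case = TRUE)
      eq <- regexpr("=", rhs, fixed = TRUE)
      if (eq == -1L)
        stop_parse(sprintf("malformed TREE statement: \"%s\"",
                           .unmask_text(st_trim, masked)))
      nm <- .unquote_name(.unmask_text(substr(rhs, 1L, eq - 1L), masked))
      nw <- .unmask_text(trimws(substr(rhs, eq + 1L, nchar(rhs))), masked)
      tr <- read_tree_newick(paste0(nw, ";"))
      if (grepl("^\\s*utree\\b", st_trim, ignore.case = TRUE))
        tr$is_rooted <- FALSE
      tree_names <- c(tree_names, nm)
      trees[[length(trees) + 1L]] <- tr
    }
    # other statements (e.g. LINK) are ignored
  }

  if (length(translate)) {
    for (tr in trees) {
      it <- .stack_new(tr$root)
      while (!is.null(u <- .stack_pop_push_children(it))) {
        # tokens name taxa, which sit at leaves; internal labels (e.g.
        # support values) are left untouched
        if (length(u$children) == 0L && !is.null(u$label) &&
            !is.na(translate[u$label]))
          u$label <- unname(translate[u$label])
      }
    }
  }
  names(trees) <- tree_names
  structure(list(trees = trees, translate = translate),
            class = "nexus_document")
}

#' @export
print.nexus_document <- function(x, ...) {
  cat(sprintf("<nexus_document: %d tree(s)%s>\n", length(x$trees),
              if (length(x$translate))
                sprintf(", translate table of %d", length(x$translate))
              else ""))
  for (nm in names(x$trees)) {
    n <- num_nodes(x$trees[[nm]])
    cat(sprintf("  %s: %d leaves\n", nm, n[["leaves"]]))
  }
  invisible(x)
}
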