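# Newick reading/writing. The parser is single-pass over a vectorized token
# stream: one gregexpr() locates all structural characters, substring() lifts
# the text between them, and a single R loop (O(#tokens), not O(#characters))
# assembles nodes. Quoted labels and [comments] are masked out first so the
# structural scan never sees them; inputs without quotes/comments skip that
# step entirely, which is the fast path taken by large machine-written trees.

# ---- source handling ----

# A "source" is a literal tree string or a path. Anything containing ';', '('
# or a newline is text; otherwise it must name an existing file.
.source_is_path <- function(source) {
  length(source) == 1L && !grepl("[;(\n]", source) && file.exists(source)
}

#' Test whether a file is gzip-compressed
#'
#' Detection is by the gzip magic bytes `0x1f 0x8b`, never by file extension.
#'
#' @param path Path to an existing file.
#' @return Logical scalar.
#' @export
is_gzip_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Resolve a source to its text, decompressing gzip transparently.
.source_text <- function(source) {
  if (!is.character(source) || length(source) < 1L)
    stop_invalid_value("`source` must be a character string or file path")
  if (length(source) > 1L) return(paste(source, collapse = "\n"))
  if (!.source_is_path(source)) return(source)
  gz <- is_gzip_file(source)
  con <- if (gz) gzfile(source, "rt") else file(source, "rt")
  on.exit(close(con))
  fail <- function(c) stop_io(sprintf("cannot read %s%s: %s", source,
                                      if (gz) " (gzip)" else "",
                                      conditionMessage(c)))
  # a warning while decompressing means a truncated/corrupt stream
  lines <- withCallingHandlers(
    tryCatch(readLines(con, warn = FALSE), error = fail),
    warning = fail)
  paste(lines, collapse = "\n")
}

# ---- masking of quoted labels and comments ----

# Replaces 'quoted labels' by \x02<id>\x03 and [comments] by \x04<id>\x05 so
# that structural characters inside them are invisible to the tokenizer.
.mask_special <- function(s) {
  if (!grepl("['\\[]", s, perl = TRUE))
    return(list(text = s, quotes = character(), comments = character()))
  m <- gregexpr("['\\[\\]]", s, perl = TRUE)[[1]]
  pos <- as.integer(m)
  chars <- substring(s, pos, pos)
  np <- length(pos)
  chunks <- character(0)
  quotes <- character(0)
  comments <- character(0)
  last <- 1L
  i <- 1L
  while (i <= np) {
    p <- pos[i]
    if (p < last) { i <- i + 1L; next }
    c1 <- chars[i]
    if (c1 == "'") {
      # find the closing quote; '' inside is an escaped literal quote
      j <- i + 1L
      close_at <- NA_integer_
      while (j <= np) {
        if (chars[j] == "'") {
          if (j + 1L <= np && chars[j + 1L] == "'" && pos[j + 1L] == pos[j] + 1L) {
            j <- j + 2L
          } else {
            close_at <- pos[j]
            break
          }
        } else {
          j <- j + 1L
        }
      }
      if (is.na(close_at))
        stop_parse("unterminated quoted label", offset = p)
      content <- gsub("''", "'", substr(s, p + 1L, close_at - 1L), fixed = TRUE)
      quotes <- c(quotes, content)
      chunks <- c(chunks, substr(s, last, p - 1L),
                  sprintf("\x02%d\x03", length(quotes)))
      last <- close_at + 1L
      i <- j + 1L
    } else if (c1 == "[") {
      j <- i + 1L
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) stop_parse("unterminated [comment]", offset = p)
      comments <- c(comments, substr(s, p + 1L, pos[j] - 1L))
      chunks <- c(chunks, substr(s, last, p - 1L),
                  sprintf("\x04%d\x05", length(comments)))
      last <- pos[j] + 1L
      i <- j + 1L
    } else {
      i <- i + 1L  # stray ']' outside a comment: left in place
    }
  }
  chunks <- c(chunks, substr(s, last, nchar(s)))
  list(text = paste(chunks, collapse = ""), quotes = quotes,
       comments = comments)
}

# Resolve a masked token: substitute quoted-label placeholders, pull out
# comment ids. Returns list(text=, comments=integer ids).
.resolve_token <- function(tk, masked) {
  cm <- integer(0)
  if (grepl("\x04", tk, fixed = TRUE)) {
    mm <- gregexpr("\x04([0-9]+)\x05", tk)[[1]]
    ids <- regmatches(tk, gregexpr("\x04([0-9]+)\x05", tk))[[1]]
    cm <- as.integer(gsub("[\x04\x05]", "", ids))
    tk <- gsub("\x04[0-9]+\x05", "", tk)
  }
  tk <- trimws(tk)
  if (grepl("\x02", tk, fixed = TRUE)) {
    mm <- regmatches(tk, gregexpr("\x02([0-9]+)\x03", tk))[[1]]
    for (ph in mm) {
      id <- as.integer(gsub("[\x02\x03]", "", ph))
      tk <- sub(ph, masked$quotes[id], tk, fixed = TRUE)
    }
  }
  list(text = tk, comments = cm)
}

# ---- the parser ----

# Parses all ';'-terminated statements in `text`. Returns list of treekit_tree.
.parse_newick_text <- function(text, max_trees = Inf) {
  masked <- .mask_special(text)
  s <- masked$text
  special <- length(masked$quotes) > 0L || length(masked$comments) > 0L

  m <- gregexpr("[(),:;]", s)[[1]]
  pos <- as.integer(m)
  if (pos[1] == -1L)
    stop_parse("no ';'-terminated Newick statement found")
  chs <- substring(s, pos, pos)
  starts <- c(1L, pos + 1L)
  ends <- c(pos - 1L, nchar(s))
  toks <- substring(s, starts, ends)  # toks[i] is the text before pos[i]
  toks <- trimws(toks)
  np <- length(pos)

  if (!any(chs == ";"))
    stop_parse("missing ';' statement terminator", offset = nchar(text))
  tail_txt <- trimws(toks[np + 1L])
  if (nzchar(gsub("\x04[0-9]+\x05", "", tail_txt)))
    stop_parse("trailing text after final ';'", offset = pos[np] + 1L)

  trees <- list()
  is_rooted <- TRUE
  root <- .bare_node()
  cur <- root
  have_content <- FALSE
  depth <- 0L
  comment_n <- 0L

  set_label <- function(u, tk) {
    if (special) {
      r <- .resolve_token(tk, masked)
      if (length(r$comments)) {
        for (id in r$comments) {
          cmt <- masked$comments[id]
          if (!have_content && identical(toupper(cmt), "&R")) {
            is_rooted <<- TRUE
          } else if (!have_content && identical(toupper(cmt), "&U")) {
            is_rooted <<- FALSE
          } else {
            comment_n <<- comment_n + 1L
            u$attributes[[paste0("comment", comment_n)]] <- cmt
          }
        }
      }
      tk <- r$text
    }
    if (nzchar(tk)) u$label <- tk
  }

  i <- 1L
  skip_tok <- FALSE
  while (i <= np) {
    c1 <- chs[i]
    tk <- if (skip_tok) "" else toks[i]
    skip_tok <- FALSE
    if (c1 == "(") {
      if (nzchar(tk) && nzchar(gsub("\x04[0-9]+\x05", "", tk)))
        stop_parse("unexpected text before '('", offset = pos[i])
      if (special && nzchar(tk)) set_label(cur, tk)  # pick up [&R]-style hints
      have_content <- TRUE
      k <- .bare_node()
      k$parent <- cur
      cur$children[[length(cur$children) + 1L]] <- k
      cur <- k
      depth <- depth + 1L
    } else if (c1 == ",") {
      if (depth == 0L)
        stop_parse("',' outside parentheses", offset = pos[i])
      set_label(cur, tk)
      p <- cur$parent
      k <- .bare_node()
      k$parent <- p
      p$children[[length(p$children) + 1L]] <- k
      cur <- k
    } else if (c1 == ")") {
      if (depth == 0L)
        stop_parse("unbalanced ')'", offset = pos[i])
      set_label(cur, tk)
      cur <- cur$parent
      depth <- depth - 1L
    } else if (c1 == ":") {
      set_label(cur, tk)
      if (i == np)
        stop_parse("dangling ':' at end of input", offset = pos[i])
      num_tok <- toks[i + 1L]
      if (special) num_tok <- .resolve_token(num_tok, masked)$text
      val <- suppressWarnings(as.numeric(num_tok))
      if (is.na(val))
        stop_parse(sprintf("dangling ':' (expected a branch length, got \"%s\")",
                           num_tok), offset = pos[i])
      if (val < 0)
        stop_parse(sprintf("negative branch length %g", val), offset = pos[i])
      cur$edge_length <- val
      skip_tok <- TRUE
      have_content <- TRUE
    } else if (c1 == ";") {
      if (depth != 0L)
        stop_parse("unbalanced '(' (statement ended inside parentheses)",
                   offset = pos[i])
      set_label(cur, tk)
      trees[[length(trees) + 1L]] <- {
        tr <- new.env(parent = emptyenv(), size = 4L)
        tr$root <- root
        tr$is_rooted <- is_rooted
        class(tr) <- "treekit_tree"
        tr
      }
      if (length(trees) >= max_trees) return(trees)
      root <- .bare_node()
      cur <- root
      is_rooted <- TRUE
      have_content <- FALSE
      comment_n <- 0L
    }
    i <- i + 1L
  }
  if (chs[np] != ";")
    stop_parse("missing ';' statement terminator", offset = pos[np])
  if (length(trees) == 0L)
    stop_parse("no ';'-terminated Newick statement found")
  trees
}

#' Read a tree from Newick
#'
#' Accepts a literal Newick string, a path to a plain-text file, or a path to
#' a gzip-compressed file (detected by magic bytes, not extension). Supports
#' nested parentheses, leaf and internal labels, `:`-prefixed branch lengths
#' in decimal or scientific notation, single-quoted labels with `''` escapes,
#' square-bracket comments (kept verbatim in the node's attribute list, keyed
#' `comment1`, `comment2`, ... in reading order), and a leading `[&R]`/`[&U]`
#' rootedness hint. Underscores in unquoted labels are preserved verbatim.
#' If the input holds several `;`-terminated statements, the first tree is
#' returned; use [read_trees_newick()] for all of them.
#'
#' @param source Newick text or file path.
#' @return A `treekit_tree`.
#' @examples
#' tr <- read_tree_newick("((A:1,B:1):1,C:2);")
#' num_nodes(tr)
#' @export
read_tree_newick <- function(source) {
  .parse_newick_text(.source_text(source), max_trees = 1L)[[1L]]
}

#' @rdname read_tree_newick
#' @return `read_trees_newick()`: a list of `treekit_tree`, one per statement.
#' @export
read_trees_newick <- function(source) {
  .parse_newick_text(.source_text(source))
}

#' Read a gzip-compressed Newick file
#'
#' Same as [read_tree_newick()] but insists that the file really is
#' gzip-compressed; the result is identical to parsing the decompressed text.
#'
#' @param path Path to a gzip file whose content is Newick.
#' @return A `treekit_tree`.
#' @export
read_tree_gzip <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (!is_gzip_file(path))
    stop_io(sprintf("%s does not start with the gzip magic bytes", path))
  read_tree_newick(path)
}

# ---- the writer ----

# Numbers serialize with the shortest of 15/17 significant digits that
# round-trips the stored double, unless a precision is requested.
.fmt_lengths <- function(x, precision = NULL) {
  if (!is.null(precision))
    return(sprintf("%.*f", precision, x))
  out <- sprintf("%.15g", x)
  bad <- suppressWarnings(as.numeric(out)) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out
}

.quote_label <- function(lab) {
  needs <- grepl("[][(),:;'[:space:]]", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs], fixed = TRUE), "'")
  lab
}

#' Serialize a tree to Newick
#'
#' Emits children in stored order, quotes labels containing structural
#' characters or whitespace, writes `:length` for every node with a stored
#' edge length (missing lengths are omitted, not written as 0), and ends with
#' `;`. Iterative, so arbitrarily deep trees serialize safely.
#'
#' @param tree A `treekit_tree` (or bare root node).
#' @param path Optional output file path; written gzip-compressed when it
#'   ends in `.gz`. When `NULL` (default) the text is returned only.
#' @param precision Optional number of decimal digits for branch lengths;
#'   default is the shortest representation that round-trips the value.
#' @return The Newick string (invisibly when `path` is given).
#' @examples
#' write_tree_newick(read_tree_newick("((A:1,B:1):1,C:2);"))
#' @export
write_tree_newick <- function(tree, path = NULL, precision = NULL) {
  root <- .as_root(tree)
  toks <- character(1024L)
  nt <- 0L
  emit <- function(x) {
    nt <<- nt + 1L
    if (nt > length(toks)) length(toks) <<- 2L * length(toks)
    toks[nt] <<- x
  }
  tail_token <- function(u) {
    lab <- if (is.null(u$label)) "" else .quote_label(u$label)
    len <- if (is.null(u$edge_length)) "" else
      paste0(":", .fmt_lengths(u$edge_length, precision))
    paste0(lab, len)
  }
  s_node <- vector("list", 64L)
  s_child <- integer(64L)
  s_node[[1L]] <- root; s_child[1L] <- 0L
  top <- 1L
  while (top > 0L) {
    u <- s_node[[top]]
    ci <- s_child[top] + 1L
    nc <- length(u$children)
    if (nc == 0L) {
      emit(tail_token(u))
      top <- top - 1L
    } else if (ci > nc) {
      emit(paste0(")", tail_token(u)))
      top <- top - 1L
    } else {
      emit(if (ci == 1L) "(" else ",")
      s_child[top] <- ci
      top <- top + 1L
      if (top > length(s_node)) {
        length(s_node) <- 2L * length(s_node)
        length(s_child) <- length(s_node)
      }
      s_node[[top]] <- u$children[[ci]]
      s_child[top] <- 0L
    }
  }
  emit(";")
  length(toks) <- nt
  out <- paste(toks, collapse = "")
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    tryCatch(writeLines(out, con),
             error = function(e) stop_io(sprintf("cannot write %s: %s", path,
                                                 conditionMessage(e))))
    return(invisible(out))
  }
  out
}
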