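#' Read a tree from a Newick string
#'
#' Parses one Newick statement into an [rtree()]. Per-node sizes are read
#' from NHX-style comments of the form `[&&NHX:size=X]` placed after a
#' node's label (or branch length); this keeps the size annotation out of
#' the branch-length colon field. Branch lengths are parsed and discarded:
#' J1 and the Sackin indices are functions of topology and node sizes only.
#'
#' Unannotated nodes receive default sizes according to `default_sizes`:
#' \describe{
#'   \item{`"leafy"`}{leaves size 1, internal nodes size 0 (the cladogram
#'     convention; default).}
#'   \item{`"unit"`}{all nodes size 1.}
#'   \item{`"explicit"`}{annotations are the only source; unannotated
#'     nodes get size 0.}
#' }
#' Explicit annotations always win over the default mode.
#'
#' @param text a single Newick statement (trailing `;` optional).
#' @param default_sizes size convention for unannotated nodes.
#' @return An [rtree()].
#' @examples
#' parse_newick("((A,B),C);")
#' parse_newick("((A[&&NHX:size=4],B[&&NHX:size=2]),C);")
#' @export
parse_newick <- function(text, default_sizes = c("leafy", "unit", "explicit")) {
  default_sizes <- match.arg(default_sizes)
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  pos <- 1L
  nchar_s <- nchar(s)
  peek <- function() if (pos > nchar_s) "" else substr(s, pos, pos)
  fail <- function(msg) stop(sprintf("Newick parse error at position %d: %s", pos, msg),
                             call. = FALSE)

  parent <- integer(0)
  size <- numeric(0)
  label <- character(0)
  has_size <- logical(0)

  new_node <- function(par) {
    parent[length(parent) + 1L] <<- par
    size[length(size) + 1L] <<- NA_real_
    label[length(label) + 1L] <<- NA_character_
    has_size[length(has_size) + 1L] <<- FALSE
    length(parent)
  }

  read_label <- function() {
    start <- pos
    while (pos <= nchar_s && !grepl("[][(),:;]", substr(s, pos, pos))) pos <<- pos + 1L
    trimws(substr(s, start, pos - 1L))
  }
  read_comment <- function() {
    # returns size annotation or NA; pos sits on '['
    start <- pos
    end <- regexpr("]", substr(s, pos, nchar_s), fixed = TRUE)
    if (end < 0L) fail("unterminated comment")
    com <- substr(s, pos, pos + end - 1L)
    pos <<- pos + end
    m <- regmatches(com, regexec("&&NHX.*?:size=([^]:,]+)", com))[[1]]
    if (length(m) == 2L) {
      val <- suppressWarnings(as.numeric(m[2]))
      if (is.na(val)) fail(sprintf("invalid size annotation in %s", com))
      if (val < 0) stop("negative node size in Newick annotation", call. = FALSE)
      val
    } else NA_real_
  }
  read_suffix <- function(id) {
    # label? comment? (:length)? comment?
    lb <- read_label()
    if (nzchar(lb)) label[id] <<- lb
    repeat {
      c0 <- peek()
      if (c0 == "[") {
        v <- read_comment()
        if (!is.na(v)) { size[id] <<- v; has_size[id] <<- TRUE }
      } else if (c0 == ":") {
        pos <<- pos + 1L
        len <- read_label() # branch length, ignored
        if (!nzchar(len)) fail("empty branch length")
      } else break
    }
  }
  parse_subtree <- function(par) {
    id <- new_node(par)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_subtree(id)
        c0 <- peek()
        if (c0 == ",") { pos <<- pos + 1L; next }
        if (c0 == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    read_suffix(id)
    id
  }

  parse_subtree(NA_integer_)
  if (peek() == ";") pos <- pos + 1L
  if (pos <= nchar_s && nzchar(trimws(substr(s, pos, nchar_s))))
    fail("trailing characters after tree")

  tr <- rtree(parent, ifelse(has_size, size, 0), label)
  is_leaf <- vapply(tr$children, length, 1L) == 0L
  default_size <- switch(default_sizes,
    leafy = ifelse(is_leaf, 1, 0),
    unit = rep(1, length(parent)),
    explicit = rep(0, length(parent)))
  tr$size <- ifelse(has_size, size, default_size)
  tr
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()]: node sizes that deviate from the leafy
#' convention (leaves 1, internal 0) are serialized as `[&&NHX:size=X]`
#' annotations, so that `parse_newick(write_newick(t))` is isomorphic to
#' `t` with identical sizes.
#'
#' @param tree an [rtree()].
#' @return A single Newick statement ending in `;`.
#' @export
write_newick <- function(tree) {
  is_leaf <- vapply(tree$children, length, 1L) == 0L
  fmt_node <- function(v) {
    lb <- tree$label[v]
    out <- if (is.na(lb)) "" else lb
    def <- if (is_leaf[v]) 1 else 0
    if (tree$size[v] != def)
      out <- paste0(out, "[&&NHX:size=", format(tree$size[v], digits = 15), "]")
    out
  }
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) return(fmt_node(v))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")", fmt_node(v))
  }
  paste0(rec(tree$root), ";")
}

#' Read or write multi-tree Newick files
#'
#' One Newick statement per line (blank lines ignored).
#'
#' @param path file path.
#' @param default_sizes passed to [parse_newick()].
#' @return `read_newick_file()`: a list of [rtree()] objects.
#' @export
read_newick_file <- function(path, default_sizes = "leafy") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, parse_newick, default_sizes = default_sizes)
}

#' @rdname read_newick_file
#' @param trees list of [rtree()] objects.
#' @param header optional comment lines (written with a leading `#`).
#' @export
write_newick_file <- function(trees, path, header = NULL) {
  out <- vapply(trees, write_newick, "")
  if (!is.null(header)) out <- c(paste0("# ", header), out)
  writeLines(out, path)
  invisible(path)
}
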