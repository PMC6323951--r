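# Newick / NHX parsing and formatting shared by the species- and gene-tree
# readers. The dialect is deliberately small: unquoted labels, optional
# ':length', and optional '[&&NHX:key=value:...]' comments after the label or
# length. No other installed package reads NHX tags, hence the bespoke parser.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @noRd
nwk_parse <- function(text) {
  text <- gsub("[[:space:]]+", "", paste(text, collapse = ""))
  s <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(s)
  i <- 1L
  peek <- function() if (i <= n) s[[i]] else ""
  adv <- function() i <<- i + 1L
  fail <- function(msg) {
    stop(sprintf("newick format error near character %d: %s", i, msg),
         call. = FALSE)
  }
  special <- c("(", ")", ",", ":", ";", "[", "]")
  read_token <- function() {
    j <- i
    while (i <= n && !(s[[i]] %in% special)) adv()
    if (i > j) paste(s[j:(i - 1L)], collapse = "") else ""
  }
  read_number <- function() {
    tok <- read_token()
    x <- suppressWarnings(as.numeric(tok))
    if (is.na(x)) fail(sprintf("invalid branch length '%s'", tok))
    x
  }
  read_nhx <- function() {
    adv()  # consume '['
    head <- read_token()
    if (!identical(head, "&&NHX")) {
      fail("unsupported comment (only [&&NHX:...] comments are understood)")
    }
    tags <- character(0)
    while (peek() == ":") {
      adv()
      kv <- read_token()
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0L) {
        # values may themselves contain ':' (e.g. FAM1:0000 stable IDs):
        # a segment without '=' continues the previous tag's value
        if (!length(tags)) {
          fail(sprintf("malformed NHX tag '%s' (expected key=value)", kv))
        }
        tags[[length(tags)]] <- paste0(tags[[length(tags)]], ":", kv)
      } else {
        tags[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
      }
    }
    if (peek() != "]") fail("unterminated NHX comment")
    adv()
    tags
  }
  read_clade <- function() {
    children <- list()
    if (peek() == "(") {
      adv()
      repeat {
        children[[length(children) + 1L]] <- read_clade()
        if (peek() == ",") { adv(); next }
        if (peek() == ")") { adv(); break }
        fail("expected ',' or ')'")
      }
    }
    label <- read_token()
    blen <- NA_real_
    tags <- character(0)
    if (peek() == ":") { adv(); blen <- read_number() }
    if (peek() == "[") {
      tags <- read_nhx()
      if (peek() == ":") { adv(); blen <- read_number() }
    }
    list(label = label, blen = blen, nhx = tags, children = children)
  }
  if (n == 0L) fail("empty input")
  root <- read_clade()
  if (peek() != ";") fail("missing terminating ';'")
  root
}

#' @noRd
nwk_format <- function(node) {
  kids <- ""
  if (length(node$children)) {
    kids <- paste0("(", paste(vapply(node$children, nwk_format, character(1)),
                              collapse = ","), ")")
  }
  len <- if (!is.na(node$blen %||% NA_real_)) {
    paste0(":", sprintf("%.10g", node$blen))
  } else ""
  tag <- if (length(node$nhx)) {
    paste0("[&&NHX:", paste(names(node$nhx), unlist(node$nhx),
                            sep = "=", collapse = ":"), "]")
  } else ""
  paste0(kids, node$label %||% "", len, tag)
}

nhx_tag <- function(tags, key) {
  if (key %in% names(tags)) tags[[key]] else NA_character_
}

read_text_or_path <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either 'path' or 'text' must be given", call. = FALSE)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    text <- readLines(path, warn = FALSE)
  }
  paste(text, collapse = "\n")
}
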