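# Indexing of annotated module libraries. A library is an ordinary model file
# in which named blocks are delimited by `//%START <name>` / `//%END` marker
# lines; everything outside a block is ignored. Generated models that used
# insertion markers are themselves indexable libraries (hierarchical reuse).

# Marker recognition is whitespace-tolerant: published listings contain both
# `//%END name` and `// %END name`.
match_marker <- function(line) {
  m <- regexec("^\\s*//\\s*%\\s*(START|END)\\b\\s*([A-Za-z_][A-Za-z0-9_]*)?",
               line, perl = TRUE)
  r <- regmatches(line, m)[[1]]
  if (!length(r)) return(NULL)
  list(kind = r[2], name = if (length(r) >= 3 && nzchar(r[3])) r[3] else NA_character_)
}

#' Index an annotated library file into named module blocks
#'
#' Every `//%START <name>` opens a block closed by the next `//%END`; block
#' contents exclude the marker lines, and text outside any block is ignored.
#' An `//%END` closes the most recently opened block regardless of the name
#' that follows; a name mismatch is a warning, not an error (published
#' libraries close blocks under case-mismatched names). Nested `//%START` is
#' an error, as are an `//%END` with no open block, an unclosed block at end
#' of file, and duplicate block names.
#'
#' @param text Character vector of lines (or one newline-joined string), or a
#'   file path when `is_path = TRUE`.
#' @param origin Name recorded for diagnostics.
#' @param is_path Read `text` as a file path.
#' @return An `mpc_library` with ordered, uniquely named blocks.
#' @examples
#' lib <- index_library(c("//%START m", "x:t = -k*x;", "//%END m"))
#' fetch_module(lib, "m")
#' @export
index_library <- function(text, origin = "<text>", is_path = FALSE) {
  if (is_path) {
    origin <- text
    text <- readLines(text, warn = FALSE)
  }
  lines <- split_lines(text)
  blocks <- list()
  open_name <- NULL
  open_start <- NA_integer_
  buf <- character()
  buf_nos <- integer()
  for (i in seq_along(lines)) {
    mk <- match_marker(lines[[i]])
    if (is.null(mk)) {
      if (!is.null(open_name)) {
        buf <- c(buf, lines[[i]])
        buf_nos <- c(buf_nos, i)
      }
      next
    }
    if (mk$kind == "START") {
      if (!is.null(open_name))
        stop(sprintf("%s:%d: nested //%%START '%s' inside open block '%s'",
                     origin, i, mk$name, open_name), call. = FALSE)
      if (is.na(mk$name))
        stop(sprintf("%s:%d: //%%START without a block name", origin, i), call. = FALSE)
      if (mk$name %in% names(blocks))
        stop(sprintf("%s:%d: duplicate block name '%s' (first declared at line %d)",
                     origin, i, mk$name, blocks[[mk$name]]$start_lineno), call. = FALSE)
      open_name <- mk$name
      open_start <- i
      buf <- character(); buf_nos <- integer()
    } else {
      if (is.null(open_name))
        stop(sprintf("%s:%d: //%%END with no open block", origin, i), call. = FALSE)
      if (!is.na(mk$name) && !identical(mk$name, open_name))
        warning(sprintf("%s:%d: //%%END name '%s' does not match open block '%s'",
                        origin, i, mk$name, open_name), call. = FALSE)
      blocks[[open_name]] <- list(name = open_name, lines = buf,
                                  linenos = buf_nos, origin = origin,
                                  start_lineno = open_start)
      open_name <- NULL
    }
  }
  if (!is.null(open_name))
    stop(sprintf("%s: end of file with open block '%s' (started at line %d)",
                 origin, open_name, open_start), call. = FALSE)
  structure(list(file = origin, blocks = blocks), class = "mpc_library")
}

#' @export
print.mpc_library <- function(x, ...) {
  cat(sprintf("<mpc_library> %s: %d modules\n", x$file, length(x$blocks)))
  for (b in x$blocks)
    cat(sprintf("  %-20s %d lines (from line %d)\n",
                b$name, length(b$lines), b$start_lineno))
  invisible(x)
}

#' List module names in a library
#' @param lib An `mpc_library`.
#' @return Character vector of block names in file order.
#' @export
module_names <- function(lib) {
  stopifnot(inherits(lib, "mpc_library"))
  names(lib$blocks)
}

#' Fetch a module's lines from a library
#'
#' @param lib An `mpc_library` from [index_library()].
#' @param name Module name.
#' @return Character vector: the block's lines verbatim, marker lines excluded.
#' @export
fetch_module <- function(lib, name) {
  stopifnot(inherits(lib, "mpc_library"))
  if (!name %in% names(lib$blocks))
    stop(sprintf("no module '%s' in %s; available: %s", name, lib$file,
                 paste(names(lib$blocks), collapse = ", ")), call. = FALSE)
  lib$blocks[[name]]$lines
}
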