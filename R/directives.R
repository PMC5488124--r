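# Directive parsing and the construction pipeline. Directive lines start with
# `//%` so that, to the downstream model compiler, they are ordinary comments.
# Pipeline order in build_model(): (1) read lines, (2) merge `//%`
# continuation lines of unclosed directives, (3) consume REPLACE groups and
# expand all subsequent lines (directive lines included), (4) execute GET
# splices with renaming, (5) merge equations named by COLLECT, (6) rewrite
# INSERTSTART/INSERTEND into library markers, then emit.

DIRECTIVE_KEYWORDS <- c("REPLACE", "GET", "COLLECT", "INSERTSTART", "INSERTEND",
                        "START", "END")

directive_prefix <- function(line) {
  m <- regexpr("^\\s*//\\s*%", line, perl = TRUE)
  if (m == -1L) return(NULL)
  attr(m, "match.length")
}

# Position of a `//` comment start outside double quotes, searching from
# `from` (past the directive's own `//%` prefix). -1 if none.
comment_start <- function(line, from = 1L) {
  in_quote <- FALSE
  n <- nchar(line)
  i <- from
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch == '"') in_quote <- !in_quote
    if (!in_quote && ch == "/" && i < n && substr(line, i + 1L, i + 1L) == "/")
      return(i)
    i <- i + 1L
  }
  -1L
}

# Split a directive line into content (comment stripped) and trailing comment.
split_directive_comment <- function(line) {
  p <- directive_prefix(line)
  cs <- comment_start(line, from = p + 1L)
  if (cs == -1L) return(list(content = line, comment = NA_character_))
  list(content = substr(line, 1L, cs - 1L),
       comment = substr(line, cs, nchar(line)))
}

# Parenthesis balance outside quotes.
paren_balance <- function(text) {
  in_quote <- FALSE
  bal <- 0L
  for (ch in strsplit(text, "", fixed = TRUE)[[1]]) {
    if (ch == '"') in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "(") bal <- bal + 1L
      if (ch == ")") bal <- bal - 1L
    }
  }
  bal
}

extract_quoted <- function(text) {
  m <- gregexpr('"([^"]*)"', text)[[1]]
  if (m[1] == -1L) return(character())
  gsub('^"|"$', "", regmatches(text, list(m))[[1]])
}

#' Parse one directive line
#'
#' Recognizes `REPLACE`, `GET`, `COLLECT`, `INSERTSTART`, `INSERTEND`,
#' `START`, `END` and bare `//%` continuation lines; a trailing `// comment`
#' on the directive is stripped (and preserved where it matters, on insertion
#' markers). Non-directive lines return `NULL` (passthrough). A `//%`
#' followed by an unknown keyword is an error.
#'
#' @param line Character scalar.
#' @param lineno Line number for diagnostics.
#' @return A list describing the directive (`type` plus type-specific
#'   fields), or `NULL` for passthrough lines. A `GET` whose argument list is
#'   not closed on this line has `complete = FALSE`; callers append the
#'   following `//%` continuation lines until the parentheses balance (see
#'   [build_model()]).
#' @examples
#' parse_directive('//%GET CodeLibrary.mod reactionCalc ("A=A2","B=B2")')
#' parse_directive("real Flow = 1 ml/(g*min);")  # NULL: not a directive
#' @export
parse_directive <- function(line, lineno = 1L) {
  p <- directive_prefix(line)
  if (is.null(p)) return(NULL)
  rest <- substr(line, p + 1L, nchar(line))
  kw <- regmatches(rest, regexpr("^\\s*[A-Za-z]+", rest))
  kw <- if (length(kw)) trimws(kw) else ""
  if (!nzchar(kw)) {
    sc <- split_directive_comment(line)
    return(list(type = "continuation",
                content = substr(sc$content, p + 1L, nchar(sc$content)),
                lineno = lineno))
  }
  if (!kw %in% DIRECTIVE_KEYWORDS)
    stop(sprintf("line %d: unknown directive '//%%%s'", lineno, kw), call. = FALSE)
  sc <- split_directive_comment(line)
  body <- sub(paste0("^\\s*", kw), "",
              substr(sc$content, p + 1L, nchar(sc$content)))
  switch(kw,
    REPLACE = parse_replace_body(body, lineno),
    GET = parse_get_body(body, lineno, comment = sc$comment),
    COLLECT = parse_collect_body(body, lineno),
    INSERTSTART = parse_insert_body(body, "start", lineno, sc$comment),
    INSERTEND = parse_insert_body(body, "end", lineno, sc$comment),
    START = list(type = "start", name = trimws(body), lineno = lineno),
    END = list(type = "end", name = trimws(body), lineno = lineno)
  )
}

parse_replace_body <- function(body, lineno) {
  pat <- paste0("%(", RE_IDENT, ")%\\s*=\\s*\\(([^)]*)\\)")
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] == -1L)
    stop(sprintf("line %d: REPLACE directive with no bindings: %s", lineno, body),
         call. = FALSE)
  hits <- regmatches(body, list(m))[[1]]
  bindings <- list()
  for (h in hits) {
    name <- sub(pat, "\\1", h, perl = TRUE)
    inner <- sub(pat, "\\2", h, perl = TRUE)
    values <- extract_quoted(inner)
    if (!length(values))
      stop(sprintf("line %d: REPLACE binding %%%s%% has no quoted values", lineno, name),
           call. = FALSE)
    if (name %in% names(bindings))
      stop(sprintf("line %d: placeholder %%%s%% bound twice in one REPLACE", lineno, name),
           call. = FALSE)
    bindings[[name]] <- values
  }
  sizes <- lengths(bindings)
  if (length(unique(sizes)) > 1L)
    stop(sprintf("line %d: REPLACE bindings advance in parallel but have unequal lengths (%s)",
                 lineno, paste(sizes, collapse = ", ")), call. = FALSE)
  list(type = "replace", bindings = bindings, declared_at = lineno)
}

parse_get_body <- function(body, lineno, comment = NA_character_) {
  m <- regexec(paste0("^\\s*(\\S+)\\s+(", RE_IDENT, ")\\s*(\\(.*)?$"), body)
  r <- regmatches(body, m)[[1]]
  if (!length(r) || !nzchar(r[2]))
    stop(sprintf("line %d: cannot parse GET directive: %s", lineno, body), call. = FALSE)
  args_part <- if (length(r) >= 4) r[4] else ""
  complete <- paren_balance(args_part) <= 0L
  renames <- character()
  if (complete && nzchar(trimws(args_part))) {
    pairs <- extract_quoted(args_part)
    for (p in pairs) {
      eq <- regexpr("=", p, fixed = TRUE)
      if (eq == -1L)
        stop(sprintf("line %d: GET rename pair without '=': \"%s\"", lineno, p),
             call. = FALSE)
      old <- trimws(substr(p, 1L, eq - 1L))
      new <- trimws(substr(p, eq + 1L, nchar(p)))
      if (old %in% names(renames)) {
        if (!identical(unname(renames[[old]]), new))
          stop(sprintf("line %d: conflicting renames for '%s': '%s' vs '%s'",
                       lineno, old, renames[[old]], new), call. = FALSE)
        next  # duplicate pair with identical value collapses silently
      }
      renames[[old]] <- new
    }
  }
  list(type = "get", library_ref = r[2], module_name = r[3],
       renames = renames, complete = complete, body = body,
       comment = comment, declared_at = lineno)
}

parse_collect_body <- function(body, lineno) {
  pats <- extract_quoted(body)
  if (length(pats) != 1L)
    stop(sprintf("line %d: COLLECT expects one quoted pattern: %s", lineno, body),
         call. = FALSE)
  list(type = "collect", lhs_pattern = pats[[1]], declared_at = lineno)
}

parse_insert_body <- function(body, kind, lineno, comment) {
  m <- regexec(paste0("^\\s*(", RE_IDENT, ")\\s*(.*)$"), body)
  r <- regmatches(body, m)[[1]]
  if (!length(r) || !nzchar(r[2]))
    stop(sprintf("line %d: INSERT%s without a section name", lineno, toupper(kind)),
         call. = FALSE)
  leftover <- trimws(r[3])
  list(type = paste0("insert", kind), section_name = r[2],
       leftover = if (nzchar(leftover)) leftover else NA_character_,
       comment = comment, lineno = lineno)
}

# ---- REPLACE expansion ------------------------------------------------------

placeholder_token <- function(name) paste0("%", name, "%")

group_contributes <- function(group, line) {
  any(vapply(names(group$bindings),
             function(n) grepl(placeholder_token(n), line, fixed = TRUE),
             TRUE))
}

substitute_group <- function(line, group, index) {
  for (n in names(group$bindings))
    line <- gsub(placeholder_token(n), group$bindings[[n]][index], line, fixed = TRUE)
  line
}

expand_one_line <- function(line, groups) {
  contrib <- Filter(function(g) group_contributes(g, line), groups)
  if (!length(contrib)) return(line)
  sizes <- vapply(contrib, function(g) length(g$bindings[[1]]), 1L)
  total <- prod(sizes)
  out <- character(total)
  for (k in seq_len(total)) {
    idx <- k - 1L
    text <- line
    # groups declared earlier vary fastest (innermost)
    for (gi in seq_along(contrib)) {
      i_g <- idx %% sizes[gi]
      idx <- idx %/% sizes[gi]
      text <- substitute_group(text, contrib[[gi]], i_g + 1L)
    }
    out[k] <- text
  }
  out
}

normalize_groups <- function(groups) {
  lapply(groups, function(g) {
    if (is.list(g) && identical(g$type, "replace")) return(g)
    if (is.list(g) && !is.null(g$bindings)) return(g)
    stopifnot(is.list(g) || (is.character(g) && !is.null(names(g))))
    list(type = "replace", bindings = as.list(g), declared_at = NA_integer_)
  })
}

#' Expand template lines over REPLACE groups
#'
#' Each group is a set of placeholder/value-list bindings that advance in
#' parallel; a line is replicated once per element of the cross product of
#' the index ranges of the groups whose placeholders occur in it, with
#' earlier-declared groups varying fastest. Substitution is plain-text
#' replacement of `%name%`.
#'
#' @param lines Character vector of template lines.
#' @param groups List of groups: each either a parsed `REPLACE` directive
#'   (from [parse_directive()]) or a named list/character vector of
#'   placeholder value vectors, in declaration order.
#' @return Character vector of expanded lines.
#' @examples
#' expand_replace("when(t=t.min)  %AB%%N%=0;",
#'                list(list(N = c("1", "2")), list(AB = c("A", "B", "C"))))
#' @export
expand_replace <- function(lines, groups) {
  groups <- normalize_groups(groups)
  unlist(lapply(split_lines(lines), expand_one_line, groups = groups),
         use.names = FALSE)
}

residual_placeholders <- function(line) {
  m <- gregexpr(paste0("%", RE_IDENT, "%"), line)[[1]]
  if (m[1] == -1L) return(character())
  gsub("%", "", regmatches(line, list(m))[[1]], fixed = TRUE)
}

# ---- GET --------------------------------------------------------------------

make_library_resolver <- function(base_dir, lib_paths) {
  cache <- new.env(parent = emptyenv())
  function(ref) {
    if (exists(ref, envir = cache)) return(get(ref, envir = cache))
    candidates <- c(file.path(base_dir, ref), file.path(lib_paths, ref), ref)
    hit <- candidates[file.exists(candidates)]
    if (!length(hit))
      stop(sprintf("cannot resolve module library '%s' (searched: %s)",
                   ref, paste(unique(candidates), collapse = ", ")), call. = FALSE)
    lib <- index_library(hit[[1]], is_path = TRUE)
    assign(ref, lib, envir = cache)
    lib
  }
}

#' Execute one GET directive
#'
#' Fetches the named module and pipes its lines through
#' [rename_identifiers()] with the directive's mapping. Rename keys that
#' match no identifier token in the module are reported with a warning.
#'
#' @param g A parsed `GET` directive from [parse_directive()].
#' @param libs A library resolver: an `mpc_library`, a named list of
#'   libraries keyed by file reference, or a function mapping a file
#'   reference to an `mpc_library`.
#' @return Character vector of renamed module lines.
#' @export
resolve_get <- function(g, libs) {
  stopifnot(identical(g$type, "get"))
  if (!isTRUE(g$complete))
    stop(sprintf("line %d: GET argument list is not closed", g$declared_at),
         call. = FALSE)
  lib <-
    if (inherits(libs, "mpc_library")) libs
    else if (is.function(libs)) libs(g$library_ref)
    else if (is.list(libs)) {
      if (!g$library_ref %in% names(libs))
        stop(sprintf("unknown library '%s'; available: %s", g$library_ref,
                     paste(names(libs), collapse = ", ")), call. = FALSE)
      libs[[g$library_ref]]
    } else stop("unsupported library resolver", call. = FALSE)
  lines <- fetch_module(lib, g$module_name)
  out <- rename_identifiers(lines, g$renames)
  unused <- setdiff(names(g$renames), attr(out, "used_keys"))
  if (length(unused))
    warning(sprintf("line %d: GET %s: rename key(s) %s match no identifier in the module",
                    g$declared_at, g$module_name,
                    paste(sprintf("'%s'", unused), collapse = ", ")), call. = FALSE)
  as.character(out)
}

# ---- COLLECT ----------------------------------------------------------------

# Light-weight equation recognition on a raw line: returns list(key, rhs)
# where key is "<lhs>:<dom>..." , or NULL.
match_equation_line <- function(line) {
  cs <- comment_start(line)
  body <- if (cs > 0L) substr(line, 1L, cs - 1L) else line
  m <- regexec(paste0("^\\s*(", RE_IDENT, ")((?:\\s*:\\s*", RE_IDENT,
                      ")*)\\s*=(.*);\\s*$"), body, perl = TRUE)
  r <- regmatches(body, m)[[1]]
  if (!length(r) || !nzchar(r[2])) return(NULL)
  derivs <- regmatches(r[3], gregexpr(RE_IDENT, r[3]))[[1]]
  key <- paste(c(r[2], derivs), collapse = ":")
  list(key = key, rhs = trimws(r[4]))
}

join_contributions <- function(rhss) {
  out <- rhss[[1]]
  for (r in rhss[-1])
    out <- paste0(out, if (startsWith(r, "-")) " " else " +", r)
  out
}

#' Merge equations named by a COLLECT directive
#'
#' All equations in the stream whose left-hand side (identifier plus
#' derivative suffix, e.g. `A2:t`) matches one of the directive's expanded
#' targets are removed from their positions; one merged equation per matched
#' left-hand side is emitted at the directive's position, its right-hand side
#' the concatenation of the contributing right-hand sides in stream order,
#' each subsequent contribution prefixed with `+` unless it already starts
#' with `-`. Merged equations are ordered by first occurrence of their
#' left-hand side in the stream.
#'
#' @param collect Either a parsed `COLLECT` directive whose `targets` field
#'   holds the expanded left-hand sides, or a character vector of target
#'   left-hand sides (e.g. `c("A1:t", "A2:t")`).
#' @param stream Character vector of lines containing the contributing
#'   equations and, optionally, a `//%COLLECT` line marking the merge
#'   position (defaults to the end of the stream).
#' @return Character vector: the stream with contributions merged.
#' @export
apply_collect <- function(collect, stream) {
  targets <- if (is.character(collect)) collect else collect$targets
  stopifnot(is.character(targets), length(targets) >= 1L)
  stream <- split_lines(stream)
  marker <- which(vapply(stream, function(l) {
    d <- tryCatch(parse_directive(l), error = function(e) NULL)
    !is.null(d) && identical(d$type, "collect")
  }, TRUE))
  marker <- if (length(marker)) marker[[1]] else length(stream) + 1L

  eqs <- lapply(stream, match_equation_line)
  hit <- vapply(seq_along(stream), function(i) {
    !is.null(eqs[[i]]) && eqs[[i]]$key %in% targets && i != marker
  }, TRUE)
  if (!any(hit))
    warning(sprintf("COLLECT pattern(s) %s matched no equations",
                    paste(unique(targets), collapse = ", ")), call. = FALSE)
  keys <- vapply(which(hit), function(i) eqs[[i]]$key, "")
  merged <- character()
  for (key in unique(keys)) {  # first-occurrence order
    rhss <- lapply(which(hit)[keys == key], function(i) eqs[[i]]$rhs)
    merged <- c(merged, paste0(key, " = ", join_contributions(rhss), ";"))
  }
  out <- character()
  for (i in seq_along(stream)) {
    if (i == marker) { out <- c(out, merged); next }
    if (hit[i]) next
    out <- c(out, stream[[i]])
  }
  if (marker == length(stream) + 1L) out <- c(out, merged)
  out
}

# ---- INSERT markers ---------------------------------------------------------

#' Rewrite insertion markers into library markers
#'
#' `//%INSERTSTART <name>` / `//%INSERTEND <name>` lines become
#' `//%START <name>` / `//%END <name>` marker lines, which makes the built
#' output itself an indexable module library. Trailing comments on the marker
#' line are preserved; trailing non-comment text (such as the closing brace
#' of the model) is emitted on the following line. Unbalanced markers are an
#' error.
#'
#' @param stream Character vector of lines.
#' @return Character vector with markers rewritten.
#' @export
apply_insert <- function(stream) {
  stream <- split_lines(stream)
  out <- character()
  depth <- 0L
  for (i in seq_along(stream)) {
    d <- tryCatch(parse_directive(stream[[i]], lineno = i), error = function(e) NULL)
    if (is.null(d) || !d$type %in% c("insertstart", "insertend")) {
      out <- c(out, stream[[i]])
      next
    }
    if (d$type == "insertstart") depth <- depth + 1L else depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("line %d: INSERTEND without matching INSERTSTART", i), call. = FALSE)
    marker <- paste0("//%", if (d$type == "insertstart") "START" else "END",
                     " ", d$section_name)
    if (is.na(d$leftover) && !is.na(d$comment))
      marker <- paste0(marker, "    ", d$comment)
    out <- c(out, marker)
    if (!is.na(d$leftover)) {
      extra <- d$leftover
      if (!is.na(d$comment)) extra <- paste0(extra, "  ", d$comment)
      out <- c(out, extra)
    }
  }
  if (depth != 0L)
    stop("unbalanced INSERTSTART/INSERTEND markers", call. = FALSE)
  out
}

# ---- pipeline ---------------------------------------------------------------

merge_continuations <- function(lines) {
  out <- character()
  nos <- integer()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    d <- tryCatch(parse_directive(line, lineno = i), error = function(e) NULL)
    if (!is.null(d) && identical(d$type, "get") && !isTRUE(d$complete)) {
      sc <- split_directive_comment(line)
      logical_line <- sc$content
      j <- i + 1L
      repeat {
        if (j > n)
          stop(sprintf("line %d: GET argument list never closed", i), call. = FALSE)
        dj <- tryCatch(parse_directive(lines[[j]], lineno = j), error = function(e) NULL)
        if (is.null(dj) || !identical(dj$type, "continuation"))
          stop(sprintf("line %d: GET argument list continued by a non-'//%%' line %d",
                       i, j), call. = FALSE)
        logical_line <- paste0(logical_line, " ", trimws(dj$content))
        j <- j + 1L
        if (paren_balance(split_directive_comment(logical_line)$content) <= 0L) break
      }
      out <- c(out, logical_line)
      nos <- c(nos, i)
      i <- j
    } else {
      out <- c(out, line)
      nos <- c(nos, i)
      i <- i + 1L
    }
  }
  list(lines = out, linenos = nos)
}

#' Build a model from a constructor file
#'
#' Runs the full construction pipeline: REPLACE groups are consumed in order
#' and expand every subsequent line (directive lines included); GET
#' directives splice renamed module code; COLLECT merges the per-process
#' differential-equation contributions into one equation per state;
#' INSERTSTART/INSERTEND markers are rewritten so the output is itself an
#' indexable library; everything else passes through verbatim.
#'
#' @param input Path to a constructor (`.mpc`) file, or a character vector of
#'   its lines.
#' @param lib_paths Extra directories searched for module library files
#'   (after the constructor file's own directory).
#' @param strict Treat residual placeholders and unparseable model-body text
#'   as errors.
#' @param base_dir Directory for resolving library references when `input` is
#'   given as lines.
#' @return Character vector: the generated model file's lines.
#' @examples
#' mpc <- system.file("extdata", "Example.mpc", package = "modcon")
#' mod <- build_model(mpc)
#' @export
build_model <- function(input, lib_paths = character(), strict = FALSE,
                        base_dir = NULL) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    if (is.null(base_dir)) base_dir <- dirname(input)
    input <- readLines(input, warn = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  lines <- split_lines(input)
  mc <- merge_continuations(lines)

  # names declared by any REPLACE, for used-before-declared diagnostics
  all_declared <- character()
  for (k in seq_along(mc$lines)) {
    d <- tryCatch(parse_directive(mc$lines[[k]], lineno = mc$linenos[[k]]),
                  error = function(e) NULL)
    if (!is.null(d) && identical(d$type, "replace"))
      all_declared <- c(all_declared, names(d$bindings))
  }

  groups <- list()
  stream <- list()  # items: list(type = "line"/"collect", ...)
  declared_so_far <- character()
  push_line <- function(text, lineno) {
    resid <- residual_placeholders(text)
    if (length(resid)) {
      later <- setdiff(intersect(resid, all_declared), declared_so_far)
      if (length(later))
        stop(sprintf("line %d: placeholder(s) %s used before their REPLACE declaration",
                     lineno, paste(sprintf("%%%s%%", later), collapse = ", ")),
             call. = FALSE)
      msg <- sprintf("line %d: unresolved placeholder(s) %s", lineno,
                     paste(sprintf("%%%s%%", resid), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    stream[[length(stream) + 1L]] <<- list(type = "line", text = text, lineno = lineno)
  }

  for (k in seq_along(mc$lines)) {
    line <- mc$lines[[k]]
    lineno <- mc$linenos[[k]]
    d <- parse_directive(line, lineno = lineno)
    if (!is.null(d) && identical(d$type, "replace")) {
      # a REPLACE line may itself use earlier placeholders
      for (ex in expand_one_line(line, groups)) {
        g <- parse_directive(ex, lineno = lineno)
        groups[[length(groups) + 1L]] <- g
        declared_so_far <- c(declared_so_far, names(g$bindings))
      }
      next
    }
    if (!is.null(d) && identical(d$type, "collect")) {
      targets <- expand_one_line(d$lhs_pattern, groups)
      resid <- unique(unlist(lapply(targets, residual_placeholders)))
      if (length(resid))
        stop(sprintf("line %d: COLLECT pattern has unresolved placeholder(s) %s",
                     lineno, paste(sprintf("%%%s%%", resid), collapse = ", ")),
             call. = FALSE)
      stream[[length(stream) + 1L]] <- list(type = "collect", targets = targets,
                                            lineno = lineno)
      next
    }
    for (ex in expand_one_line(line, groups)) push_line(ex, lineno)
  }

  # GET execution
  resolver <- make_library_resolver(base_dir, lib_paths)
  expanded <- list()
  for (item in stream) {
    if (item$type != "line") { expanded[[length(expanded) + 1L]] <- item; next }
    d <- parse_directive(item$text, lineno = item$lineno)
    if (!is.null(d) && identical(d$type, "get")) {
      for (ln in resolve_get(d, resolver))
        expanded[[length(expanded) + 1L]] <- list(type = "line", text = ln,
                                                  lineno = item$lineno)
    } else {
      expanded[[length(expanded) + 1L]] <- item
    }
  }

  # COLLECT: merge contributions at each collect marker
  texts <- vapply(expanded, function(it) {
    if (it$type == "collect") "//%COLLECT(\"<pending>\")" else it$text
  }, "")
  for (i in seq_along(expanded)) {
    if (expanded[[i]]$type != "collect") next
    texts <- apply_collect(expanded[[i]]$targets, texts)
  }

  out <- apply_insert(texts)

  doc <- suppressWarnings(parse_model(out, origin = "<built>", strict = strict))
  kinds <- vapply(doc$statements, `[[`, "", "kind")
  if (sum(kinds == "header") != 1L || sum(kinds == "footer") != 1L)
    warning("built output is not a complete model document (expected exactly one 'math <name> {' header and one '}' footer)",
            call. = FALSE)
  out
}
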