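# Lexer, statement parser, identifier renamer and emitter for the MML-like
# declarative dialect that module libraries and generated models are written
# in. The dialect is line-oriented: every line of a well-formed model file
# parses to exactly one statement (a single line may carry several
# ';'-terminated declaration segments, which stay together as one statement).

RE_IDENT <- "[A-Za-z_][A-Za-z0-9_]*"

#' Tokenize one line of model code
#'
#' Splits a single source line into identifier, number, operator, punctuation
#' and comment tokens. Dotted names such as `t.min` (domain attributes) are a
#' single identifier token, so renaming `t` can never touch `t.min`. A
#' trailing `// ...` comment is one token. Each token records the whitespace
#' that preceded it, so `paste0(space, text)` collapsed reproduces the input
#' up to trailing whitespace.
#'
#' @param line A character scalar containing no newline.
#' @return A tibble with columns `kind` (one of `"identifier"`, `"number"`,
#'   `"operator"`, `"punctuation"`, `"comment"`), `text`, and `space` (the
#'   whitespace run preceding the token).
#' @examples
#' tokenize("C:t = (F/V)*(Cin-C);")
#' @export
tokenize <- function(line) {
  stopifnot(is.character(line), length(line) == 1L, !grepl("\n", line, fixed = TRUE))
  kinds <- character()
  texts <- character()
  spaces <- character()
  rest <- line
  pos <- 1L
  pending_space <- ""
  pat_id  <- paste0("^", RE_IDENT, "(?:\\.", RE_IDENT, ")*")
  pat_num <- "^(?:[0-9]+(?:\\.[0-9]+)?|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr("^[ \t]+", rest))
    if (length(m)) {
      pending_space <- m
      pos <- pos + nchar(m)
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
      next
    }
    if (startsWith(rest, "//")) {
      kinds <- c(kinds, "comment"); texts <- c(texts, rest); spaces <- c(spaces, pending_space)
      pending_space <- ""
      break
    }
    m <- regmatches(rest, regexpr(pat_num, rest))
    if (length(m) && grepl("^[0-9.]", rest)) {
      kinds <- c(kinds, "number"); texts <- c(texts, m); spaces <- c(spaces, pending_space)
    } else if (length(m <- regmatches(rest, regexpr(pat_id, rest)))) {
      kinds <- c(kinds, "identifier"); texts <- c(texts, m); spaces <- c(spaces, pending_space)
    } else {
      ch <- substr(rest, 1L, 1L)
      if (ch %in% c("+", "-", "*", "/", "=", ":")) {
        kinds <- c(kinds, "operator")
      } else if (ch %in% c("(", ")", ",", ";", "{", "}", "%")) {
        # '%' appears only in pre-expansion template text (placeholders);
        # it lexes as punctuation so constructor files round-trip too

        kinds <- c(kinds, "punctuation")
      } else {
        stop(sprintf("lexical error: illegal character '%s' at column %d in: %s",
                     ch, pos, line), call. = FALSE)
      }
      m <- ch
      texts <- c(texts, ch); spaces <- c(spaces, pending_space)
    }
    pending_space <- ""
    pos <- pos + nchar(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  tibble::tibble(kind = kinds, text = texts, space = spaces)
}

# Rebuild a source line from its token table.
detokenize <- function(tokens) {
  if (nrow(tokens) == 0L) return("")
  paste0(tokens$space, tokens$text, collapse = "")
}

# ---- statement parsing ------------------------------------------------------

new_statement <- function(kind, text, tokens, lineno = 1L, origin = "<text>", ...) {
  structure(
    c(list(kind = kind, text = text, tokens = tokens,
           lineno = lineno, origin = origin), list(...)),
    class = "mpc_statement"
  )
}

#' @export
print.mpc_statement <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$kind, x$text))
  invisible(x)
}

# token cursor helpers: `tk` is the code-token table (comments stripped)
tk_at <- function(tk, i) if (i <= nrow(tk)) tk$text[i] else NA_character_
tk_kind <- function(tk, i) if (i <= nrow(tk)) tk$kind[i] else NA_character_

# Parse one `real`/`extern real` declaration segment starting at index i
# (pointing at "extern" or "real"). Returns list(entries, i_after) or NULL.
parse_decl_segment <- function(tk, i) {
  is_extern <- identical(tk_at(tk, i), "extern")
  if (is_extern) i <- i + 1L
  if (!identical(tk_at(tk, i), "real")) return(NULL)
  i <- i + 1L
  entries <- list()
  repeat {
    if (!identical(tk_kind(tk, i), "identifier")) return(NULL)
    name <- tk_at(tk, i); i <- i + 1L
    domains <- character()
    if (identical(tk_at(tk, i), "(")) {
      i <- i + 1L
      repeat {
        if (!identical(tk_kind(tk, i), "identifier")) return(NULL)
        domains <- c(domains, tk_at(tk, i)); i <- i + 1L
        if (identical(tk_at(tk, i), ",")) { i <- i + 1L; next }
        if (identical(tk_at(tk, i), ")")) { i <- i + 1L; break }
        return(NULL)
      }
    }
    init <- NA_character_
    if (identical(tk_at(tk, i), "=")) {
      i <- i + 1L
      sign <- ""
      if (tk_at(tk, i) %in% c("-", "+")) { sign <- tk_at(tk, i); i <- i + 1L }
      if (!identical(tk_kind(tk, i), "number")) return(NULL)
      init <- paste0(sign, tk_at(tk, i)); i <- i + 1L
    }
    unit_parts <- character()
    while (!is.na(tk_at(tk, i)) && !tk_at(tk, i) %in% c(",", ";")) {
      if (!tk_kind(tk, i) %in% c("identifier", "operator", "punctuation") ||
          tk_at(tk, i) %in% c("{", "}", "=")) return(NULL)
      unit_parts <- c(unit_parts, tk_at(tk, i)); i <- i + 1L
    }
    unit <- if (length(unit_parts)) paste0(unit_parts, collapse = "") else NA_character_
    entries <- c(entries, list(list(name = name, domains = domains,
                                    init = init, unit = unit,
                                    extern = is_extern)))
    if (identical(tk_at(tk, i), ",")) { i <- i + 1L; next }
    if (identical(tk_at(tk, i), ";")) { i <- i + 1L; break }
    return(NULL)
  }
  list(entries = entries, i = i)
}

#' Parse one line into a statement
#'
#' Classifies a source line as one of the statement kinds of the dialect:
#' `domain-decl`, `param-decl`, `var-decl`, `extern-decl`,
#' `initial-condition`, `equation`, `header`, `footer`, `comment`, `blank`,
#' or `raw`. Legal-but-unrecognized text falls back to `raw` and is passed
#' through verbatim with a warning (the `import nsrunit; unit conversion on;`
#' prologue is recognized passthrough and does not warn). With
#' `strict = TRUE` the raw fallback is an error instead.
#'
#' @param line Character scalar (one source line).
#' @param lineno,origin Provenance recorded on the statement.
#' @param strict Error instead of warning on unparseable text.
#' @return An object of class `mpc_statement`. Payload fields depend on
#'   `kind`: declarations carry `entries` (name, domains, init, unit),
#'   equations carry `lhs_var`, `lhs_derivs`, `rhs_text` and `rhs_tokens`,
#'   initial conditions carry `guard`, `var`, `value`, domain declarations
#'   carry `name`, `unit` and `attrs` (min/max/delta), headers carry `name`.
#' @examples
#' parse_statement("when(t=t.min)  A1=0;")
#' parse_statement("real KmA =1.0 mM, VmaxA  =2 umol/(g*min);")
#' @export
parse_statement <- function(line, lineno = 1L, origin = "<text>", strict = FALSE) {
  toks <- tokenize(line)
  mk <- function(kind, ...) new_statement(kind, line, toks, lineno, origin, ...)
  if (nrow(toks) == 0L) return(mk("blank"))
  comment <- if (any(toks$kind == "comment")) toks$text[toks$kind == "comment"][1] else NA_character_
  tk <- toks[toks$kind != "comment", , drop = FALSE]
  if (nrow(tk) == 0L) return(mk("comment", trailing_comment = comment))

  first <- tk$text[1]

  if (identical(first, "math") && identical(tk_at(tk, 3), "{") && nrow(tk) == 3L)
    return(mk("header", name = tk_at(tk, 2), trailing_comment = comment))
  if (identical(first, "}") && nrow(tk) == 1L)
    return(mk("footer", trailing_comment = comment))

  if (identical(first, "realDomain")) {
    st <- parse_domain_decl(tk)
    if (!is.null(st))
      return(mk("domain-decl", name = st$name, unit = st$unit, attrs = st$attrs,
                trailing_comment = comment))
  }

  if (identical(first, "when")) {
    st <- parse_when(tk)
    if (!is.null(st))
      return(mk("initial-condition", guard = st$guard, var = st$var,
                value = st$value, trailing_comment = comment))
  }

  if (first %in% c("real", "extern")) {
    i <- 1L
    entries <- list()
    ok <- TRUE
    while (i <= nrow(tk)) {
      seg <- parse_decl_segment(tk, i)
      if (is.null(seg)) { ok <- FALSE; break }
      entries <- c(entries, seg$entries)
      i <- seg$i
    }
    if (ok && length(entries)) {
      is_extern <- any(vapply(entries, `[[`, TRUE, "extern"))
      is_var <- any(vapply(entries, function(e) length(e$domains) > 0L, TRUE))
      kind <- if (is_extern) "extern-decl" else if (is_var) "var-decl" else "param-decl"
      return(mk(kind, entries = entries, trailing_comment = comment))
    }
  }

  eq <- parse_equation_tokens(tk)
  if (!is.null(eq))
    return(mk("equation", lhs_var = eq$lhs_var, lhs_derivs = eq$lhs_derivs,
              rhs_text = eq$rhs_text, rhs_tokens = eq$rhs_tokens,
              trailing_comment = comment))

  if (first %in% c("import", "unit"))
    return(mk("raw", trailing_comment = comment))
  if (strict)
    stop(sprintf("%s:%d: cannot parse statement: %s", origin, lineno, line), call. = FALSE)
  warning(sprintf("%s:%d: unrecognized statement passed through verbatim: %s",
                  origin, lineno, line), call. = FALSE)
  mk("raw", trailing_comment = comment)
}

parse_domain_decl <- function(tk) {
  if (!identical(tk_kind(tk, 2), "identifier")) return(NULL)
  name <- tk_at(tk, 2)
  i <- 3L
  unit <- NA_character_
  if (identical(tk_kind(tk, i), "identifier")) { unit <- tk_at(tk, i); i <- i + 1L }
  if (!identical(tk_at(tk, i), ";")) return(NULL)
  i <- i + 1L
  attrs <- list()
  while (i <= nrow(tk)) {
    key <- tk_at(tk, i)
    if (!identical(tk_kind(tk, i), "identifier") ||
        !startsWith(key, paste0(name, "."))) return(NULL)
    if (!identical(tk_at(tk, i + 1L), "=")) return(NULL)
    sign <- ""
    j <- i + 2L
    if (tk_at(tk, j) %in% c("-", "+")) { sign <- tk_at(tk, j); j <- j + 1L }
    if (!identical(tk_kind(tk, j), "number")) return(NULL)
    attrs[[sub(paste0("^", name, "\\."), "", key)]] <- paste0(sign, tk_at(tk, j))
    if (!identical(tk_at(tk, j + 1L), ";")) return(NULL)
    i <- j + 2L
  }
  list(name = name, unit = unit, attrs = attrs)
}

parse_when <- function(tk) {
  if (!identical(tk_at(tk, 2), "(")) return(NULL)
  depth <- 1L; i <- 3L
  guard_parts <- character()
  while (i <= nrow(tk) && depth > 0L) {
    t <- tk_at(tk, i)
    if (t == "(") depth <- depth + 1L
    if (t == ")") { depth <- depth - 1L; if (depth == 0L) { i <- i + 1L; break } }
    guard_parts <- c(guard_parts, t)
    i <- i + 1L
  }
  if (depth != 0L) return(NULL)
  if (!identical(tk_kind(tk, i), "identifier")) return(NULL)
  var <- tk_at(tk, i); i <- i + 1L
  if (!identical(tk_at(tk, i), "=")) return(NULL)
  i <- i + 1L
  value_parts <- character()
  while (i <= nrow(tk) && !identical(tk_at(tk, i), ";")) {
    value_parts <- c(value_parts, tk_at(tk, i)); i <- i + 1L
  }
  if (!identical(tk_at(tk, i), ";") || i != nrow(tk) || !length(value_parts)) return(NULL)
  list(guard = paste0(guard_parts, collapse = ""), var = var,
       value = paste0(value_parts, collapse = ""))
}

parse_equation_tokens <- function(tk) {
  if (!identical(tk_kind(tk, 1), "identifier")) return(NULL)
  lhs_var <- tk_at(tk, 1)
  i <- 2L
  derivs <- character()
  while (identical(tk_at(tk, i), ":")) {
    if (!identical(tk_kind(tk, i + 1L), "identifier")) return(NULL)
    derivs <- c(derivs, tk_at(tk, i + 1L))
    i <- i + 2L
  }
  if (!identical(tk_at(tk, i), "=")) return(NULL)
  i <- i + 1L
  if (!identical(tk_at(tk, nrow(tk)), ";") || i > nrow(tk) - 1L) return(NULL)
  rhs_tokens <- tk[seq.int(i, nrow(tk) - 1L), , drop = FALSE]
  rhs_text <- trimws(detokenize(rhs_tokens))
  if (!nzchar(rhs_text)) return(NULL)
  list(lhs_var = lhs_var, lhs_derivs = derivs,
       rhs_text = rhs_text, rhs_tokens = rhs_tokens)
}

# ---- documents --------------------------------------------------------------

#' Parse a model file into a document
#'
#' @param text Either a single string (split on newlines) or a character
#'   vector of lines.
#' @param origin File name recorded on statements for diagnostics.
#' @param strict Error on unparseable lines inside the model body.
#' @return An `mpc_document`: ordered statements plus the model `name` taken
#'   from the `math <name> {` header (NA when absent).
#' @export
parse_model <- function(text, origin = "<text>", strict = FALSE) {
  lines <- split_lines(text)
  statements <- vector("list", length(lines))
  in_body <- FALSE
  for (i in seq_along(lines)) {
    st <- parse_statement(lines[[i]], lineno = i, origin = origin,
                          strict = strict && in_body)
    if (st$kind == "header") in_body <- TRUE
    if (st$kind == "footer") in_body <- FALSE
    statements[[i]] <- st
  }
  name <- NA_character_
  headers <- which(vapply(statements, `[[`, "", "kind") == "header")
  if (length(headers)) name <- statements[[headers[1]]]$name
  structure(list(statements = statements, name = name, origin = origin),
            class = "mpc_document")
}

#' @export
print.mpc_document <- function(x, ...) {
  kinds <- vapply(x$statements, `[[`, "", "kind")
  cat(sprintf("<mpc_document> model '%s': %d statements\n",
              ifelse(is.na(x$name), "?", x$name), length(kinds)))
  print(table(kinds))
  invisible(x)
}

#' Emit a document back to source lines
#'
#' One line per statement, in order; `parse_model()` then `emit_document()`
#' reproduces the input up to trailing whitespace.
#'
#' @param doc An `mpc_document`.
#' @return Character vector of lines.
#' @export
emit_document <- function(doc) {
  stopifnot(inherits(doc, "mpc_document"))
  vapply(doc$statements, `[[`, "", "text")
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  as.character(text)
}

# ---- renaming ---------------------------------------------------------------

# Simultaneous single-pass identifier substitution in free text (comments),
# longest key first, firing only at identifier-token boundaries.
rename_in_text <- function(text, renames) {
  if (!length(renames) || !nzchar(text)) return(text)
  keys <- names(renames)[order(-nchar(names(renames)))]
  pat <- paste0("(?<![A-Za-z0-9_])(?:", paste(keys, collapse = "|"),
                ")(?![A-Za-z0-9_])")
  m <- gregexpr(pat, text, perl = TRUE)
  hits <- regmatches(text, m)[[1]]
  if (!length(hits)) return(text)
  regmatches(text, m) <- list(unname(renames[hits]))
  text
}

#' Rename identifiers in a statement or line
#'
#' Applies an old-name to new-name mapping simultaneously, in a single pass,
#' and only at identifier-token boundaries: a key that is a substring of a
#' longer identifier (`A` inside `VmaxA`) never fires inside it, and
#' substituted text is never re-scanned. Comments are renamed too, so module
#' comments track the new names.
#'
#' @param stmt An `mpc_statement`, or a character scalar treated as one line.
#' @param renames Named character vector: `c(old = "new", ...)`.
#' @return An object of the same type as `stmt` with all occurrences renamed;
#'   attribute `"used_keys"` lists the keys that matched at least one code
#'   token.
#' @examples
#' rename_identifiers("A:t = -G*(A)/V;",
#'                    c(A = "B2", B = "C2", V = "V2", G = "Gb2c"))
#' @export
rename_identifiers <- function(stmt, renames) {
  renames <- validate_renames(renames)
  if (is.character(stmt)) {
    used <- character()
    out <- character(length(stmt))
    for (i in seq_along(stmt)) {
      r <- rename_line(stmt[[i]], renames)
      used <- union(used, attr(r, "used_keys"))
      out[[i]] <- r
    }
    attr(out, "used_keys") <- used
    return(out)
  }
  stopifnot(inherits(stmt, "mpc_statement"))
  new_text <- rename_line(stmt$text, renames)
  out <- suppressWarnings(
    parse_statement(new_text, lineno = stmt$lineno, origin = stmt$origin)
  )
  attr(out, "used_keys") <- attr(new_text, "used_keys")
  out
}

validate_renames <- function(renames) {
  if (is.null(renames) || !length(renames)) return(character())
  stopifnot(is.character(renames), !is.null(names(renames)))
  bad <- !grepl(paste0("^", RE_IDENT, "$"), names(renames))
  if (any(bad))
    stop("rename keys must be legal identifiers: ",
         paste(names(renames)[bad], collapse = ", "), call. = FALSE)
  renames
}

rename_line <- function(line, renames, tokens_only = FALSE) {
  if (!length(renames)) {
    attr(line, "used_keys") <- character()
    return(line)
  }
  toks <- tokenize(line)
  used <- character()
  for (i in seq_len(nrow(toks))) {
    if (toks$kind[i] == "identifier" && toks$text[i] %in% names(renames)) {
      used <- c(used, toks$text[i])
      toks$text[i] <- unname(renames[[toks$text[i]]])
    } else if (toks$kind[i] == "comment" && !tokens_only) {
      toks$text[i] <- rename_in_text(toks$text[i], renames)
    }
  }
  out <- detokenize(toks)
  attr(out, "used_keys") <- unique(used)
  out
}

# ---- token equivalence ------------------------------------------------------

canonical_units <- function(doc) {
  decls <- character()
  others <- character()
  for (st in doc$statements) {
    if (st$kind %in% c("comment", "blank")) next
    if (st$kind %in% c("param-decl", "var-decl", "extern-decl")) {
      for (e in st$entries) {
        decls <- c(decls, paste(
          if (isTRUE(e$extern)) "extern real" else "real",
          e$name,
          if (length(e$domains)) paste0("(", paste(e$domains, collapse = ","), ")") else "",
          if (!is.na(e$init)) paste("=", e$init) else "",
          if (!is.na(e$unit)) e$unit else ""
        ))
      }
    } else {
      tk <- st$tokens[st$tokens$kind != "comment", , drop = FALSE]
      if (nrow(tk) == 0L) next
      others <- c(others, paste(tk$text, collapse = " "))
    }
  }
  list(decls = decls, others = others)
}

#' Compare two model texts for token equivalence
#'
#' The normative comparison for reproduction tests: comments and whitespace
#' are ignored; declarations are compared as a multiset of per-name
#' declaration units (declaration order carries no meaning in a declarative
#' language, and published listings group them freely); all other statements
#' (domains, initial conditions, equations, header/footer, passthrough
#' prologue) are compared as an ordered token sequence, so term order and
#' signs inside merged equations are compared exactly.
#'
#' @param a,b Character vectors of lines (or single newline-joined strings).
#' @return `TRUE` or `FALSE`; on mismatch the return value carries a `"diff"`
#'   attribute describing the first difference.
#' @export
token_equivalent <- function(a, b) {
  ca <- canonical_units(suppressWarnings(parse_model(a)))
  cb <- canonical_units(suppressWarnings(parse_model(b)))
  norm <- function(x) gsub("[ \t]+", " ", trimws(x))
  da <- sort(norm(ca$decls)); db <- sort(norm(cb$decls))
  oa <- norm(ca$others); ob <- norm(cb$others)
  if (!identical(da, db)) {
    out <- FALSE
    attr(out, "diff") <- list(kind = "declarations",
                              only_a = setdiff(da, db), only_b = setdiff(db, da))
    return(out)
  }
  if (!identical(oa, ob)) {
    n <- min(length(oa), length(ob))
    i <- which(oa[seq_len(n)] != ob[seq_len(n)])
    i <- if (length(i)) i[1] else n + 1L
    out <- FALSE
    attr(out, "diff") <- list(kind = "statements", index = i,
                              a = oa[i], b = ob[i])
    return(out)
  }
  TRUE
}
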