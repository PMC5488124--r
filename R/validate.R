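# Structural well-formedness checks on generated models. Dimensional balance
# is deliberately out of scope (that is the downstream compiler's job); units
# are carried opaquely and only checked against the unit grammar
#   unit := factor (('*'|'/') factor)* ;  factor := name | '(' unit ')'

issue_tbl <- function(severity = character(), code = character(),
                      lineno = integer(), message = character()) {
  tibble::tibble(severity = severity, code = code,
                 lineno = as.integer(lineno), message = message)
}

add_issue <- function(issues, severity, code, lineno, message) {
  dplyr::bind_rows(issues, issue_tbl(severity, code, lineno, message))
}

# Parse a unit string against the unit grammar, returning a named vector of
# net exponents per base name, or NULL if the string does not parse.
unit_exponents <- function(unit) {
  if (is.null(unit) || is.na(unit) || !nzchar(unit)) return(numeric())
  toks <- regmatches(unit, gregexpr(paste0(RE_IDENT, "|[*/()]"), unit))[[1]]
  if (paste(toks, collapse = "") != gsub("\\s+", "", unit)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() pos <<- pos + 1L
  merge_exp <- function(a, b) {
    for (n in names(b)) a[n] <- (if (n %in% names(a)) a[[n]] else 0) + b[[n]]
    a
  }
  parse_factor <- function(sign) {
    t <- peek()
    if (is.na(t)) return(NULL)
    if (t == "(") {
      advance()
      inner <- parse_expr(sign)
      if (is.null(inner) || !identical(peek(), ")")) return(NULL)
      advance()
      return(inner)
    }
    if (grepl(paste0("^", RE_IDENT, "$"), t)) {
      advance()
      return(stats::setNames(sign, t))
    }
    NULL
  }
  parse_expr <- function(sign) {
    acc <- parse_factor(sign)
    if (is.null(acc)) return(NULL)
    while (!is.na(peek()) && peek() %in% c("*", "/")) {
      op <- peek(); advance()
      f <- parse_factor(if (op == "/") -sign else sign)
      if (is.null(f)) return(NULL)
      acc <- merge_exp(acc, f)
    }
    acc
  }
  out <- parse_expr(1)
  if (is.null(out) || pos <= length(toks)) return(NULL)
  out
}

#' Check that construction finished
#'
#' Flags residual `%placeholder%` text and unexecuted construction directives
#' (`REPLACE`, `GET`, `COLLECT`, `INSERTSTART`/`INSERTEND`, orphan `//%`
#' continuations) in a generated model. `//%START` / `//%END` marker lines
#' are allowed: they are the module annotation that makes the output
#' reusable as a library.
#'
#' @param text Character vector of lines (or one newline-joined string).
#' @return A tibble of issues with columns `severity`, `code`, `lineno`,
#'   `message` (zero rows when clean).
#' @export
validate_resolved <- function(text) {
  lines <- split_lines(text)
  issues <- issue_tbl()
  for (i in seq_along(lines)) {
    resid <- residual_placeholders(lines[[i]])
    if (length(resid))
      issues <- add_issue(issues, "error", "residual-placeholder", i,
                          sprintf("unresolved placeholder(s) %s",
                                  paste(sprintf("%%%s%%", resid), collapse = ", ")))
    d <- tryCatch(parse_directive(lines[[i]], lineno = i),
                  error = function(e) list(type = "unknown"))
    if (is.null(d) || d$type %in% c("start", "end")) next
    issues <- add_issue(issues, "error", "unexecuted-directive", i,
                        sprintf("construction directive not executed: %s",
                                trimws(lines[[i]])))
  }
  issues
}

#' Structural validation of a model document
#'
#' Checks that every identifier used in an equation or initial condition is
#' declared (or is a domain / domain attribute such as `t.min`), that every
#' state with a time derivative has an initial condition, that every
#' time-dependent variable is defined by some equation (`extern` variables
#' are model inputs and exempt), and that every unit string parses against
#' the unit grammar.
#'
#' @param doc An `mpc_document`, or text parsed with [parse_model()].
#' @return A tibble of issues (`severity`, `code`, `lineno`, `message`).
#' @examples
#' mod <- build_model(system.file("extdata", "Example.mpc", package = "modcon"))
#' validate_structure(mod)
#' @export
validate_structure <- function(doc) {
  if (!inherits(doc, "mpc_document")) doc <- suppressWarnings(parse_model(doc))
  issues <- issue_tbl()

  domains <- list()
  params <- character(); vars <- character(); externs <- character()
  var_domains <- list()

  for (st in doc$statements) {
    if (st$kind == "domain-decl") {
      domains[[st$name]] <- st
      if (!is.na(st$unit) && is.null(unit_exponents(st$unit)))
        issues <- add_issue(issues, "error", "bad-unit", st$lineno,
                            sprintf("unit '%s' of domain '%s' does not parse",
                                    st$unit, st$name))
    } else if (st$kind %in% c("param-decl", "var-decl", "extern-decl")) {
      for (e in st$entries) {
        if (isTRUE(e$extern)) externs <- c(externs, e$name)
        else if (length(e$domains)) { vars <- c(vars, e$name); var_domains[[e$name]] <- e$domains }
        else params <- c(params, e$name)
        if (length(e$domains)) var_domains[[e$name]] <- e$domains
        if (!is.na(e$unit) && is.null(unit_exponents(e$unit)))
          issues <- add_issue(issues, "error", "bad-unit", st$lineno,
                              sprintf("unit '%s' of '%s' does not parse", e$unit, e$name))
      }
    }
  }
  declared <- c(names(domains), params, vars, externs)

  known_identifier <- function(id) {
    if (id %in% declared) return(TRUE)
    if (grepl(".", id, fixed = TRUE)) {
      base <- sub("\\..*$", "", id)
      return(base %in% names(domains))
    }
    FALSE
  }

  defined_vars <- character()
  ode_states <- character()
  ode_linenos <- integer()
  ic_vars <- character()

  for (st in doc$statements) {
    if (st$kind == "equation") {
      if (!known_identifier(st$lhs_var))
        issues <- add_issue(issues, "error", "undeclared-identifier", st$lineno,
                            sprintf("equation defines undeclared identifier '%s'", st$lhs_var))
      defined_vars <- c(defined_vars, st$lhs_var)
      if (length(st$lhs_derivs)) {
        bad_dom <- setdiff(st$lhs_derivs, names(domains))
        if (length(bad_dom))
          issues <- add_issue(issues, "error", "undeclared-identifier", st$lineno,
                              sprintf("derivative over undeclared domain(s) %s",
                                      paste(bad_dom, collapse = ", ")))
        if ("t" %in% st$lhs_derivs || length(intersect(st$lhs_derivs, names(domains)))) {
          ode_states <- c(ode_states, st$lhs_var)
          ode_linenos <- c(ode_linenos, st$lineno)
        }
      }
      ids <- st$rhs_tokens$text[st$rhs_tokens$kind == "identifier"]
      for (id in unique(ids))
        if (!known_identifier(id))
          issues <- add_issue(issues, "error", "undeclared-identifier", st$lineno,
                              sprintf("identifier '%s' is not declared", id))
    } else if (st$kind == "initial-condition") {
      ic_vars <- c(ic_vars, st$var)
      if (!known_identifier(st$var))
        issues <- add_issue(issues, "error", "undeclared-identifier", st$lineno,
                            sprintf("initial condition for undeclared '%s'", st$var))
    }
  }

  for (i in seq_along(ode_states)) {
    s <- ode_states[[i]]
    if (!s %in% ic_vars)
      issues <- add_issue(issues, "error", "missing-ic", ode_linenos[[i]],
                          sprintf("state '%s' has a time derivative but no initial condition", s))
  }

  undef <- setdiff(vars, defined_vars)
  for (v in undef) {
    issues <- add_issue(issues, "error", "undefined-variable", 1L,
                        sprintf("time-dependent variable '%s' is never defined by an equation", v))
  }
  issues
}

#' Validate a generated model (resolution + structure)
#'
#' Convenience wrapper running [validate_resolved()] on the text and
#' [validate_structure()] on its parse.
#'
#' @param text Character vector of model lines, or a file path.
#' @return A tibble of issues.
#' @export
validate_model <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  dplyr::arrange(
    dplyr::bind_rows(validate_resolved(text), validate_structure(text)),
    .data$lineno
  )
}
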