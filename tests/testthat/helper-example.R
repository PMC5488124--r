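# Shared fixtures: paths to the shipped worked example and a cached build of
# it (the build itself is exercised explicitly in the directive tests).

example_path <- function(file) {
  p <- system.file("extdata", file, package = "modcon")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

.example_cache <- new.env(parent = emptyenv())

built_example <- function() {
  if (is.null(.example_cache$built))
    .example_cache$built <- suppressWarnings(build_model(example_path("Example.mpc")))
  .example_cache$built
}

compiled_example <- function() {
  if (is.null(.example_cache$model))
    .example_cache$model <- compile_model(built_example())
  .example_cache$model
}

# The worked example's inflow: lagged normal density for species A, nothing
# flowing in for B and C.
example_inputs <- function() {
  list(Ain = lagged_normal_fn(area = 20, mean = 3, rd = 0.25, skew = 1.3),
       Bin = 0, Cin = 0)
}

# Independent single-pass rename oracle: chunk the line into maximal
# identifier-character runs and non-identifier runs, then map whole chunks.
# Mechanically unrelated to the token-based implementation.
oracle_rename <- function(line, renames) {
  chunks <- regmatches(line, gregexpr("[A-Za-z0-9_.]+|[^A-Za-z0-9_.]+", line))[[1]]
  mapped <- vapply(chunks, function(ch) {
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", ch) && ch %in% names(renames))
      unname(renames[[ch]])
    else ch
  }, "", USE.NAMES = FALSE)
  paste0(mapped, collapse = "")
}

# Multiset of the "substance" tokens (identifiers and numbers) on the RHS of
# every equation in a line set whose LHS key is in `targets`.
substance_tokens <- function(lines, targets) {
  out <- character()
  for (l in lines) {
    eq <- modcon:::match_equation_line(l)
    if (is.null(eq) || !eq$key %in% targets) next
    tk <- tokenize(eq$rhs)
    out <- c(out, tk$text[tk$kind %in% c("identifier", "number")])
  }
  sort(out)
}

# Minimal simulatable decay model text, parameterized by grid step.
decay_model <- function(delta, t_max = 2) {
  c("math decay {",
    sprintf("realDomain t s; t.min=0; t.max=%g; t.delta = %g;", t_max, delta),
    "real k = 1 ml/(g*s);",
    "real V = 0.5 ml/g;",
    "real x0 = 2 mM;",
    "real x(t) mM;",
    "when(t=t.min) x=x0;",
    "x:t = -k/V*x;",
    "}")
}

trapz_test <- function(x, y) pracma::trapz(x, y)
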