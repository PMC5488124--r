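test_that("directive parser recognizes every directive form", {
  d <- parse_directive('//%REPLACE %CL% =("CodeLibrary.mod") // Library to get code from')
  expect_identical(d$type, "replace")
  expect_identical(d$bindings, list(CL = "CodeLibrary.mod"))

  d2 <- parse_directive('//%REPLACE (%N%=("1","2"), %vol%=("0.05","0.05"))')
  expect_identical(d2$bindings, list(N = c("1", "2"), vol = c("0.05", "0.05")))

  g <- parse_directive('//%GET CodeLibrary.mod reactionCalc  ("A=A2","B=B2","V=V2","G=Ga2b")')
  expect_identical(g$type, "get")
  expect_identical(g$library_ref, "CodeLibrary.mod")
  expect_identical(g$module_name, "reactionCalc")
  expect_identical(g$renames, c(A = "A2", B = "B2", V = "V2", G = "Ga2b"))

  cl <- parse_directive('//%COLLECT("%AB%%N%:t")      //Group all ODE calculations')
  expect_identical(cl$type, "collect")
  expect_identical(cl$lhs_pattern, "%AB%%N%:t")

  ins <- parse_directive("//%INSERTSTART a2bParmsVars  // Specify params")
  expect_identical(ins[c("type", "section_name")],
                   list(type = "insertstart", section_name = "a2bParmsVars"))
  ie <- parse_directive("//%INSERTEND a2bCalc }  // curly bracket ends model")
  expect_identical(ie$leftover, "}")

  expect_null(parse_directive("real Flow = 1 ml/(g*min);"))
  expect_null(parse_directive("// plain comment"))
  expect_error(parse_directive("//%FROBNICATE x"), "unknown directive")
})

test_that("a GET continued across //% lines merges into one directive", {
  lines <- c(
    '//%GET %CL% MMreactionCalc ("A=B2","B=C2","V=V2","G=Gb2c", // B ->C MM reaction',
    '//% "KmA=KmB2","VmaxA = VmaxB2", "KmA = KmB2")             // continued')
  mc <- modcon:::merge_continuations(lines)
  expect_length(mc$lines, 1L)
  g <- parse_directive(mc$lines[[1]])
  # duplicate "KmA=KmB2" pair collapses silently; whitespace around '=' trimmed
  expect_identical(g$renames,
                   c(A = "B2", B = "C2", V = "V2", G = "Gb2c",
                     KmA = "KmB2", VmaxA = "VmaxB2"))
  expect_error(
    parse_directive('//%GET L m ("A=x","A=y")'),
    "conflicting renames")
})

test_that("REPLACE expansion replicates over the cross product, earlier group fastest", {
  groups <- list(list(N = c("1", "2"), vol = c("0.05", "0.05")),
                 list(AB = c("A", "B", "C"), PS3 = c("6", "5", "4")))

  expect_identical(
    expand_replace("real PS%AB%12 = %PS3% ml/(g*min);", groups),
    c("real PSA12 = 6 ml/(g*min);",
      "real PSB12 = 5 ml/(g*min);",
      "real PSC12 = 4 ml/(g*min);"))

  # parallel advance within one group
  expect_identical(expand_replace("real V%N% = %vol% ml/g;", groups),
                   c("real V1 = 0.05 ml/g;", "real V2 = 0.05 ml/g;"))

  # cross product of two groups: %N% declared first, so it varies fastest
  expect_identical(
    expand_replace("when(t=t.min)  %AB%%N%=0;", groups),
    sprintf("when(t=t.min)  %s=0;", c("A1", "A2", "B1", "B2", "C1", "C2")))

  line <- "real Flow = 1 ml/(g*min);"
  expect_identical(expand_replace(line, groups), line)
})

test_that("expansion counts follow the cross-product formula on random specs", {
  withr::with_seed(7, {
    for (rep in 1:40) {
      n_groups <- sample(1:3, 1)
      groups <- list()
      all_ph <- character()
      for (g in seq_len(n_groups)) {
        size <- sample(1:4, 1)
        n_ph <- sample(1:2, 1)
        ph <- paste0("p", g, "_", seq_len(n_ph))
        groups[[g]] <- stats::setNames(
          lapply(seq_len(n_ph), function(i)
            paste0("v", g, i, "_", seq_len(size))),
          ph)
        all_ph <- c(all_ph, ph)
      }
      used <- sample(all_ph, sample(seq_along(all_ph), 1))
      line <- paste0("real x_",
                     paste(sprintf("%%%s%%", used), collapse = "_"),
                     " = 1 mM;")
      out <- expand_replace(line, groups)
      contributing <- vapply(groups, function(b) any(names(b) %in% used), TRUE)
      sizes <- vapply(groups[contributing],
                      function(b) length(b[[1]]), 1L)
      expect_length(out, prod(sizes))
      expect_false(any(grepl("%", out, fixed = TRUE)))
      expect_identical(anyDuplicated(out), 0L)
    }
  })
})

test_that("GET splices renamed module code and reports unmatched keys", {
  lib <- suppressWarnings(index_library(example_path("CodeLibrary.mod"), is_path = TRUE))
  g <- parse_directive('//%GET CL reactionCalc ("A=A2","B=B2","V=V2","G=Ga2b")')
  expect_identical(resolve_get(g, lib),
                   c("real Ga2b = 5 ml/(g*min);   // Const reaction rate.",
                     "A2:t = -Ga2b/V2*A2;",
                     "B2:t = Ga2b/V2*A2;"))

  g0 <- parse_directive("//%GET CL odeDomains()")
  expect_identical(resolve_get(g0, lib),
                   "realDomain t s; t.min=0; t.max=16; t.delta = 0.1;")

  gf <- parse_directive('//%GET CL flowCalc ("Cin=Ain","C=A1","V=V1","F=Flow","D=DA1")')
  expect_warning(got <- resolve_get(gf, lib), "'D' match no identifier")
  expect_identical(got, "A1:t = (Flow/V1)*(Ain-A1);")

  gbad <- parse_directive("//%GET CL nosuch()")
  expect_error(resolve_get(gbad, lib), "no module 'nosuch'")
})

test_that("COLLECT merges contributions in stream order with sign-aware joining", {
  stream <- c(
    "A2:t = -Ga2b/V2*A2;",
    "B2:t = Ga2b/V2*A2;",
    "B2:t = -Gb2c*(B2)/V2;",
    "C2:t = Gb2c*(B2)/V2;",
    "A2:t = PSA12/V2*(A1-A2);",
    "B2:t = PSB12/V2*(B1-B2);",
    "C2:t = PSC12/V2*(C1-C2);",
    '//%COLLECT("x")')
  out <- apply_collect(c("A2:t", "B2:t", "C2:t"), stream)
  expect_identical(out, c(
    "A2:t = -Ga2b/V2*A2 +PSA12/V2*(A1-A2);",
    "B2:t = Ga2b/V2*A2 -Gb2c*(B2)/V2 +PSB12/V2*(B1-B2);",
    "C2:t = Gb2c*(B2)/V2 +PSC12/V2*(C1-C2);"))

  # single contribution: unchanged except position
  expect_identical(apply_collect("q:t", c("q:t = -k*q;", "real z = 1 mM;")),
                   c("real z = 1 mM;", "q:t = -k*q;"))

  expect_warning(apply_collect("none:t", "real z = 1 mM;"), "matched no equations")
})

test_that("COLLECT conserves the substance tokens of merged right-hand sides", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      states <- paste0("S", seq_len(sample(2:5, 1)))
      targets <- paste0(states, ":t")
      mk_rhs <- function() {
        terms <- replicate(sample(1:3, 1), paste0(
          sample(c("", "-"), 1), "k", sample(9, 1), "/V", sample(3, 1), "*",
          sample(states, 1)))
        paste(terms, collapse = " +")
      }
      n_eq <- sample(3:8, 1)
      eqs <- vapply(seq_len(n_eq), function(i)
        paste0(sample(states, 1), ":t = ", mk_rhs(), ";"), "")
      stream <- c(eqs, "real noise = 1 mM;", '//%COLLECT("x")')
      out <- suppressWarnings(apply_collect(targets, stream))
      expect_identical(substance_tokens(out, targets),
                       substance_tokens(stream, targets))
      merged <- Filter(function(l) !is.null(modcon:::match_equation_line(l)) &&
                         modcon:::match_equation_line(l)$key %in% targets, out)
      expect_length(merged, length(unique(sub(":t.*", ":t", eqs))))
    }
  })
})

test_that("insertion markers become library markers; leftovers keep their line", {
  out <- apply_insert(c("//%INSERTSTART a2bCalc  // calc section",
                        "G = (V/(K+B));",
                        "//%INSERTEND a2bCalc }  // ends model"))
  expect_identical(out[[1]], "//%START a2bCalc    // calc section")
  expect_identical(out[[3]], "//%END a2bCalc")
  expect_identical(out[[4]], "}  // ends model")
  expect_identical(apply_insert("no markers"), "no markers")
  expect_error(apply_insert("//%INSERTEND a"), "without matching")
  expect_error(apply_insert("//%INSERTSTART a"), "unbalanced")
})

test_that("the worked example builds token-equivalent to the printed reference", {
  built <- built_example()
  ref <- readLines(example_path("Example.mod"))
  eq <- token_equivalent(built, ref)
  expect_true(isTRUE(eq), info = paste(capture.output(print(attr(eq, "diff"))),
                                       collapse = "\n"))
  # determinism: identical inputs, byte-identical outputs
  expect_identical(suppressWarnings(build_model(example_path("Example.mpc"))),
                   built)
})

test_that("a constructor with no directives passes through byte-identical", {
  plain <- decay_model(0.1)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "plain.mpc")
  writeLines(plain, p)
  expect_identical(build_model(p), plain)
})

test_that("the built output is itself a library exposing exactly the inserted sections", {
  built <- built_example()
  lib <- index_library(built, origin = "<built>")
  expect_identical(module_names(lib), c("a2bParmsVars", "a2bCalc"))
  sec <- fetch_module(lib, "a2bParmsVars")
  expect_true(any(grepl("^real Flow = 1 ml/\\(g\\*min\\);", sec)))
  expect_true(any(grepl("^when\\(t=t.min\\)  C2=0;", sec)))
  # hierarchical reuse: GET a section out of the built output
  g <- parse_directive('//%GET built a2bParmsVars ()')
  expect_identical(resolve_get(g, lib), sec)
})

test_that("placeholder misuse is diagnosed", {
  lines <- c("real x%Q% = 1 mM;", '//%REPLACE (%Q%=("1"))', "math m {", "}")
  expect_error(build_model(lines), "used before their REPLACE declaration")
  expect_warning(build_model(c("math m {", "real x%Z% = 1 mM;", "}")),
                 "unresolved placeholder")
  expect_error(build_model(c("math m {", "real x%Z% = 1 mM;", "}"), strict = TRUE),
               "unresolved placeholder")
})
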