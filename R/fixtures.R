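# Reference input files and parameterized synthetic model families. The
# shipped files are the worked two-compartment, three-species example: a
# small module library (CodeLibrary.mod), the constructor that assembles the
# model from it (Example.mpc), and the reference output (Example.mod) used by
# the end-to-end reproduction test. The generator emits the same constructor
# structure scaled to arbitrary species x region counts.

#' Paths of the shipped reference files
#' @return Named character vector of installed file paths.
#' @export
reference_fixture_paths <- function() {
  files <- c("CodeLibrary.mod", "Example.mpc", "Example.mod")
  stats::setNames(
    vapply(files, function(f) system.file("extdata", f, package = "modcon"), ""),
    files
  )
}

#' Copy the shipped reference files into a directory
#'
#' Writes `CodeLibrary.mod`, `Example.mpc` and `Example.mod` (the reference
#' build output) into `dest_dir`.
#'
#' @param dest_dir Writable destination directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_paper_fixtures <- function(dest_dir) {
  if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
  src <- reference_fixture_paths()
  dst <- file.path(dest_dir, names(src))
  ok <- file.copy(src, dst, overwrite = TRUE)
  if (!all(ok))
    stop("failed to write fixture file(s): ",
         paste(names(src)[!ok], collapse = ", "), call. = FALSE)
  invisible(dst)
}

FIXTURE_PROCESSES <- c("flow", "exchange", "first-order-reaction",
                       "MM-reaction", "convection-PDE")

synth_library_text <- function() {
  c("// Synthetic module library for species-by-region scaling fixtures.",
    "//%START odeDomains",
    "realDomain t s; t.min=0; t.max=16; t.delta = 0.1;",
    "//%END odeDomains",
    "//%START xDomain",
    "realDomain x cm; x.min=0; x.max=0.1; x.delta=0.01;",
    "//%END xDomain",
    "//%START flowCalc",
    "C:t = (F/V)*(Cin-C);",
    "//%END flowCalc",
    "//%START exchangeCalc",
    "C1:t = PS/V1*(C2-C1);",
    "C2:t = PS/V2*(C1-C2);",
    "//%END exchangeCalc",
    "//%START reactionCalc",
    "A:t = -G/V*A;",
    "B:t = G/V*A;",
    "//%END reactionCalc",
    "//%START MMreactionCalc",
    "A:t = -(Vmax/(Km+A))*A/V;",
    "B:t = (Vmax/(Km+A))*A/V;",
    "//%END MMreactionCalc",
    "//%START pdeCalc",
    "C:t = -U*(C:x) + D*(C:x:x);",
    "//%END pdeCalc")
}

qlist <- function(x) paste0("(", paste(sprintf('"%s"', x), collapse = ","), ")")

#' Generate a synthetic species-by-region constructor
#'
#' Emits a one-state-per-process template library plus a constructor file
#' whose REPLACE groups enumerate `n_species` species names (`S1`, `S2`, ...)
#' and `n_regions` region suffixes (`1`, `2`, ...), mirroring the structure
#' of the shipped worked example: flow enters region 1, passive exchange
#' couples adjacent regions, and a reaction chain runs through the species in
#' the last region (Michaelis-Menten kinetics for the final link when
#' selected). The convection-PDE process instead gives every species-region
#' state a convection-diffusion equation over a spatial domain. Parameter
#' values are drawn log-uniformly from [0.1, 10] under the given seed, so
#' generated fixtures are reproducible.
#'
#' Built models contain exactly `n_species * n_regions` state equations; the
#' one exception is that a reaction chain needs a product, so when a reaction
#' process is selected with `n_species = 1` the species count is raised to 2
#' (substrate and product).
#'
#' @param n_species,n_regions Positive integers.
#' @param processes Subset of
#'   `c("flow", "exchange", "first-order-reaction", "MM-reaction",
#'   "convection-PDE")`.
#' @param seed Integer seed for the randomized parameter values.
#' @return List with elements `library` and `constructor` (character vectors
#'   of lines), plus `library_name` (the file name the constructor GETs from).
#' @examples
#' fx <- generate_species_region_mpc(5, 3, "convection-PDE")
#' @export
generate_species_region_mpc <- function(n_species, n_regions,
                                        processes = c("flow", "exchange",
                                                      "first-order-reaction"),
                                        seed = 1L) {
  stopifnot(n_species >= 1L, n_regions >= 1L)
  processes <- match.arg(processes, FIXTURE_PROCESSES, several.ok = TRUE)
  if (any(c("first-order-reaction", "MM-reaction") %in% processes) && n_species < 2L)
    n_species <- 2L
  is_pde <- "convection-PDE" %in% processes
  if (is_pde && length(processes) > 1L)
    stop("convection-PDE replaces the compartmental processes; select it alone",
         call. = FALSE)

  species <- paste0("S", seq_len(n_species))
  regions <- as.character(seq_len(n_regions))
  rnd <- local({
    i <- 0L
    vals <- withr::with_seed(seed, {
      10^stats::runif(1000L, -1, 1)  # log-uniform in [0.1, 10]
    })
    function(n = 1L) {
      out <- vals[i + seq_len(n)]
      i <<- i + n
      signif(out, 4)
    }
  })

  lib_name <- "SynthLibrary.mod"
  con <- c(
    sprintf('//%%REPLACE %%LB%% =("%s")', lib_name),
    sprintf("//%%REPLACE (%%S%%=%s)", qlist(species)),
    sprintf("//%%REPLACE (%%R%%=%s %%vol%%=%s)", qlist(regions),
            qlist(rnd(n_regions))),
    "math synth {",
    "//%GET %LB% odeDomains()"
  )
  if (is_pde) con <- c(con, "//%GET %LB% xDomain()")
  con <- c(con, "//%INSERTSTART parmsVars")
  if ("flow" %in% processes)
    con <- c(con, sprintf("real Flow = %s ml/(g*min);", rnd()))
  con <- c(con, "real V%R% = %vol% ml/g;")
  if ("exchange" %in% processes && n_regions >= 2L)
    for (r in seq_len(n_regions - 1L))
      con <- c(con, sprintf("real PS%%S%%%d%d = %s ml/(g*min);", r, r + 1L, rnd()))
  chain <- character()
  if (any(c("first-order-reaction", "MM-reaction") %in% processes)) {
    last_region <- regions[n_regions]
    links <- n_species - 1L
    mm_last <- "MM-reaction" %in% processes
    for (i in seq_len(links)) {
      if (i == links && mm_last) {
        con <- c(con,
                 sprintf("real Km%d = %s mM, Vmax%d = %s umol/(g*min);",
                         i, rnd(), i, rnd()))
        chain <- c(chain, sprintf(
          '//%%GET %%LB%% MMreactionCalc ("A=%s%s","B=%s%s","V=V%s","Km=Km%d","Vmax=Vmax%d")',
          species[i], last_region, species[i + 1L], last_region, last_region, i, i))
      } else {
        con <- c(con, sprintf("real G%d = %s ml/(g*min);", i, rnd()))
        chain <- c(chain, sprintf(
          '//%%GET %%LB%% reactionCalc ("A=%s%s","B=%s%s","V=V%s","G=G%d")',
          species[i], last_region, species[i + 1L], last_region, last_region, i))
      }
    }
  }
  if (is_pde) {
    con <- c(con,
             sprintf("real U = %s cm/s;", rnd()),
             sprintf("real Dif = %s cm*cm/s;", rnd()))
  }
  if ("flow" %in% processes)
    con <- c(con, "extern real %S%in(t) mM;")
  con <- c(con,
           if (is_pde) "real %S%%R%(t,x) mM;" else "real %S%%R%(t) mM;",
           "when(t=t.min)  %S%%R%=0;",
           "//%INSERTEND parmsVars",
           "//%INSERTSTART calc")
  if ("flow" %in% processes)
    con <- c(con, '//%GET %LB% flowCalc ("Cin=%S%in","C=%S%1","V=V1","F=Flow")')
  if ("exchange" %in% processes && n_regions >= 2L)
    for (r in seq_len(n_regions - 1L))
      con <- c(con, sprintf(
        '//%%GET %%LB%% exchangeCalc ("C1=%%S%%%d","C2=%%S%%%d","PS=PS%%S%%%d%d","V1=V%d","V2=V%d")',
        r, r + 1L, r, r + 1L, r, r + 1L))
  con <- c(con, chain)
  if (is_pde)
    con <- c(con, '//%GET %LB% pdeCalc ("C=%S%%R%","D=Dif")')
  con <- c(con,
           '//%COLLECT("%S%%R%:t")',
           "//%INSERTEND calc }")

  list(library = synth_library_text(), constructor = con,
       library_name = lib_name)
}

#' Write a generated fixture to disk and build it
#'
#' Convenience wrapper: writes the generated library and constructor into
#' `dir` and runs [build_model()] on the constructor.
#'
#' @inheritParams generate_species_region_mpc
#' @param dir Directory to write into (default: a session temp directory).
#' @return The built model lines (invisibly also written next to the inputs
#'   as `Synth.mod`).
#' @export
build_synthetic_model <- function(n_species, n_regions,
                                  processes = c("flow", "exchange",
                                                "first-order-reaction"),
                                  seed = 1L, dir = tempfile("synthfix")) {
  fx <- generate_species_region_mpc(n_species, n_regions, processes, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(fx$library, file.path(dir, fx$library_name))
  con_path <- file.path(dir, "Synth.mpc")
  writeLines(fx$constructor, con_path)
  out <- build_model(con_path)
  writeLines(out, file.path(dir, "Synth.mod"))
  invisible(out)
}

#' Count state equations in model text
#'
#' A state equation is an equation whose left-hand side carries a time
#' derivative (`<var>:t = ...`).
#'
#' @param text Model lines (or an `mpc_document`).
#' @return Integer count of distinct states with a time-derivative equation.
#' @export
count_state_equations <- function(text) {
  doc <- if (inherits(text, "mpc_document")) text else suppressWarnings(parse_model(text))
  states <- character()
  for (st in doc$statements)
    if (st$kind == "equation" && "t" %in% st$lhs_derivs)
      states <- c(states, st$lhs_var)
  length(unique(states))
}
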