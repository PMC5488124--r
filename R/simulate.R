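# Interpreter for the ODE subset of generated models: compiles a validated
# document into an executable system (parameters, ordered algebraic
# assignments, ODE right-hand sides, extern input slots) and integrates it
# with classic fixed-step 4th-order Runge-Kutta. Parameter values are used as
# printed except for one unit rule: a parameter whose unit carries `min` with
# a net negative exponent (flows, conductances, maximal reaction velocities
# in ml/(g*min) or umol/(g*min)) is converted to per-second at compile time.

allowed_expr_tokens <- function(tokens) {
  ok <- tokens$kind %in% c("identifier", "number") |
    (tokens$kind == "operator" & tokens$text %in% c("+", "-", "*", "/")) |
    (tokens$kind == "punctuation" & tokens$text %in% c("(", ")"))
  all(ok)
}

parse_rhs_expr <- function(rhs_text, tokens, what, lineno) {
  if (!allowed_expr_tokens(tokens))
    stop(sprintf("line %d: expression for %s uses tokens outside the + - * / subset: %s",
                 lineno, what, rhs_text), call. = FALSE)
  str2lang(rhs_text)
}

minute_exponent <- function(unit) {
  exps <- unit_exponents(unit)
  if (is.null(exps)) return(0)
  e <- exps["min"]
  if (is.na(e)) 0 else unname(e)
}

#' Compile a model document into an executable ODE system
#'
#' Requires a structurally valid, fully resolved model with a single time
#' domain and no spatial derivatives. Algebraic assignments are ordered by
#' dependency (an assignment may reference states, parameters, externs, `t`
#' and earlier algebraics); a cyclic algebraic dependency is an error, as is
#' any spatial derivative (`:x`), which makes the model "not simulatable"
#' by this interpreter.
#'
#' @param doc An `mpc_document`, or model text/lines.
#' @return An `mpc_model` with fields `grid` (t_min, t_max, delta), `states`,
#'   `params` (values after the per-minute conversion), `externs`,
#'   `algebraics` (dependency order) and `odes`.
#' @examples
#' mod <- build_model(system.file("extdata", "Example.mpc", package = "modcon"))
#' compile_model(mod)
#' @export
compile_model <- function(doc) {
  if (!inherits(doc, "mpc_document")) doc <- suppressWarnings(parse_model(doc))
  issues <- validate_structure(doc)
  if (any(issues$severity == "error"))
    stop("model fails structural validation:\n",
         paste(sprintf("  %s:%d: %s", issues$code, issues$lineno, issues$message),
               collapse = "\n"), call. = FALSE)

  sts <- doc$statements
  kinds <- vapply(sts, `[[`, "", "kind")

  dom <- sts[kinds == "domain-decl"]
  tdom <- Filter(function(d) identical(d$name, "t"), dom)
  if (length(tdom) != 1L)
    stop("model must declare exactly one time domain 't'", call. = FALSE)
  if (length(dom) > 1L)
    stop("not simulatable: model declares spatial domains (PDE); this interpreter integrates ODE models only",
         call. = FALSE)
  a <- tdom[[1]]$attrs
  need <- setdiff(c("min", "max", "delta"), names(a))
  if (length(need))
    stop("time domain lacks attribute(s): ", paste(need, collapse = ", "), call. = FALSE)
  grid <- list(t_min = as.numeric(a$min), t_max = as.numeric(a$max),
               delta = as.numeric(a$delta), unit = tdom[[1]]$unit)

  params <- tibble::tibble(name = character(), value = numeric(),
                           printed_value = numeric(), unit = character())
  vars <- tibble::tibble(name = character(), unit = character())
  externs <- tibble::tibble(name = character(), unit = character())
  for (st in sts[kinds %in% c("param-decl", "var-decl", "extern-decl")]) {
    for (e in st$entries) {
      if (isTRUE(e$extern)) {
        externs <- dplyr::bind_rows(externs, tibble::tibble(name = e$name, unit = e$unit))
      } else if (length(e$domains)) {
        if (any(e$domains != "t"))
          stop(sprintf("not simulatable: variable '%s' depends on spatial domain(s) %s",
                       e$name, paste(setdiff(e$domains, "t"), collapse = ", ")),
               call. = FALSE)
        vars <- dplyr::bind_rows(vars, tibble::tibble(name = e$name, unit = e$unit))
      } else {
        printed <- if (is.na(e$init)) NA_real_ else as.numeric(e$init)
        value <- printed * 60^minute_exponent(e$unit)
        params <- dplyr::bind_rows(params, tibble::tibble(
          name = e$name, value = value, printed_value = printed, unit = e$unit))
      }
    }
  }

  odes <- list(); algebraics <- list()
  for (st in sts[kinds == "equation"]) {
    if (length(st$lhs_derivs) == 0L) {
      algebraics[[st$lhs_var]] <- list(name = st$lhs_var,
                                       expr = parse_rhs_expr(st$rhs_text, st$rhs_tokens,
                                                             st$lhs_var, st$lineno),
                                       text = st$rhs_text,
                                       deps = unique(st$rhs_tokens$text[st$rhs_tokens$kind == "identifier"]))
    } else if (identical(st$lhs_derivs, "t")) {
      if (!is.null(odes[[st$lhs_var]]))
        stop(sprintf("state '%s' has more than one time-derivative equation (COLLECT not applied?)",
                     st$lhs_var), call. = FALSE)
      odes[[st$lhs_var]] <- list(state = st$lhs_var,
                                 expr = parse_rhs_expr(st$rhs_text, st$rhs_tokens,
                                                       paste0(st$lhs_var, ":t"), st$lineno),
                                 text = st$rhs_text)
    } else {
      stop(sprintf("not simulatable: line %d has spatial derivative(s) :%s",
                   st$lineno, paste(st$lhs_derivs, collapse = ":")), call. = FALSE)
    }
  }

  # topological order of algebraic assignments
  anames <- names(algebraics)
  ordered <- character()
  remaining <- anames
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      length(setdiff(intersect(algebraics[[n]]$deps, anames),
                     c(ordered, n))) == 0L
    }, TRUE)]
    if (!length(ready))
      stop("cyclic dependency among algebraic assignments: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  algebraics <- algebraics[ordered]

  ics <- list()
  for (st in sts[kinds == "initial-condition"]) ics[[st$var]] <- st$value
  state_names <- intersect(vars$name, names(odes))
  states <- tibble::tibble(
    name = state_names,
    unit = vars$unit[match(state_names, vars$name)],
    init = vapply(state_names, function(s)
      if (is.null(ics[[s]])) NA_character_ else ics[[s]], "", USE.NAMES = FALSE)
  )

  structure(list(grid = grid, states = states, params = params,
                 externs = externs,
                 algebraics = algebraics, odes = odes,
                 name = doc$name),
            class = "mpc_model")
}

#' @export
print.mpc_model <- function(x, ...) {
  cat(sprintf("<mpc_model> '%s': %d states, %d parameters, %d algebraics, %d externs\n",
              ifelse(is.na(x$name), "?", x$name), nrow(x$states), nrow(x$params),
              length(x$algebraics), nrow(x$externs)))
  cat(sprintf("  grid: t in [%g, %g] %s, delta %g\n", x$grid$t_min, x$grid$t_max,
              ifelse(is.na(x$grid$unit), "", x$grid$unit), x$grid$delta))
  invisible(x)
}

#' Time grid of a compiled model
#' @param model An `mpc_model`.
#' @return Numeric vector of output time points (both interval ends included).
#' @export
model_times <- function(model) {
  g <- model$grid
  n <- round((g$t_max - g$t_min) / g$delta)
  g$t_min + g$delta * seq.int(0L, n)
}

# ---- lagged normal input ----------------------------------------------------

lagged_normal_params <- function(mean, rd, skew) {
  stopifnot(mean > 0, rd > 0)
  if (!(skew > 0 && skew < 2))
    stop("skewness must lie in (0, 2) for the Gaussian-convolved-exponential family (the Gaussian spread would otherwise be negative)",
         call. = FALSE)
  v <- (rd * mean)^2
  tau <- (skew * v^1.5 / 2)^(1 / 3)
  sigma2 <- v - tau^2
  list(tau = tau, sigma = sqrt(sigma2), t_c = mean - tau)
}

#' Lagged normal density inflow function
#'
#' The standard arterial inflow concentration-time curve of indicator
#' dilution work: the density of the convolution of a Gaussian with a single
#' exponential, parameterized by moment matching. With total variance
#' `v = (rd * mean)^2`, the exponential time constant solves
#' `skew = 2 tau^3 / v^(3/2)`, the Gaussian spread is `sigma^2 = v - tau^2`
#' and the Gaussian center is `mean - tau`, so the curve's first moment is
#' `mean`, its relative dispersion `rd` and its skewness `skew`; the curve is
#' scaled to integrate to `area`.
#'
#' @param area Area under the curve (concentration x time, e.g. mM*s); > 0.
#' @param mean First temporal moment (mean transit time), s; > 0.
#' @param rd Relative dispersion (SD/mean), dimensionless; > 0.
#' @param skew Skewness, dimensionless, in (0, 2).
#' @return A function of time returning concentrations (vectorized,
#'   non-negative everywhere, zero in the limit t -> -Inf).
#' @examples
#' f <- lagged_normal_fn(area = 20, mean = 3, rd = 0.25, skew = 1.3)
#' f(c(1, 2, 3, 4))
#' @export
lagged_normal_fn <- function(area, mean, rd, skew) {
  stopifnot(area > 0)
  p <- lagged_normal_params(mean, rd, skew)
  force(area)
  function(t) {
    z <- (t - p$t_c) / p$sigma - p$sigma / p$tau
    logf <- -log(p$tau) + p$sigma^2 / (2 * p$tau^2) - (t - p$t_c) / p$tau +
      stats::pnorm(z, log.p = TRUE)
    area * exp(logf)
  }
}

#' Sample the lagged normal input on a time grid
#'
#' @inheritParams lagged_normal_fn
#' @param times Numeric vector of sample times (e.g. [model_times()]).
#' @return A tibble of class `mpc_timeseries` with columns `t` and `value`;
#'   the trapezoid integral over the grid equals `area` up to truncation of
#'   the tails.
#' @export
lagged_normal_input <- function(area, mean, rd, skew, times) {
  f <- lagged_normal_fn(area, mean, rd, skew)
  ts <- tibble::tibble(t = as.numeric(times), value = f(times))
  class(ts) <- c("mpc_timeseries", class(ts))
  ts
}

# ---- integration ------------------------------------------------------------

as_extern_fun <- function(x, name) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  if (is.data.frame(x)) {
    ycol <- if ("value" %in% names(x)) "value" else setdiff(names(x), "t")[1]
    f <- stats::approxfun(x$t, x[[ycol]], rule = 2)
    return(f)
  }
  stop(sprintf("extern '%s': unsupported input (use a function, a constant, or a data frame with columns t and value)",
               name), call. = FALSE)
}

make_eval_env <- function(model) {
  e <- new.env(parent = baseenv())
  for (i in seq_len(nrow(model$params)))
    assign(model$params$name[i], model$params$value[i], envir = e)
  g <- model$grid
  assign("t.min", g$t_min, envir = e)
  assign("t.max", g$t_max, envir = e)
  assign("t.delta", g$delta, envir = e)
  e
}

#' Integrate a compiled model
#'
#' Classic fixed-step 4th-order Runge-Kutta on the model's own time grid,
#' with `substeps` internal steps per output step. Extern inputs may be
#' functions of time, constants, or sampled series (linearly interpolated);
#' an extern not supplied defaults to zero with a warning. Deterministic:
#' identical inputs give identical trajectories.
#'
#' @param model An `mpc_model` from [compile_model()].
#' @param inputs Named list mapping extern names to inputs.
#' @param substeps Internal integration steps per output step (default 10).
#' @return A tibble of class `mpc_timeseries`: column `t`, then one column
#'   per state, algebraic variable and extern, sampled on the model grid.
#' @examples
#' mod <- compile_model(build_model(system.file("extdata", "Example.mpc",
#'                                              package = "modcon")))
#' sim <- integrate_odes(mod,
#'   inputs = list(Ain = lagged_normal_fn(20, 3, 0.25, 1.3), Bin = 0, Cin = 0))
#' @export
integrate_odes <- function(model, inputs = list(), substeps = 10L) {
  stopifnot(inherits(model, "mpc_model"), substeps >= 1L)
  times <- model_times(model)
  e <- make_eval_env(model)

  ext_names <- model$externs$name
  missing_ext <- setdiff(ext_names, names(inputs))
  if (length(missing_ext))
    warning("extern input(s) not supplied, defaulting to 0: ",
            paste(missing_ext, collapse = ", "), call. = FALSE)
  ext_funs <- lapply(stats::setNames(ext_names, ext_names), function(n) {
    if (n %in% names(inputs)) as_extern_fun(inputs[[n]], n) else function(t) rep(0, length(t))
  })

  snames <- model$states$name
  y <- vapply(seq_along(snames), function(i) {
    init <- model$states$init[i]
    if (is.na(init)) 0 else eval(str2lang(init), envir = e)
  }, 1)
  names(y) <- snames
  anames <- names(model$algebraics)
  ode_exprs <- lapply(model$odes[snames], `[[`, "expr")
  alg_exprs <- lapply(model$algebraics, `[[`, "expr")

  set_algebraics <- function(tt, yy) {
    assign("t", tt, envir = e)
    for (i in seq_along(yy)) assign(snames[i], yy[[i]], envir = e)
    for (n in ext_names) assign(n, ext_funs[[n]](tt), envir = e)
    for (n in anames) assign(n, eval(alg_exprs[[n]], envir = e), envir = e)
  }
  deriv <- function(tt, yy) {
    set_algebraics(tt, yy)
    vapply(ode_exprs, function(ex) eval(ex, envir = e), 1)
  }

  nt <- length(times)
  out_states <- matrix(NA_real_, nt, length(snames), dimnames = list(NULL, snames))
  out_alg <- matrix(NA_real_, nt, length(anames), dimnames = list(NULL, anames))
  record <- function(i, tt, yy) {
    set_algebraics(tt, yy)
    out_states[i, ] <<- yy
    if (length(anames))
      out_alg[i, ] <<- vapply(anames, function(n) get(n, envir = e), 1)
  }
  record(1L, times[1], y)
  h <- model$grid$delta / substeps
  for (i in seq_len(nt - 1L)) {
    tt <- times[i]
    for (s in seq_len(substeps)) {
      k1 <- deriv(tt, y)
      k2 <- deriv(tt + h / 2, y + h / 2 * k1)
      k3 <- deriv(tt + h / 2, y + h / 2 * k2)
      k4 <- deriv(tt + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    if (!all(is.finite(y)))
      stop(sprintf("integration aborted: non-finite state value at t = %g (%s)",
                   times[i + 1L],
                   paste(snames[!is.finite(y)], collapse = ", ")), call. = FALSE)
    record(i + 1L, times[i + 1L], y)
  }

  res <- tibble::as_tibble(cbind(t = times, out_states, out_alg))
  for (n in ext_names) res[[n]] <- ext_funs[[n]](times)
  class(res) <- c("mpc_timeseries", class(res))
  attr(res, "state_names") <- snames
  res
}

#' @export
print.mpc_timeseries <- function(x, ...) {
  cat(sprintf("<mpc_timeseries> %d time points, variables: %s\n",
              nrow(x), paste(setdiff(names(x), "t"), collapse = ", ")))
  NextMethod()
}

# ---- mass balance -----------------------------------------------------------

trapz_impl <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Relative mass-balance residual of a simulation
#'
#' For the two-compartment transport-reaction family (flow in and out of
#' region 1, conservative reactions, passive exchange) the moles delivered by
#' inflow must equal the moles stored in both regions at the final time plus
#' the moles carried out by outflow:
#' `residual = |V1*sum(C1(T)) + V2*sum(C2(T)) + F*int(sum(outflow)) -
#' F*int(sum(inflow))| / (F*int(sum(inflow)))`, sums over species, integrals
#' by trapezoid on the output grid. Region membership and inflow slots are
#' read from the naming convention of the model family: states suffixed `1`
#' and `2`, inflow externs suffixed `in`.
#'
#' @param result An `mpc_timeseries` from [integrate_odes()] covering the
#'   full model grid.
#' @param model The `mpc_model` that produced it.
#' @param flow,v1,v2 Names of the flow and volume parameters.
#' @return Dimensionless non-negative scalar; 0 for an all-zero run; error
#'   when inflow is zero but mass is present.
#' @export
mass_balance_residual <- function(result, model, flow = "Flow",
                                  v1 = "V1", v2 = "V2") {
  stopifnot(inherits(model, "mpc_model"))
  pv <- stats::setNames(model$params$value, model$params$name)
  for (p in c(flow, v1, v2))
    if (!p %in% names(pv))
      stop(sprintf("parameter '%s' not found in model", p), call. = FALSE)
  snames <- model$states$name
  r1 <- snames[endsWith(snames, "1")]
  r2 <- snames[endsWith(snames, "2")]
  inflow <- model$externs$name[endsWith(model$externs$name, "in")]
  if (!length(r1) || !length(inflow))
    stop("model does not follow the two-compartment naming convention (states *1/*2, externs *in)",
         call. = FALSE)
  tt <- result$t
  rowsum_of <- function(cols) {
    if (length(cols) == 1L) result[[cols]] else rowSums(as.matrix(result[cols]))
  }
  s1 <- rowsum_of(r1)
  s2 <- if (length(r2)) rowsum_of(r2) else rep(0, length(tt))
  sin <- rowsum_of(inflow)
  stored <- pv[[v1]] * s1[length(tt)] + pv[[v2]] * s2[length(tt)]
  out_int <- pv[[flow]] * trapz_impl(tt, s1)
  in_int <- pv[[flow]] * trapz_impl(tt, sin)
  if (in_int == 0) {
    if (stored == 0 && out_int == 0) return(0)
    stop("mass-balance residual undefined: zero total inflow with nonzero stored or outflowed mass",
         call. = FALSE)
  }
  abs(stored + out_int - in_int) / in_int
}
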