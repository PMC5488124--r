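test_that("the example compiles to the expected executable structure", {
  m <- compiled_example()
  expect_identical(m$states$name, c("A1", "A2", "B1", "B2", "C1", "C2"))
  expect_setequal(m$params$name,
                  c("Flow", "PSA12", "PSB12", "PSC12", "V1", "V2",
                    "Ga2b", "KmB2", "VmaxB2"))
  expect_identical(names(m$algebraics), "Gb2c")
  expect_identical(m$externs$name, c("Ain", "Bin", "Cin"))
  expect_identical(unname(unlist(m$grid[c("t_min", "t_max", "delta")])),
                   c(0, 16, 0.1))

  # parameters in per-minute units are converted to per-second; others kept
  p <- tidy(m)
  expect_equal(p$value[p$name == "Flow"], 1 / 60)
  expect_equal(p$value[p$name == "Ga2b"], 5 / 60)
  expect_equal(p$value[p$name == "KmB2"], 1)
  expect_equal(p$value[p$name == "V1"], 0.05)

  m1 <- compile_model(decay_model(0.1))
  expect_identical(nrow(m1$states), 1L)
  expect_length(m1$algebraics, 0L)
})

test_that("spatial models are rejected as not simulatable", {
  pde <- suppressWarnings(build_synthetic_model(2, 2, "convection-PDE"))
  expect_error(compile_model(pde), "not simulatable")
})

test_that("compile rejects cyclic algebraic dependencies and broken models", {
  cyc <- c("math m {", "realDomain t s; t.min=0; t.max=1; t.delta = 0.5;",
           "real a(t) mM; real b(t) mM; real x(t) mM;",
           "when(t=t.min) x=0;",
           "a = b+x;", "b = a+x;", "x:t = -a*x;", "}")
  expect_error(compile_model(cyc), "cyclic")
  expect_error(compile_model(c("math m {", "}")), "time domain")
  # validation failures propagate
  expect_error(compile_model(c("math m {",
                               "realDomain t s; t.min=0; t.max=1; t.delta = 0.5;",
                               "real x(t) mM;", "x:t = -x*k;", "}")),
               "structural validation")
})

test_that("the lagged normal input matches its moment parameterization", {
  area <- 20; mu <- 3; rd <- 0.25; sk <- 1.3
  tl <- seq(0, 30, 0.01)
  curve <- lagged_normal_input(area, mu, rd, sk, tl)
  expect_true(all(curve$value >= 0))

  a <- trapz_test(curve$t, curve$value)
  m1 <- trapz_test(curve$t, curve$t * curve$value) / a
  v <- trapz_test(curve$t, (curve$t - m1)^2 * curve$value) / a
  m3 <- trapz_test(curve$t, (curve$t - m1)^3 * curve$value) / a
  expect_equal(m1, mu, tolerance = 0.01)
  expect_equal(sqrt(v) / m1, rd, tolerance = 0.01)
  expect_equal(m3 / v^1.5, sk, tolerance = 0.01)

  # area on the model's own [0,16] x 0.1 grid within 0.5% (tail truncation)
  g <- lagged_normal_input(area, mu, rd, sk, seq(0, 16, 0.1))
  expect_equal(trapz_test(g$t, g$value), area, tolerance = 0.005)

  expect_error(lagged_normal_fn(20, 3, 0.25, 2.1), "skewness")
  expect_error(lagged_normal_fn(20, 3, 0.25, -0.5), "skewness")
})

test_that("the closed form equals the numerical Gaussian-exponential convolution", {
  # independent oracle: convolve the two component densities on a fine grid
  p <- modcon:::lagged_normal_params(mean = 3, rd = 0.25, skew = 1.3)
  dt <- 0.002
  tg <- seq(-8, 20, dt)
  gauss <- stats::dnorm(tg, mean = p$t_c, sd = p$sigma)
  texp <- seq(0, 28, dt)
  expo <- stats::dexp(texp, rate = 1 / p$tau)
  expo[1] <- expo[1] / 2  # trapezoid endpoint weight at the density's jump
  conv <- stats::convolve(gauss, rev(expo), type = "open")[seq_along(tg)] * dt
  f <- lagged_normal_fn(1, 3, 0.25, 1.3)
  keep <- tg >= 0 & tg <= 16
  expect_equal(conv[keep], f(tg[keep]), tolerance = 1e-4)

  # skew -> 0 approaches a Gaussian with variance (rd*mean)^2
  fsmall <- lagged_normal_fn(1, 3, 0.25, 0.01)
  tl <- seq(-5, 15, 0.005)
  vals <- fsmall(tl)
  m1 <- trapz_test(tl, tl * vals)
  v <- trapz_test(tl, (tl - m1)^2 * vals)
  m3 <- trapz_test(tl, (tl - m1)^3 * vals)
  expect_equal(v, (0.25 * 3)^2, tolerance = 1e-3)
  expect_lt(abs(m3 / v^1.5), 0.02)
})

test_that("integration reproduces the closed-form exponential decay", {
  m <- compile_model(decay_model(0.1))
  r <- integrate_odes(m)
  exact <- 2 * exp(-2 * r$t)
  expect_lt(max(abs(r$x - exact) / pmax(exact, .Machine$double.eps)), 1e-6)
})

test_that("the solver converges at fourth order", {
  err_at <- function(h) {
    m <- compile_model(decay_model(h))
    r <- integrate_odes(m, substeps = 1L)
    exact <- 2 * exp(-2 * 2)
    abs(r$x[nrow(r)] - exact) / exact
  }
  errs <- vapply(c(0.2, 0.1, 0.05), err_at, 1)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 12 & ratios < 24))
})

test_that("null input gives the null solution; missing externs warn", {
  m <- compiled_example()
  r0 <- integrate_odes(m, inputs = list(Ain = 0, Bin = 0, Cin = 0))
  expect_true(all(abs(as.matrix(r0[m$states$name])) == 0))
  expect_identical(mass_balance_residual(r0, m), 0)
  expect_no_warning(integrate_odes(compile_model(decay_model(0.5)),
                                   inputs = list()))
  expect_warning(integrate_odes(m, inputs = list(Ain = 0)),
                 "Bin, Cin")
})

test_that("runaway trajectories abort with a diagnostic", {
  blow <- c("math blow {",
            "realDomain t s; t.min=0; t.max=5; t.delta = 0.5;",
            "real k = 50 ml/(g*s);", "real V = 0.1 ml/g;",
            "real x(t) mM;", "when(t=t.min) x=1;",
            "x:t = k/V*x*x;", "}")
  expect_error(integrate_odes(compile_model(blow)), "non-finite")
})

test_that("the worked simulation conserves mass through flow, exchange and reactions", {
  m <- compiled_example()
  r <- integrate_odes(m, inputs = example_inputs())
  res <- mass_balance_residual(r, m)
  expect_lt(res, 1e-4)

  # cross-check the trajectory against an independent general-purpose solver
  pv <- stats::setNames(m$params$value, m$params$name)
  Ain <- example_inputs()$Ain
  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), {
      Gb2c <- VmaxB2 / (KmB2 + B2)
      list(c(
        A1 = (Flow / V1) * (Ain(t) - A1) + PSA12 / V1 * (A2 - A1),
        B1 = (Flow / V1) * (0 - B1) + PSB12 / V1 * (B2 - B1),
        C1 = (Flow / V1) * (0 - C1) + PSC12 / V1 * (C2 - C1),
        A2 = -Ga2b / V2 * A2 + PSA12 / V2 * (A1 - A2),
        B2 = Ga2b / V2 * A2 - Gb2c * B2 / V2 + PSB12 / V2 * (B1 - B2),
        C2 = Gb2c * B2 / V2 + PSC12 / V2 * (C1 - C2)))
    })
  }
  y0 <- stats::setNames(rep(0, 6), c("A1", "B1", "C1", "A2", "B2", "C2"))
  ref <- deSolve::ode(y0, model_times(m), rhs, pv, method = "lsoda",
                      atol = 1e-10, rtol = 1e-10)
  for (s in names(y0))
    expect_lt(max(abs(r[[s]] - ref[, s])), 1e-6)
})

test_that("halving the grid step improves the trapezoid-limited residual", {
  base <- built_example()
  res_h <- function(h) {
    txt <- sub("t.delta = 0.1;", sprintf("t.delta = %g;", h), base, fixed = TRUE)
    m <- compile_model(txt)
    r <- integrate_odes(m, inputs = example_inputs(), substeps = 1L)
    mass_balance_residual(r, m)
  }
  r1 <- res_h(0.2); r2 <- res_h(0.1)
  # the residual's own trapezoid quadrature limits convergence to 2nd order
  expect_gt(r1 / r2, 2.5)
  expect_lt(r2, 1e-4)
})

test_that("tidiers and plots summarize results without computing new ones", {
  m <- compiled_example()
  g <- glance(m)
  expect_identical(g$n_states, 6L)
  expect_identical(g$n_externs, 3L)
  r <- integrate_odes(m, inputs = example_inputs())
  p <- autoplot(r, vars = c("A1", "A2", "Ain"))
  expect_s3_class(p, "ggplot")
})
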