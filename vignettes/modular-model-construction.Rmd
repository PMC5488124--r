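---
title: "Modular construction of compartmental model code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular construction of compartmental model code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcon)
```

## The problem

Writing a multi-compartment transport-reaction model by hand means repeating
the same few mathematical fragments — flow through a well-mixed volume,
passive exchange across a membrane with a permeability-surface (PS)
conductance, first-order and Michaelis-Menten reactions — once per species
and per compartment, and then merging, by hand, every process contribution
to each state's rate equation. That is slow and error-prone exactly where
models get interesting: when many variants must be configured and tested.

`modcon` treats the model file as a *generated* artifact. Model fragments
live as named **modules** in annotated plain-text libraries; a short
**constructor** file mixes ordinary declarative model code with directive
lines, and the package assembles the complete model. Because directives are
written as `//%` comments, a library file is simultaneously a runnable model
and a machine-readable archive of parts.

## The construction method

Four directive families do the work, executed in this order by
`build_model()`:

1. **REPLACE** declares placeholder bindings. Bindings inside one REPLACE
   advance *in parallel* (a species list and its matching list of PS values
   step together); bindings in separate REPLACE directives are independent,
   and a line mentioning placeholders from several groups is replicated over
   the *cross product* of their index ranges. Earlier-declared groups vary
   fastest. With compartments `(1,2)` declared before species `(A,B,C)`,
   the template `when(t=t.min) %AB%%N%=0;` therefore expands to initial
   conditions in the order `A1, A2, B1, B2, C1, C2`.
2. **GET** fetches a named module from a library file and splices it in,
   rewriting identifiers through an explicit old=new mapping. Renaming is
   simultaneous, single-pass and token-bounded: a key that is a substring of
   a longer identifier (`A` inside `VmaxA`) never fires inside it, and
   substituted text is never re-scanned, so swap-like mappings are safe.
   Comments are renamed too, so module commentary tracks the new names. A
   key that matches nothing in the module is reported as a warning, not an
   error: constructors routinely pass a superset mapping to variant modules.
3. **COLLECT** merges equations. All equations whose left-hand side matches
   one of the pattern's expansions (`%AB%%N%:t` covers all six states) are
   removed and re-emitted at the COLLECT position as one equation per state,
   right-hand sides concatenated in stream order, each later contribution
   prefixed `+` unless it already starts with `-`. Merged equations are
   ordered by first occurrence of their state in the stream, which is why
   reaction-bearing compartment-2 equations precede the flow-bearing
   compartment-1 equations in the worked example.
4. **INSERTSTART / INSERTEND** mark sections of the constructor; in the
   output they are rewritten to `//%START` / `//%END` markers, which makes
   every generated model itself an indexable library — the mechanism for
   hierarchical reuse (a whole-organ model can GET an assembled cell model).

Everything else passes through verbatim, so the constructor remains ordinary
model code wherever no generation is needed.

### Design choices in the directive engine

Several behaviors are deliberate choices where the format admits more than
one reading:

* A `//%END` closes the most recently opened block regardless of the name
  after it; a name mismatch warns rather than errors. Distributed libraries
  contain case-mismatched END names, and indexing must not die on them.
  Nested `//%START` is an error — nesting is ambiguous under
  "END closes the latest START".
* A GET whose argument list is not closed on its line continues on following
  `//%` lines. Continuations are merged into one logical line *before*
  REPLACE expansion, so a replicated multi-line GET cannot interleave its
  copies. Duplicate rename pairs with identical values collapse silently;
  the same key mapped to different values is an error.
* COLLECT is the one directive exempt from line replication: its quoted
  pattern is expanded internally into the concrete target list. Replicating
  the directive line instead would emit merged equations in expansion order
  rather than first-occurrence order.
* Declaration order in the output follows expansion order. Published
  listings sometimes regroup declarations for presentation; since
  declaration order carries no meaning in a declarative language, the
  reproduction comparison (`token_equivalent()`) compares declarations as a
  multiset of per-name units and everything else as an ordered token
  sequence, ignoring comments and whitespace.

## Validation

`validate_model()` checks what the generator is responsible for:
construction actually finished (no residual `%placeholder%`, no unexecuted
directive) and the result is structurally coherent (all identifiers
declared, every `x:t` state has an initial condition, every time-dependent
variable is defined by some equation unless it is an `extern` input, unit
strings parse against `unit := factor (('*'|'/') factor)*`). Dimensional
*balance* is deliberately not checked: units are carried opaquely for the
downstream compiler, which owns unit conversion.

## The interpreter

`compile_model()` turns a validated ODE-only document into an executable
system: parameters, algebraic assignments sorted by dependency (cycles are
an error), ODE right-hand sides over the `+ - * /` expression subset, and
extern input slots. Spatial derivatives (`:x`) make a model "not
simulatable" here by design — distributed models are counted and validated,
not integrated.

One numerical convention matters: the example corpus mixes seconds (the time
grid) with per-minute rate units. A parameter whose unit carries `min` with
net negative exponent — `ml/(g*min)`, `umol/(g*min)` — is divided by 60 at
compile time; everything else is used as printed. This single rule makes the
worked example internally consistent; `tidy()` on a compiled model shows
both the printed and the converted values.

`integrate_odes()` is classic fixed-step 4th-order Runge-Kutta with 10
internal substeps per output step by default. Fixed-step was chosen over
adaptive integration because it is deterministic, trivially reproducible,
and entirely adequate at the grids these models declare (0.1 s against
fastest rate constants of a few per second). The suite verifies 4th-order
convergence against the closed-form exponential (error ratios 17-19 per
halving, bracketing the asymptotic 16) and cross-checks the full worked
simulation against an independent adaptive solver.

### The lagged normal inflow

The arterial inflow curve is the lagged normal density: a Gaussian convolved
with a single exponential, the standard indicator-dilution input shape. It
is parameterized by area, mean transit time, relative dispersion
RD = SD/mean, and skewness, via moment matching: total variance
$v = (RD \cdot \bar t)^2$, exponential time constant from
$\mathrm{skew} = 2\tau^3/v^{3/2}$, Gaussian spread $\sigma^2 = v - \tau^2$,
Gaussian center $\bar t - \tau$. Skewness must lie in (0, 2) or $\sigma^2$
would be negative — that is the family's intrinsic bound, not an
implementation limit. The closed form is checked against direct numerical
convolution of the two component densities, and the sampled curve's
numerically computed moments recover the parameters to well under 1%.

### Mass balance as verification

For the flow/exchange/conservative-reaction family, everything delivered
must end up stored or washed out:

$$\mathrm{residual} = \frac{\left| V_1 \sum_s C_{s1}(T) + V_2 \sum_s C_{s2}(T)
 + F \int_0^T \sum_s C_{s1}\,dt - F \int_0^T \sum_s C_{s,\mathrm{in}}\,dt \right|}
 {F \int_0^T \sum_s C_{s,\mathrm{in}}\,dt}$$

with integrals by trapezoid on the output grid. The worked example under its
published inflow gives a residual of about $2.6 \times 10^{-6}$, comfortably
below the $10^{-4}$ verification threshold. One subtlety: because the
residual's own quadrature is trapezoidal, its convergence under grid
refinement is second-order (about 4x per halving) once the solver error is
subdominant; the solver's fourth order is therefore asserted on the
closed-form test, where no quadrature intervenes.

## The synthetic model family

`generate_species_region_mpc()` emits a library-plus-constructor pair with
the same shape as the worked example, scaled to `n_species` x `n_regions`:
flow enters region 1, exchange couples adjacent regions, a reaction chain
runs through the species in the last region (Michaelis-Menten for the final
link when selected), or — for the convection-PDE process — every
species-region state receives a convection-diffusion equation over a spatial
domain (`x` in [0, 0.1] cm, 0.01 cm steps; a conventional capillary-scale
grid, chosen once). Time grids are the example's own: [0, 16] s in 0.1 s
steps. Randomized parameter values are drawn log-uniformly from [0.1, 10]
under a caller seed so fixtures are reproducible; positivity is the only
constraint the family needs. A reaction chain needs a product, so a
one-species request with a reaction process is promoted to two species
(substrate and product) — the single deviation from the
states = species x regions rule.

What the generator emulates is the *combinatorial structure* of real model
families — state count, coupling pattern, declaration/IC bookkeeping — which
is exactly what the constructor is responsible for. It does not emulate
physiological parameter magnitudes, stiffness contrasts, or spatially
resolved boundary-condition sets; passing its tests says the construction
and bookkeeping scale correctly, not that any generated model is a validated
physiological description.

## Problem sizes and costs

Everything here is deliberately small: the worked example builds in well
under a second; the 15-equation convection family likewise; the full
simulation is 161 output points x 10 substeps over 6 states. The
property-style tests run dozens of randomized cases in a few seconds under
fixed seeds.

## Known limitations

* Only the ODE subset is integrated; `:x` models are constructed, counted
  and validated but not solved.
* No reconciliation of clashing declarations arriving from different GETs
  beyond exact-duplicate collapse; in strict mode a conflicting
  re-declaration is an error. Smarter merging of near-identical module code
  is out of scope.
* No semantic/ontological annotation of modules: module choice and renaming
  maps are the user's statement of intent.
* The per-minute conversion is the only unit arithmetic performed; models
  mixing other time units would need their parameters pre-converted.
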