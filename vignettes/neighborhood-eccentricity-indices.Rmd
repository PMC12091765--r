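---
title: "Neighborhood-eccentricity indices, the NEC polynomial and QSPR modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-eccentricity indices, the NEC polynomial and QSPR modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necindex)
```

## The descriptors

A drug molecule is represented as its hydrogen-depleted graph $G$: vertices
are the heavy atoms, edges the covalent bonds between them, with bond order
and element identity ignored. For a connected $G$, the eccentricity
$\varepsilon(u)$ of a vertex is its maximum graph distance to any vertex,
and the *neighborhood eccentricity* is

$$\mu(u) = \sum_{v \in N(u)} \varepsilon(v),$$

the sum of the eccentricities of the neighbors of $u$. Edges are grouped
into classes $E_{i,j} = \{uv : \mu(u) = i, \mu(v) = j\}$ (keys normalised
so $i \le j$) with multiplicities $m_{ij}$, and the NEC polynomial is the
generating polynomial of this partition,

$$\mathrm{NEC}(G, x, y) = \sum_{i \le j} m_{ij}\, x^i y^j .$$

A note on the $\mu$ definition: the defining formula is sometimes typeset
with the eccentricity of $u$ itself inside the sum, which would reduce
$\mu(u)$ to $\deg(u)\,\varepsilon(u)$. We use the sum of *neighbor*
eccentricities. The choice is not free: only this reading makes the
reconstructed thalidomide skeleton (19 atoms, 21 bonds) reproduce the
published 12-class edge partition exactly, and the package tests enforce
that cross-check.

Eight descriptors are computed from the partition. Each is an edge sum
$\sum_{(i,j)} m_{ij} f(i,j)$ and, equivalently, an operator composition
applied to the NEC polynomial and evaluated at $(1,1)$:

| index | $f(i,j)$ | operator route |
|---|---|---|
| NE1 | $i+j$ | $(d_x + d_y)$ |
| NE2 | $ij$ | $d_x d_y$ |
| NFE | $i^2+j^2$ | $d_x^2 + d_y^2$ |
| NRE | $ij(i+j)$ | $d_x d_y (d_x + d_y)$ |
| NSD$_{deg}$E | $i/j + j/i$ | $d_x S_y + S_x d_y$ |
| NISIE | $ij/(i+j)$ | $S_x J d_x d_y$ |
| NHE | $2/(i+j)$ | $2 S_x J$ |
| NAE | $\bigl(ij/(i+j-2)\bigr)^3$ | $S_x^3 \Psi_{-2} J d_x^3 d_y^3$ |

Here $d_x = x\,\partial/\partial x$ multiplies each monomial by its
$x$-exponent, $S_x$ divides by it, $J$ substitutes $y = x$, and $\Psi_k$
shifts $x$-exponents by $k$ (possibly below zero, so the polynomial type is
a Laurent polynomial). The NHE and NSD$_{deg}$E edge terms are occasionally
garbled in print; the forms above are confirmed both by the operator
columns and by recomputation of the published thalidomide values
(48.627 and 1.2803...).

`compute_all_indices()` always runs *both* routes and stops unless they
agree exactly, which is the package's core internal consistency guarantee.

## Exact arithmetic

The operator compositions are evaluated in exact rational arithmetic, never
floating point, so that the two routes can be compared for *equality*
rather than near-equality. Plain double-based rationals are not enough:
summing the NAE terms of the larger drugs runs the common denominator
(an lcm of values $(i+j-2)^3$) past $10^{30}$, far beyond the $2^{53}$
integer range of a double. The package therefore carries a small exact
layer (`xr_*` functions): numerators are big integers stored as base-$10^7$
limb vectors, and denominators are kept in factored form as products of
small primes. The factored denominator is what keeps the layer simple —
divisions only ever come from $S_x$/$S_y$ dividing by a monomial exponent,
so every denominator prime is small, reduction needs only small-divisor
divisions, and equality of canonical forms is structural. Decimal reporting
(`xr_format`) is computed exactly with half-up rounding at the same
precisions as the published tables (integers for NE1–NRE, 3 decimals for
NSD$_{deg}$E and NAE, 4 for NISIE and NHE); conversion to doubles happens
only at that final step.

Distances and eccentricities are delegated to igraph's unweighted
breadth-first search; the test suite checks them against an independent
Floyd–Warshall implementation on seeded random graphs.

## Fixtures

Every drug ships with its published edge partition (the authoritative
fixture, transcribed class by class) and declared vertex/edge counts. Four
drugs — arbidol, chloroquine, hydroxy-chloroquine and thalidomide — also
ship reconstructed heavy-atom skeletons as edge lists. A reconstruction is
accepted only if its *computed* partition equals the published one exactly;
all four shipped graphs pass, which validates both the reconstruction and
the whole distance–eccentricity–partition pipeline. Remdesivir is kept
partition-level only: its published graph has 41 heavy atoms while the
standard structure (C27H35N6O8P) has 42, so no certified reconstruction is
possible. Skeletons for the remaining large drugs were not attempted; the
partitions carry all the information the indices need.

## The QSPR study

`qspr_fit()` fits ordinary least squares, linear $Y = A + B\,\mathrm{TI}$
or cubic $Y = A + B\,\mathrm{TI} + C\,\mathrm{TI}^2 + D\,\mathrm{TI}^3$,
and reports $R$, $R^2$, the standard error of the estimate
$\sqrt{SSE/\mathrm{df}}$, the Fisher statistic with $(1, n-2)$ or
$(3, n-4)$ degrees of freedom, and its upper-tail $p$-value, called
significant below 0.05. The cubic design is centred and scaled before
solving — NAE reaches $4 \times 10^5$, so the raw basis
$(x, x^2, x^3)$ is numerically hostile — and the coefficients are mapped
back to the raw basis algebraically.

Missing values are explicit `NA`s (remdesivir has no tabulated boiling
point, vaporisation enthalpy or flash point). The published study never
states its sample-selection rule, so the package implements three policies
and makes the choice visible:

* `pairwise` — every computation uses all drugs with the needed values;
* `complete-case` — remdesivir is dropped everywhere ($n = 7$);
* `paper-mixed` (default) — correlations are pairwise-complete,
  coefficient fits complete-case.

`paper-mixed` is the only combination that reproduces the published
correlation matrix and coefficient tables simultaneously: the NE1/MW
correlation is 0.968 at $n = 8$ but 0.966 at $n = 7$, while the MW~NE1
intercept 207.541 only appears at $n = 7$. The reproduction report flags
policy-induced differences as expected divergences instead of failures.

## Reproducing the published tables

`cmd_reproduce()` regenerates analogues of the published tables from the
shipped fixtures and writes a cell-by-cell comparison. Tolerances: integer
indices exact; rational indices $5 \times 10^{-4}$ relative (the published
table truncates rather than rounds its last digit); correlations and
regression coefficients $\pm 0.005$; predictions $\pm 0.05$.

Three reproduction details were established while building the package and
are encoded in the report rather than papered over:

1. **The regressions were run on the printed index table.** The steep NHE
   fits (slopes near 900) only reproduce when the truncated printed NHE
   values are used as inputs; the report therefore feeds the printed index
   table to the regression phase while separately comparing the computed
   indices against that table.
2. **The published prediction tables were generated from the rounded,
   printed coefficients.** Applying full-precision coefficients shifts
   predictions by up to 0.5 units; applying the printed three-decimal
   coefficients reproduces the BP~NE1 column exactly for all eight drugs.
   `prediction_table()` exposes this as `coef_digits`; ordinary use
   defaults to full precision.
3. **Two printed cells fail any faithful re-fit** and are excluded from
   the counted cells with notes: the MR~NAE intercept (printed 86.284,
   re-fit 86.824 — a digit transposition; the slope and $R^2$ of the same
   row verify) and the PSA~NSD$_{deg}$E "cubic" row, whose printed $R^2$,
   SE and F all match a *quadratic* fit exactly (the printed cubic
   coefficient is 0.000, i.e. the collinear cubic term was dropped by the
   original software). The cubic correlation matrix is reported but not
   counted, since the sample underlying the printed values is unstated.
   Non-NE1 prediction columns are likewise reported but not counted; some
   are inconsistent with their own printed coefficients.

## Property-based testing and problem sizes

The invariants are checked on seeded random connected graphs built as a
random spanning tree plus extra non-parallel edges: route equality for all
eight indices on 200 graphs with 3–15 vertices, metric axioms and oracle
equality for distances, eccentricity bounds ($\mathrm{diam} \le 2\,
\mathrm{rad}$, adjacent eccentricities differing by at most 1,
$\deg(u)\,\mathrm{rad} \le \mu(u) \le \deg(u)\,\mathrm{diam}$), per-edge
inequalities ($2\,\mathrm{NE2} \le \mathrm{NFE}$, $\mathrm{NHE} \le |E|$,
$\mathrm{NSD}_{deg}\mathrm{E} \ge 2|E|$), and OLS parameter recovery within
three standard errors on $n = 50$ simulated points. These generators
emulate graph-theoretic structure only — they are not molecules, carry no
valence constraints, and say nothing about chemistry; what passing tests
show is that the machinery is exact and internally consistent, not that
the descriptors predict properties of unseen compounds.

## Limitations

* The descriptors ignore element identity and bond order by construction;
  two different molecules with the same skeleton get identical indices.
* With seven complete cases, the regressions have 5 (linear) or 3 (cubic)
  residual degrees of freedom; the fitted models are reproductions of the
  published analysis, not models anyone should extrapolate from.
* The NAE index is undefined on an edge class with $i + j = 2$ (only
  possible for the two-vertex graph); the package raises an error rather
  than returning a sentinel.
* The optional MOL/SDF reader is a convenience importer (via ChemmineR)
  and is not used by any fixture or test.
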