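---
title: "Comparing charge-assignment methods with standardized regression and confluence metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing charge-assignment methods with standardized regression and confluence metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confluentq)
```

## The problem

Net atomic charges (NACs) are not quantum-mechanical observables: dozens of
methods exist to assign a partial charge to each atom in a molecule, and
they disagree. Given a table of NACs — one row per atom-in-material, one
column per charge-assignment method, with each molecule carrying a known
integer net charge — `confluentq` answers three questions:

1. **Is the table internally consistent?** Charges must sum to integers
   molecule by molecule, and no atom can be assigned more positive charge
   than its nuclear charge.
2. **How do methods relate statistically?** Each method has a
   charge-transfer magnitude (its NAC spread) and a correlation to every
   other method; regression between two methods should not depend on which
   one is called "x".
3. **Which method best represents the whole group?** Confluence metrics
   rank methods by how strongly each correlates with all the others, and
   quantify how fragile that ranking is to dataset manipulation.

A point-charge electrostatics module evaluates how well a set of NACs
reproduces a reference molecular electrostatic potential, and a synthetic
generator produces correlated NAC tables with known ground truth so every
stage is testable without quantum-chemistry input.

## Standardized variables and instant least squares fitting

All correlation machinery runs on standardized variables,
$w_i = (\alpha_i - \alpha_{\mathrm{avg}})\, s_\alpha / \sigma_\alpha$, where
$\sigma_\alpha$ is the root-mean-squared deviation from the mean and
$s_\alpha = \pm 1$ an optional sign flip. The divisor convention matters
only as a choice that must be uniform: the default is the population
convention $M = N$ (the table is treated as the entire population of
interest, not a sample); the sample convention $M = N - 1$ is available via
`convention = "sample"` everywhere, and mixing conventions across variables
is impossible by construction.

Ordinary ("simple") least squares of $\alpha$ on $\beta$ and of $\beta$ on
$\alpha$ give two inequivalent lines whenever $|\Omega_{\alpha\beta}| < 1$;
`slsf_fit()` reports both plus the reversibility defect $|m m' - 1| =
|1 - \Omega^2|$. The remedy is **instant least squares fitting (ILSF)**:
standardize both variables with $s_x = 1$ and $s_y =
\operatorname{sign}(\Lambda_{xy})$ so the pair $(w, z)$ is positively
correlated; then the line $z = w$ — i.e. $(\zeta, \eta) = (1, 0)$ — is
*simultaneously* the total least squares (TLS) fit, the orthogonal distance
regression (ODR), and the first-principal-component regression of the
standardized pair, for any positively correlated input. At that optimum

$$L^{(1)} = \sum_i \big[(\Delta w_i)^2 + (\Delta z_i)^2\big] = 4M(1-\Omega_{wz}),
\qquad
L^{(2)} = \sum_i \frac{(\Delta z_i)^2}{1+\zeta^2} = M(1-\Omega_{wz}),$$

so $L^{(1)} = 4L^{(2)}$, and the fit quality equals $\Omega_{wz}$.
`evaluate_losses()` exposes both loss surfaces for any candidate
$(\zeta, \eta)$; the test suite confirms by numeric minimization (BFGS and a
dense grid) that $(1, 0)$ is the minimizer of both, and that `ilsf_fit(x, y)`
and `ilsf_fit(y, x)` produce mutually inverse original-unit lines. ILSF is
neither Deming regression (which normalizes by measurement-error variances,
not total variances) nor ordinary least squares on standardized variables
(whose slope is $\Omega$, not 1); the tests hold counterexamples for both.

Two numerical guards: a constant column is a hard error (degenerate
variance), and $|\Lambda_{xy}| < 10^{-12}\sigma_x\sigma_y$ is treated as
exactly zero, in which case the model collapses to the single point of the
means — returned as a flagged degenerate fit rather than an error, since
uncorrelated columns are a legitimate, if extreme, input.

## Confluence metrics

For a mutually positively correlated group of $V$ standardized variables,
the **average standardized variable** $\phi_i = \frac{1}{V}\sum_\alpha
w_i^{(\alpha)}$ is the linear combination with the largest possible summed
correlation to the group. With the self term included,

$$S_\alpha = \sum_\beta \Omega_{\alpha\beta}, \qquad
S_\phi = \sqrt{\textstyle\sum_{\alpha\beta} \Omega_{\alpha\beta}}, \qquad
\Omega(\alpha, \phi) = S_\alpha / S_\phi,$$

and the **superdelegate** is the member maximizing $S_\alpha$. The self
term is included deliberately: a method uncorrelated with everything still
has $S_\alpha = 1$, and threshold counts then naturally count the method
itself (a count of 1 means "correlated only with itself").

PCA of the correlation matrix (`nac_pca()`) complements this: eigenvalues
sum to $V$, so each eigenvalue is "how many variables' worth" of
correlation a component explains. The correlation of variable $\alpha$ to
component $k$ is $v_\alpha^{(k)}\sqrt{\lambda^{(k)}}$
(`pc_correlation()`), the one-step power iteration from the all-ones trial
gives $S/\lVert S\rVert_2$ as an excellent main-principal-component (MPC)
approximation, and

$$S_{\mathrm{MPC}} = \sqrt{\lambda_{\mathrm{MPC}}} \sum_\alpha
v_\alpha^{(\mathrm{MPC})}, \qquad
\Omega(\phi, \mathrm{MPC}) = S_{\mathrm{MPC}} / S_\phi \le 1.$$

The $\Omega(\phi, \mathrm{MPC})$ expression is implemented as this derived
identity and validated in the tests (and at acceptance-script runtime)
against the brute-force correlation of $\phi$ with the MPC component
scores, rather than taken on faith: both routes agree to $10^{-10}$ on
synthetic data.

Two ranking identities follow immediately and are asserted on every run:
ordering by $S_\alpha$ equals ordering by $\Omega(\alpha,\phi)$, and
ordering by MPC coefficient equals ordering by $\Omega(\alpha,
\mathrm{MPC})$. `rank_methods()` therefore reports six criteria (the four
above plus one threshold count per cut), with ties broken alphabetically so
output is reproducible.

Conventions worth noting:

* **Threshold counts** default to strict `>` (the convention used in
  summary tables); block shading conventionally uses `>=`, so
  `threshold_counts()` and `find_blocks()` expose a `strict` flag and a
  `>=`-based edge rule respectively.
* **Eigenvector signs**: the MPC is flipped so its coefficient sum is
  positive (all-positive coefficients are expected for a mutually positive
  group); other components so their largest-magnitude coefficient is
  positive.
* **Degeneracy**: eigenvalue gaps below $10^{-9}$ flag the affected
  components as non-unique (rotation freedom); `mpc_summary()` refuses a
  degenerate top eigenvalue.
* **Block ordering**: any seriation that keeps connected components
  contiguous is acceptable for heatmap display; the implementation sorts
  components by size and members by within-component degree, which is
  simple and deterministic.

If the correlation matrix is not mutually positive, $S_\alpha$ is still
computed but the $\phi$-based quantities are flagged with a warning — they
lie outside the premise of the confluence construction.

## Consistency checking and physical bounds

Because every molecule carries an integer net charge, the running sum of
NACs over any block of whole molecules must reach an integer — for every
method independently, and the *same* integer (the summed net charge).
`partition_blocks()` packs whole molecules greedily into blocks of roughly
500 atoms (molecules are never split); `check_block_sums()` classifies each
(block, method) residual from the nearest integer. The two tolerances are a
documented choice, not a derived constant: typical numerical-integration
residuals in per-method average charges are of order 0.002 e, so
`tol_negligible = 0.01` e absorbs benign integration noise while
`tol_fatal = 0.05` e marks sums no integration error should produce. A
block whose *rounded* sum disagrees with the known summed net charge is
always fatal regardless of residual. Both tolerances are arguments (and CLI
flags). Missing cells are reported, never imputed; statistical operations
refuse tables with missing values unless rows are dropped explicitly.
Corrections to a table are applied only declaratively from a YAML/JSON file
(`set_value` / `drop_molecule`), with every applied action recorded, so no
edit is silent.

`validate_physical_bounds()` enforces two rules: a NAC above the atomic
number assigns a negative electron count ($q > Z$), and when atomic spin
moments are supplied the remaining electrons must cover the spin
($Z - q \ge |\mathrm{ASM}|$) — a hydrogen with $q = 0.75$ cannot carry an
ASM of 0.9 on its remaining 0.25 electrons.

## Robustness of rankings

`spam_analysis()` models flooding the dataset with $k$ trivial variants of
one method, each correlating 1.0 with the target and inheriting its
correlation row — the worst-case assumption that makes the manipulation
maximally effective. Closed forms follow: the target's $S$ gains exactly
$k$; any other method gains $k\,\Omega(\alpha, \mathrm{target})$; threshold
counts gain $k$ exactly when the method's correlation to the target clears
the cut. For $k \le 1000$ the enlarged $(V+k)\times(V+k)$ matrix is also
built explicitly and the closed forms verified against its row sums at
every call. Spamming a non-leading method produces a **ranking
abnormality** — the $S_\alpha$ leader and the count-criterion leader
diverge — which is exactly how such manipulation is detected. A noisy
variant model (correlation $1 - \varepsilon$) would weaken all gains; it is
deliberately not modeled, since the exact-duplicate assumption is the
conservative one for detection purposes.

`swap_sensitivity()` brackets each method's rank under the most adversarial
single $\pm 1$ count perturbation, and `subset_rerank()` recomputes the
whole analysis on a column subset.

## Point-charge electrostatics

Units follow the field's mixed conventions: coordinates and vdW radii in
bohr, charges in e, potentials in kcal mol⁻¹ e⁻¹ (conversion 627.509474
kcal mol⁻¹ per hartree), dipoles in atomic units.
`build_vdw_shell_grid()` lays a uniform axis-aligned cubic lattice centered
at the geometric center and keeps points at 1.4–2.0 times the vdW radius:
at least 1.4 R from *every* atom and within 2.0 R of at least one — the
standard all-atoms exclusion; grid weights are uniform. The spacing
defaults to 0.4 bohr and is always explicit, since published work tends to
report grid-converged ratios rather than spacings; the tests verify small
grids against brute-force predicate enumeration, so correctness does not
hinge on a particular spacing.

`esp_errors()` reports RMSE against the reference potential and RRMSE
$= 100 \cdot \mathrm{RMSE} / \mathrm{RMSE}_{\mathrm{zero}}$, the error as a
percentage of the zero-charge model (whose RMSE is just the root mean
square of the reference). Model dipoles are $\sum_a q_a \mathbf r_a +
\sum_a \mathbf d_a$; for charged systems the origin is fixed at the center
of nuclear charge (the dipole of an ion is origin-dependent), for neutral
systems the origin cancels. For a bent symmetric A–B–A molecule the
molecular dipole determines the NACs uniquely:
`triatomic_dipole_charges()` solves $q_B + 2q_A = Q$ together with the
axial dipole equation, rejecting linear geometries (where charges cannot
affect the axial dipole) and reference dipoles with an off-axis component.

## The synthetic generator

`generate_nac_dataset()` draws, per atom, two latent patterns $t_i, u_i$
(iid standard normal, centered within each molecule) and sets

$$q_i^{(\alpha)} = \sigma_\alpha\big(\cos\theta_\alpha\, t_i +
\sin\theta_\alpha\, u_i + \eta_\alpha\, \varepsilon_i^{(\alpha)}\big)
+ \text{(per-molecule shift)},$$

where the uniform shift makes every method's molecular sum equal the
molecule's integer net charge *exactly* — so the consistency checker passes
on clean output by construction. The implied large-sample correlation is
$\Omega_{\alpha\beta} = \cos(\theta_\alpha - \theta_\beta) /
\sqrt{(1+\eta_\alpha^2)(1+\eta_\beta^2)}$; because the within-molecule
centering shrinks signal and noise by the same factor, empirical
correlations converge to this closed form (verified to within
$3/\sqrt{N}$). Empirical charge-transfer magnitudes converge to
$\sigma_\alpha\sqrt{1+\eta_\alpha^2}$ up to the centering shrink
$\sqrt{1 - 1/\bar n}$, which is why the magnitude-recovery test uses large
molecules. For molecules with nonzero net charge the shift adds a common
$Q/n$ term across methods, slightly perturbing correlations — the default
configuration keeps 90% of molecules neutral, and correlation-recovery
tests use all-neutral populations.

The default 20-method profile mimics the observed topology of real
charge-method families: a 14-method main block on the primary factor plus
two 3-method side blocks at $\theta = \pm 0.7$ rad, scales spanning
0.13–0.63 e. Three independent seeded streams (structure/latents, method
noise, corruption) ensure that corrupting a table cannot perturb its
content, and that identical configurations are byte-identical.

What the generator does *not* emulate: element-dependent charge chemistry
(all atoms are generic), heavy-tailed or heteroscedastic method errors,
buried-atom failure modes, and basis-set artifacts. Passing tests on
synthetic data therefore demonstrate the statistical machinery, not the
chemical validity of any particular charge method.

`corrupt_dataset()` injects the three error classes real compilations
exhibit — column-wide integration jitter, missing cells, isolated wrong
values — with an exact log, so tests can assert that the consistency
checker flags precisely the corrupted block and method.

## Problem sizes and runtime choices

The test suite runs synthetic populations of roughly 200–4000 molecules
(10³–2×10⁴ atoms): large enough that stochastic tolerances like
$3/\sqrt{N}$ are meaningful, small enough that the full suite completes in
well under a minute on one core. Property-style suites use 100–200 random
draws under fixed seeds. ESP tests use toy-molecule grids at 0.5–0.9 bohr
spacing (a few thousand points), each verified against brute-force
enumeration. The ranking-recovery study (20 seeds × 20 000 atoms × 10
methods) asserts that the lowest-noise method tops the $S_\alpha$ ranking
in at least 18 of 20 runs.

## Known limitations

* Missing-data handling is deliberately blunt (report, never impute);
  there is no partial-pairwise correlation mode.
* ILSF is bivariate and unweighted; no robust/outlier-resistant variant.
* `find_blocks()` ordering is a display heuristic, not an optimal
  seriation.
* The spam model assumes perfect-copy variants; independent-noise variants
  would change threshold-count gains and are out of scope.
* Covariance-matrix PCA is supported as an option but all confluence
  metrics are defined on the correlation matrix.

## A worked example

```{r example}
d <- generate_nac_dataset(synth_config(n_molecules = 200, seed = 42))
ca <- confluence_analysis(d$table)
ca$scores$superdelegate
glance(ca$pca)
ca$mpc
head(tidy(ca$scores)[order(-tidy(ca$scores)$S_alpha), ], 3)
```

The superdelegate, the MPC eigenvalue and percent explained, and
$\Omega(\phi, \mathrm{MPC})$ printed here are computed from the generated
table at knit time; with the generator's default profile one of the
low-noise main-block methods leads and $\Omega(\phi, \mathrm{MPC})$ is within a few
parts in $10^4$ of 1, as expected for a confluent group.
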