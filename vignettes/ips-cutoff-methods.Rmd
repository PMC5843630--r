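---
title: "Isotropic periodic sum electrostatics under atom- and group-based cut-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotropic periodic sum electrostatics under atom- and group-based cut-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ipswater)
```

## The problem

Truncating the Coulomb interaction at a cut-off radius $r_c$ is the cheap
alternative to lattice-sum electrostatics, and it is the only practical
option for net-charge or free-boundary systems. A truncation method is
applied through one of two cut-off *schemes*: atom-based (a pair of atoms
interacts iff their distance is within $r_c$) or group-based (all atom
pairs of two charge groups interact iff the group reference points are
within $r_c$). Group-based truncation never cuts through a molecular
dipole, which is why simulation packages favour it for polar molecules —
but it also changes what happens at the cut-off boundary, and poorly
conditioned boundaries are known to produce severe artefacts in the
dipole–dipole structure of water.

The isotropic periodic sum (IPS) family replaces the discarded tail by the
analytic interaction of a pair with isotropically distributed periodic
images inside the local sphere, adding an image term to the bare Coulomb
pair function:

$$u(r) = \frac{1}{r} + \varphi(r; r_c), \qquad
\varphi(r; r_c) = \frac{1}{r_c}\sum_{k} c_k \left(\frac{r}{r_c}\right)^{2k}.$$

This package implements a minimal, fully self-contained rigid SPC/E water
MD engine around that family so the behaviour of each variant can be
compared under both cut-off schemes against a direct Ewald reference —
the role a fine-grid lattice sum plays at production scale.

## The IPS variants as boundary conditions

What distinguishes the family members is the set of derivative orders of
$u$ forced to vanish at $r = r_c$:

| method | vanishing orders at $r_c$ | extra condition |
|---|---|---|
| IPSn | 0, 1 | — |
| IPSp | 0–3 | (counter-charge boundary assumption) |
| LIPS-5th | 0–5 | — |
| LIPS-SW | 0–5 | $c_1 = \tfrac12$ (conducting reaction-field slope) |

`solve_ips_coefficients()` constructs $\varphi$ by solving this linear
system in the reduced variable $s = r/r_c$ with the lowest-degree even
polynomial basis consistent with the conditions. Three design points
deserve comment:

* **Why solve rather than transcribe?** Published closed forms of the
  image terms are scattered across the method literature in differing
  conventions. The boundary conditions, by contrast, are the *defining*
  property of each variant and fully determine the lowest-degree
  polynomial; `boundary_spec()` exposes the
  conditions so alternative coefficient sets can be dropped in and checked
  with `verify_boundary()` / `ips_derivatives()`.
* **IPSp.** The counter-charge assumption for polar systems is realized
  by its testable consequence — second and third derivatives vanish at
  the boundary — rather than by an explicit image-charge construction.
* **LIPS-SW.** Its defining text ("periodic reaction field") pins the
  quadratic term of the image polynomial to the conducting reaction-field
  value $c_1 = 1/2$ on top of the fifth-order boundary conditions; the
  basis grows to degree 12 to keep the system square. This reading is
  provisional: it produces a member of the LIPS family that is distinct
  from LIPS-5th, matches the reaction-field limiting behaviour at small
  $r$, and satisfies every stated boundary property.

The reduced coefficients are independent of $r_c$; dimensionally the image
term scales as $1/r_c$. Checking the boundary conditions numerically is
subtle: a $k$-th order central difference amplifies round-off like
$2^k\varepsilon/h^k$ while $u$ itself cancels catastrophically near $r_c$,
so order 5 cannot be verified to $10^{-6}$ relative by naive finite
differences in double precision. `verify_boundary()` therefore widens the
step with the order, Richardson-extrapolates, and reports an error
estimate alongside each value; the exact closed-form derivatives are
available through `ips_derivatives()`.

## Tables, the pseudo cut-off, and the static image energy

`write_table()` samples $u$ and plain-truncated $-r^{-6}$ / $r^{-12}$
kernels in the seven-column tabulated-interaction layout
(`r, f, -f', g, -g', h, -h'`), on a uniform grid from 0.002 nm at
0.0005 nm spacing by default. The engine interpolates with a cubic
Hermite built from the value *and* stored derivative columns, so forces
are the exact negative gradient of the interpolated energy, and every
interaction column is clamped to exactly zero beyond its cut-off.

That clamp is what makes the *pseudo cut-off radius* work: extend the
table with zeros on $(r_c, r_c^*]$ and build the group-based pair list at
$r_c^*$. Every atom pair within $r_c$ is then present (its group pair
cannot be farther than the atom distance plus twice the atom-to-centre
extent) and every extra pair contributes exactly zero, so group-based
truncation becomes numerically identical to atom-based truncation at
$r_c$ — the package asserts this bit-for-bit. The margin matters:
$r_c^* - r_c$ must exceed twice the largest atom-to-centre distance
(0.168 nm for SPC/E water); the desk defaults use 0.2 nm.

Two energy-accounting choices are explicit rather than implicit:

* **Static image energy.** The image term represents periodic images of
  *every* charge, including a charge's own images
  ($\tfrac12 q^2\varphi(0)$ with $\varphi(0) = c_0/r_c$) and the images
  of excluded intramolecular partners ($q_iq_j\varphi(r_{ij})$). For
  rigid water these are force-free constants, but they differ strongly
  between variants (at $r_c = 0.7$ nm: $-0.49$, $-2.18$, $-4.61$,
  $-0.31$ kJ/mol per molecule for IPSn, IPSp, LIPS-5th, LIPS-SW), so
  absolute energies are only comparable to a self-consistent Ewald
  reference when they are included. `run_simulation()` adds
  `ips_static_energy()` to its electrostatic energy trace;
  `nonbonded_energy_forces()` remains the pure pair sum.
* **LJ truncation.** Dispersion and repulsion are plainly truncated by
  default (the convention of the reproduced study, where the LJ cut-off
  is 1.2664 nm = 4.0 LJ length units and the truncation jump is
  $\sim 6\times10^{-4}$ kJ/mol). At desk-scale cut-offs the jump reaches
  $\sim 0.1$–$0.3$ kJ/mol per crossing and dominates microcanonical
  drift, so `write_table(lj_shift = TRUE)` offers a cut-and-shifted LJ
  used by the conservation checks.

## The engine

Velocity Verlet at 2 fs with SHAKE (relative tolerance $10^{-6}$) on the
three rigid distances of each water, the matching velocity correction
after the drift, and a RATTLE velocity stage after the second kick.
NVT runs wrap the step in symmetric half-updates of a single-chain
Nosé–Hoover thermostat with $Q = N_f k_B T\,\tau^2$, $\tau = 0.04$ ps,
updated every step; $N_f = 6N_{mol} - 3$ for rigid waters with the
centre-of-mass motion removed. The non-bonded pair list is rebuilt every
step (no buffer), pairs at exactly $r_c$ are included (closed ball), and
the group reference point is the geometric centre of the members.
Trajectories are deterministic given the velocity seed.

The Ewald reference is a direct summation (real + reciprocal + self +
intramolecular-exclusion corrections, tin-foil boundary); parameters are
chosen from a target tolerance with the real-space cut-off at half the
minimum box edge. At the system sizes this package targets the
$O(N^2)$-ish cost is unproblematic and there is no interpolation error to
reason about.

## The synthetic systems

`build_bulk()` places molecules on a jittered cubic lattice with random
orientations in a box sized exactly to the target density
($L = (n m_w/\rho)^{1/3}$; the density round-trip is exact to $10^{-6}$),
with the jitter capped so no two oxygens start closer than 0.25 nm;
`build_slab()` builds a liquid film of the same structure centred in an
elongated box. These are *starting structures*: the lattice melts during
equilibration. What the generator does **not** emulate is equilibrated
liquid structure — every production quantity in this package is measured
after an explicit NVT equilibration segment, and passing tests therefore
validate the machinery and the boundary treatment, not ns-scale
converged ensemble averages.

## Observables

* `self_diffusion()`: Einstein relation, $D = \lim_{t\to\infty}
  \langle|\mathbf r_i(t)-\mathbf r_i(0)|^2\rangle/6t$, on trajectories
  unwrapped by accumulating per-frame minimum-image displacements,
  multiple time origins (stride = fit window / 10), least-squares slope
  on a stated window, with a log-log exponent diagnostic that flags
  ballistic or sub-diffusive regimes.
* `rdf()`: $g(r) = \frac{V}{4\pi r^2\Delta r\,N(N-1)}
  \langle\sum_i n_i(r)\rangle$, O–O distances, bin centre convention.
* `kirkwood_gk()`: cumulative $G_k(r) = \frac1N\langle\sum_i
  \mathbf u_i\cdot\sum_{j, r_{ij}<r}\mathbf u_j\rangle$ with the self
  term included ($G_k(0^+) = 1$); molecular distances are measured O-to-O
  and dipoles point along the H–H bisector.
* `dipole_ordering_hoo()`: $h_{OO}(r) = 3g_{OO}(r)\langle\cos\theta(r)
  \rangle$ with the shell-wise per-molecule orientation mean; empty
  shells contribute zero.
* `density_profiles()` and `electrostatic_potential_profile()`: binned
  mass/charge densities along the surface normal and
  $\psi(z)-\psi(0) = -\frac{1}{\varepsilon_0}\int_0^z\!\!\int_0^{z'}
  \rho_c\,dz''dz'$ by cumulative trapezoids, anchored to zero in the
  vacuum (lowest-mass-density bin).

Defaults: $\Delta r = 0.002$ nm radially, $\Delta z = 0.02$ nm axially.
Every binned observable has an $O(N^2)$ brute-force oracle test at small
$N$, and the cumulative $G_k$ sign conventions are pinned by two-dipole
closed forms.

## Reduced-scale study conditions and what they can show

The full-scale conditions (6192 bulk waters, 10,976-molecule slab,
electrostatic cut-offs 1.2–2.8 nm, ns runs) are available as
`paper_profile()` but take orders of magnitude longer than a desk run.
The package's reference conditions are `desk_profile()`: 125 waters at
0.997 g/cm³ (box edge 1.554 nm), $r_c = 0.7$ nm, LJ cut-off 0.55 nm,
15 ps equilibration + 30 ps sampling under NVT at 298.15 K, block errors
from 5 blocks. Conservation checks use $r_c = 0.55$ nm with a 0.75 nm
pseudo cut-off and shifted LJ over 20 ps; drift is quantified as the
linear trend of total energy (the peak-to-peak excursion at 2 fs contains
the $O(dt^2)$ shadow-Hamiltonian oscillation, ~0.02 kJ/mol per molecule,
which is not drift).

At this scale the group-based IPSn artefact is unambiguous in the
structure and dynamics: the distance-dependent Kirkwood factor collapses
well below the Ewald curve with its largest deviation just inside $r_c$,
and the self-diffusion coefficient is overestimated several-fold, while
the LIPS variants track the Ewald reference. Two caveats are equally
clear. First, the *energy* signature of the IPSn artefact is smaller than
the block error of a 30 ps / 125-molecule run, so the sign of its offset
against Ewald is not resolved at desk scale — that comparison needs the
full-scale conditions. Second, $G_k(r)$ beyond $r_c$ (up to $L/2$) is
dominated by collective finite-size fluctuations in a 125-molecule box;
comparisons are therefore restricted to $r \le r_c$.

## Numerical choices and limitations

* Boundary-condition systems are solved by QR; underdetermined bases are
  rejected, inconsistent overdetermined ones report the conflicting
  orders.
* Table interpolation is cubic Hermite on (value, derivative) pairs;
  halving the default spacing changes interpolated energies by less than
  $10^{-6}$ relative.
* Pair lists come from a linked-cell sweep when the box holds at least
  three cells per edge and from the brute-force double loop otherwise;
  both paths return identical, lexicographically ordered lists.
* The engine is specialized to rigid 3-site waters plus single-atom LJ
  species; there are no bonded force fields, barostats or multiple
  time-stepping, and charge groups are molecules.
* LIPS-SW's functional form is this package's reading of "periodic
  reaction field" (see above) and should be reconciled against the
  published coefficients where exactness matters.
* The IPSm multipole extension and heterogeneous 3D-IPS variants are out
  of scope.
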