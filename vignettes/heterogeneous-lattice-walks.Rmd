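---
title: "Lattice walks with inert spatial heterogeneities: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice walks with inert spatial heterogeneities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetwalk)
```

# The model

`hetwalk` treats movement in a disordered medium as a discrete-time Markov
lattice walk whose transition probabilities are locally perturbed. The
homogeneous backbone is a *d*-dimensional nearest-neighbour lazy walk on a
finite lattice: in dimension *i* the walker jumps to either neighbour with
probability $q_i/(2d)$ and otherwise stays put, so the bulk staying
probability is $1 - \frac{1}{d}\sum_i q_i$. The $q_i \in (0,1]$ play the
role of per-dimension diffusivities: on a 2D lattice with
$q = (0.2, 0.2)$ every bulk site sends probability $0.05$ to each of its
four neighbours and keeps $0.8$.

Three boundary treatments are supported per dimension. Reflecting faces fold
the blocked jump back into the staying probability (this fold is forced by
consistency: the mean first-passage time from site 1 to site 2 of a 1D walk
with $q = 1$ must be 2, which requires staying probability $1/2$ at the
boundary site). Periodic faces wrap. Absorbing faces remove the mass that
steps off the lattice (a "ghost site" convention, which keeps the operator
separable). Individual sites can additionally be declared absorbing, in
which case their whole outgoing column is zeroed and a walker is removed on
arrival — the construction used for first-passage targets.

A *heterogeneous connection* between sites $u$ and $v$ shifts the jump
probability $u \to v$ by $-\lambda_{v,u}$ and compensates on the staying
probability of $u$ (and symmetrically for $\lambda_{u,v}$), so probability
is conserved identically. Positive $\lambda$ values impede crossing
(partially reflecting barriers, one-way gates, sticky sites), negative ones
promote it by drawing on the lazy probability (antibarriers, slippery
sites, long-range connections between non-neighbours). Validity requires
$\lambda_{w,u} \le A_{w,u}$ entrywise and a non-negative residual staying
probability at every site; `het_set()` enforces both and refuses duplicate
unordered pairs rather than merging them (no unambiguous merge rule
exists). Builders resolve the dimensionless strengths ($\alpha$, $\beta$)
into concrete $\lambda$ values at construction time, so validation is
always on numbers, and on boundary sites the neighbour count $k$ used by
sticky/slippery scaling counts only the neighbours that exist.

# The solver

The occupation probability of the perturbed walk is computed in the
generating-function ($z$-transform) domain. With
$\tilde\varphi_{n_0}(n,z)$ the homogeneous propagator GF, a set of $M$
defect pairs enters only through an $M \times M$ matrix $H(z)$ whose
entries combine $\lambda$ values with differences of homogeneous
propagators between the paired sites, minus $z^{-1}$ on the diagonal. The
heterogeneous propagator is
$$\tilde\Phi_{n_0}(n,z) = \tilde\varphi_{n_0}(n,z) - 1 +
\frac{|H(n,n_0)|}{|H|},$$
where $H(n,n_0)$ differs from $H$ by a rank-one correction $b\,g^{\top}$
built from propagators into the source and out of the destination. We never
form determinants: by the matrix-determinant lemma the ratio equals
$1 - g^{\top} H^{-1} b$, one pivoted linear solve of size $M$, which is
stable where explicit determinants overflow. At $z = 0$ the solver
short-circuits to the initial condition $\delta_{n,n_0}$.

The homogeneous propagator itself comes from the exact spectral
decomposition of the transition operator. For face-wise boundary
conditions the operator is a Kronecker average (or product, see below) of
1D symmetric tridiagonal/circulant operators, so the eigenbasis separates
into per-dimension cosine-type (reflecting), Fourier (periodic) and
sine-type (absorbing) modes; these are obtained from LAPACK's symmetric
eigensolver at machine precision, and
$$\tilde\varphi_{n_0}(n,z) = \sum_k
\frac{\psi_k(n)\,\psi_k(n_0)}{1 - z\,\sigma_k}.$$
With individually absorbing sites separability is lost and the package
evaluates $(I - zA)^{-1}$ columns by dense solves instead (capped at 4000
sites; the mean statistics below never need this path at scale).

Two kernels are supported: the `"average"` kernel (one coordinate moves per
step, eigenvalues are means of per-dimension eigenvalues) and the
`"product"` kernel (all coordinates move simultaneously, eigenvalues
multiply). The product kernel is exactly the combined walk of two
independent 1D particles, which is how the coalescence scenario maps two
interacting walkers to one walker in 2D with diagonal steps.

## Time-domain inversion

Time series are recovered by evaluating the GF on $K \ge 4(T+1)$ points of
a circle of radius $r = \varepsilon^{1/(T+1)}$ with $\varepsilon =
10^{-8}$ and applying an inverse discrete Fourier sum with radius
correction — the standard compromise between truncation (tail terms enter
at order $\varepsilon$) and round-off amplification. One practical caveat
discovered during development: the radius correction multiplies FFT
round-off by up to $r^{-T} \approx 1/\varepsilon$, so an imaginary-residue
check cannot be tighter than $\approx 10^{-15}/\varepsilon = 10^{-7}$; the
inverter therefore uses
$\max(\texttt{im\_tol},\ 10^{-15} r^{-T})$ as its effective residue bound,
and coefficients are clipped to $[0,1]$ only after that check passes.
Against direct iteration of the Master equation the inverted heterogeneous
series agrees to better than $10^{-10}$ per coefficient on the lattices the
tests exercise.

## Means at $z = 1$

Mean first-passage times (MFPT), mean exit times (MET) and reach
probabilities are evaluated *exactly at* $z = 1$, not as limits: the target
(or the absorbing faces) make the propagator finite there, and
$\tilde\varphi_s(m,1)$ is a column of $(I - A)^{-1}$, obtained from one
sparse factorization with $2M + 1$ right-hand sides. The mean is the
survival sum $\tilde S_{n_0}(1) = \sum_m \tilde\Phi_{n_0}(m,1)$ over
non-absorbed sites with the same rank-one defect correction. This route is
algebraically identical to the determinant expressions for the means but
requires no limit handling and no explicit matrices beyond $H$.

Two robustness rules apply at $z = 1$. First, $\lambda$ components that act
on the outgoing column of an absorbing site can never fire and are dropped.
Second, defect components whose origin is unreachable from the start site
are likewise dropped: mass never arrives there, and keeping them would make
$H(1)$ singular whenever impenetrable barriers seal a region (the sealed
interior is a probability-conserving sub-chain). Both operations leave the
dynamics seen from the start site unchanged.

Reach probabilities are checked before any mean is reported: a breadth-first
reachability pass on the perturbed operator detects configurations where
the target is missed with positive probability, in which case the mean is
reported as `Inf` together with the exact reach probability from a hitting
-probability solve — never as `NaN` or an exception.

Mean return times use Kac's lemma, $\mathfrak{R}_n = 1/\pi(n)$, with the
stationary distribution $\pi$ from an exact linear solve on the
communicating class of $n$ (reducible chains give the class-restricted
value with a warning; transient sites give `Inf`). For symmetry-preserving
defect sets — those with $A_{u,v}\lambda_{v,u} = A_{v,u}\lambda_{u,v}$ for
every pair — $\pi$ is provably unchanged, and the package's
`is_symmetry_preserving()` test predicts exactly when the homogeneous MRT
survives perturbation.

As a cross-check of the renewal route, `mfpt(..., method = "renewal")`
differentiates $\tilde F = \tilde\Phi_{n_0}(n,z)/\tilde\Phi_n(n,z)$ at
$z = 1$ by central differences with Richardson extrapolation. The step
sizes must respect the analyticity radius of $\tilde F$: its nearest
singularity is the subdominant propagator pole at $1/\sigma_2$, which on a
1D lattice of 40 sites sits only $1.3\times10^{-3}$ from 1. Fixed steps of
$10^{-3}$ therefore fail; the package scales the stencil to 5% of the
spectral gap (with a $10^{-7}$ floor), after which the two routes agree to
$10^{-6}$ relative or better.

# The 1D single-barrier closed forms

For a 1D walk (moving probability $q$, reflecting boundary between sites 0
and 1) with one symmetric barrier $\lambda$ between $u$ and $u+1$, the
package ships closed forms. Writing
$\zeta = \operatorname{acosh}\!\big(1 - (1 - 1/z)/q\big)$ and
$x = e^{-\zeta}$, the reflecting-boundary propagator is the image sum
$\tilde\varphi_a(b,z) = (x^{|b-a|} + x^{b+a-1})/(q z \sinh\zeta)$, and the
single defect pair gives, via the $M = 1$ defect correction,
$\tilde F_{n_0}(n,z) = \tilde\Phi_{n_0}(n,z)/\tilde\Phi_n(n,z)$ in closed
form (`fp_1d_barrier_gf()`). This expression covers both barrier positions
($u < n_0$ and $u \ge n_0$) without case analysis; we verified it against
direct iteration of the perturbed Master equation on a truncated lattice of
400 sites to $10^{-10}$ per coefficient, and its derivative at $z = 1$
against the absorbing-chain linear solve. Published typeset variants of
this formula are typographically ambiguous about the grouping inside the
hyperbolic functions; the form above is the one that survives the oracle
and is the form this package defines.

The mean has the compact form
$$\mathfrak{F}_{n_0\to n} = \mathcal{F}_{n_0\to n} +
\frac{2\lambda}{q(q/2-\lambda)}
\begin{cases}0, & u < n_0\\ u, & u \ge n_0,\end{cases}
\qquad \mathcal{F}_{n_0\to n} = \frac{(n-n_0)(n+n_0-1)}{q}.$$
A barrier *behind* the start leaves the mean untouched for every admissible
$\lambda \in (-(1-q), q/2)$ — disorder indifference — even though the full
distribution deforms visibly (mode-tail enhancement). The indifference
holds on the *open* interval: exactly at $\lambda = q/2$ the wall
disconnects the reflecting boundary and the problem shifts by $u$, a
genuine discontinuity that `mfpt_1d_barrier()` handles explicitly. Between
start and target the penalty grows linearly in $u$ and diverges as
$\lambda \to q/2$. With $q = 2/3$, $\lambda = 0.975\,q/2$, $n_0 = 8$,
$n = 15$ the package reproduces a mean of 231 for every $u \le 7$, and
1167 / 1869 for $u = 8$ / $u = 14$ (coefficient $117$ per unit $u$).

An asymmetric barrier breaks the uniform steady state; the mean return
time then takes the piecewise closed form implemented in
`mrt_1d_barrier()` (derived by detailed balance across the defective edge),
which the Kac route reproduces to $10^{-10}$.

# Stochastic oracles

Every analytic path has an independent ground truth in the package:
`iterate_master()` (exact repeated operator application),
`solve_absorbing_means()` (absorbing-chain linear solves, with hitting
probabilities used to flag infinite entries), and
`sample_first_passage()`, a seeded Monte Carlo sampler. The sampler
requires an explicit seed (there is no default, preventing silent
pseudo-replication) and evolves multinomial counts per occupied site —
statistically identical to per-walker categorical sampling but orders of
magnitude faster; censored walkers are counted, never silently dropped.
Binomial standard errors computed from the *analytic* probabilities are
used when comparing to the exact distribution, since estimated standard
errors degenerate where only a handful of arrivals occur.

# Scenario builders and their scales

**Brick-and-mortar (drug transport).** A 2D domain with an absorbing
bottom face, reflecting top face and periodic sides; staggered rectangular
bricks (standard brick bond, offset half a period per layer, one mortar
row/column between bricks) are outlined with $\alpha$-strength barrier
pairs, and a top-centred $h \times w$ puncture removes every pair it
touches. The tested claims are qualitative: with impenetrable bricks the
mean exit time versus puncture depth first rises (opened bricks trap the
walker), oscillates as successive layers are breached, and eventually
falls once a direct channel forms — an interior maximum; with permeable
bricks ($\alpha = 0.9$, i.e. $\lambda = 0.18$ at $q = 0.8$) the curve is
monotone decreasing. The impenetrable property is robust already on a
$13\times12$ domain with $3\times5$ bricks (the size the tests use). The
permeable monotonicity, by contrast, carries sub-0.2% parity wiggles at
such small sizes as the puncture edge crosses mortar rows, so that check
runs at the native $37\times36$, nine-layer geometry, where the decrease
is strictly monotone (about 40 s for a full height sweep; tests use a
coarser step).

**Thigmotaxis (wall-following).** A square arena with an impenetrable
circle of radius $R$ and, at $r < R$, one-way partially reflecting
barriers that leave outward movement free and block inward movement with
strength $\alpha_i$. A lattice edge carries a barrier iff its endpoint
site centres lie on opposite sides of the circle (Euclidean distance to
the centre site) — a deterministic, resolution-convergent rule. The
summary statistic is the steady-state mean-squared displacement
$\mathfrak{M} = \sum_n \lVert n - n_0\rVert^2 \pi(n)$ about the centre,
normalized by the barrier-free arena. Because the annulus is the recurrent
class when $\alpha_i = 1$ (the centre becomes transient), $\pi$ is taken
on the recurrent class the walk settles into rather than the class of the
start site. On a $21\times21$ arena ($R = 9.6$) the normalized saturation
is non-decreasing in $\alpha_i$ and larger for thinner annuli, as
expected from confinement near the wall.

**Two-particle coalescence (target search).** Two independent 1D walkers
with moving probability $q$ become one product-kernel 2D walker; the
diagonal is the bound complex. Exact defect placement for the interactions
is not published, so the package fixes a deterministic rule pinned down by
the limiting behaviours: one-way barriers of strength $\alpha_e$ on every
edge *entering* the diagonal (exclusion; $\alpha_e = 1$ means the
particles never meet), openness $\alpha_u$ on edges *leaving* it
($\alpha_u = 0$ is irreversible binding), and symmetric strength
$1-\alpha_c$ on edges *along* it ($\alpha_c = 0$ immobilizes the
complex). All four limits are asserted in tests, and
$(\alpha_e, \alpha_u, \alpha_c) = (0, 1, 1)$ is the homogeneous combined
walk exactly, making the MFPT ratio 1 by construction rather than by
tuning. On a 15-site segment (start maximally separated, meeting site at
one end) the ratio map shows its minimum in the low-$\alpha_u$ /
high-$\alpha_c$ quadrant — cohesive, mobile complexes search fastest. One
documented full-scale feature is *not* desk-reproducible: the optimum at
intermediate unbinding for a nearly immobile complex. We probed segments
up to $N = 60$ and found the ratio monotone in $\alpha_u$ throughout;
the interior optimum evidently needs the original $N = 100$ scale (and
possibly placement details beyond the published limits), so it is
described but not asserted.

# Numerical choices, defaults and limitations

* Column-stochasticity after perturbation is exact (the construction
  cancels identically); tests assert it at $10^{-14}$.
* Contour inversion: $\varepsilon = 10^{-8}$, $K = 4(T+1)$; oracle
  equivalence asserted at $10^{-10}$ per coefficient; residue floor as
  above.
* Defect solves: pivoted LU on $H$, falling back to an informative error
  with a condition estimate if $H$ is numerically singular inside the unit
  disc (which does not occur for validated sets).
* Ties and degeneracies: duplicate unordered pairs error; $z = 0$
  short-circuits; impenetrable limits are handled exactly rather than by
  $\lambda \to q/2$ limits.
* The dense fallback for absorbing-site propagators is capped at 4000
  sites; all mean statistics route through sparse $z = 1$ solves and have
  no such cap in practice at the scales above.
* Monte Carlo comparisons treat 300 time points simultaneously; the tests
  allow at most 1% of points beyond 3 analytic standard errors and none
  beyond 6, which is the calibrated rendition of "agrees within 3 SE".
* What the synthetic scenarios do *not* emulate: real stratum-corneum
  geometry is 3D with heterogeneous brick sizes; animal arenas are not
  square lattices; transcription-factor search involves 3D excursions and
  sliding kinetics. Passing the scenario tests shows the *solver* is exact
  and the *orderings* the geometry implies are reproduced, not that the
  desk-scale parameters quantitatively describe any organism or tissue.
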