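---
title: "Phragmocone mechanics: suture-driven septa under hydrostatic pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phragmocone mechanics: suture-driven septa under hydrostatic pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phragmoFEM)
```

## The question and the model system

The chambered shell (phragmocone) of ammonoid cephalopods is a gas-filled
buoyancy device loaded by a net external water pressure of order 1--3 MPa.
Its internal dividing walls (septa) meet the shell tube along suture lines
that became spectacularly folded over ammonoid evolution, and a
long-standing hypothesis reads that folding as a strengthening adaptation
for deeper water.  `phragmoFEM` implements a controlled, fully parametric
test of that idea: straight capped cylindrical shells carrying septa whose
only varied property is the geometry of their suture line, solved as
linear-elastic solids under uniform external pressure and compared through
stress statistics, line probes, displacements and strain energy.

The deliberate simplifications are part of the design: a straight cylinder
(no coiling, no whorl overlap, no siphuncle), isotropic material
(E = 70 GPa from nanoindentation of *Nautilus* shell, nu = 0.3), and purely
external pressure (chamber gas at about one atmosphere is ~0 relative).
This isolates the morphological variables -- suture complexity, septal
spacing, wall thickness -- from everything that covaries with them in real
shells.

## Geometry pipeline

**Suture curves.** Two families:

* `lobate_curve(n, amplitude)` -- a short cosine series in the arc
  position with exactly `n` primary lobes per period, bilaterally
  symmetric, lobes sharp and saddles broad (weights `c(1, 0.25, 0.05)` by
  default).  The four suite members use 3--6 lobes.
* `koch_curve(iterations, n_copies, amplitude)` -- the classic triadic
  Koch generator applied 1--3 times to each of four baseline copies
  (4^n segments per copy), smoothed by a periodic parametric spline.
  Smoothing happens in the generator's own aspect ratio before amplitude
  scaling; a spline fitted after squashing oscillates.

The axial amplitude of a suture is nowhere reported for the reference
suite, so it is a required parameter with the default 0.2 x cylinder
radius (1.822 mm at r = 9.11 mm) for both families, keeping flute aspect
ratios moderate and the two families comparable.  Curves wrap onto the
shell tube by `theta = 2*pi*x`; all vertices then sit on the cylinder to
1e-6 mm.

**The thin-Koch constraint.** `max_safe_offset()` finds, by bisection over
a brute-force segment-intersection test on the unrolled cylinder plane,
the largest half-thickness at which both normal-offset curves stay simple.
At the default amplitude the iteration-3 Koch suture admits only ~0.08 mm
of septum, which is why Koch septa are built at 0.04 mm while lobate septa
carry 0.4 mm -- the package reproduces that constraint rather than
assuming it.

**Minimum-curvature septa.** `min_curvature_surface()` triangulates a disc
(polar grid, radial rings graded geometrically toward the boundary,
angular counts halving toward the centre), pins the boundary ring to the
suture curve, and minimises the discrete thin-plate (bilaplacian) energy
`x' L M^-1 L x` with the cotangent Laplacian `L` and lumped vertex
areas `M`.  Position-only clamping is used (no boundary tangent
constraint).  The surface is initialised harmonically with flat-disc
weights and iterated on the intrinsic operator; because the bending
energy does not resist tangential vertex motion, an iterate can slide
interior vertices until triangles collapse, so any step that would
shrink a triangle below 5% of the initial minimum area -- or raise the
energy -- is rejected and terminates the iteration.  The in-plane
relaxation the early iterates perform is physically meaningful: it packs
vertices into the frilled boundary zone and is required to resolve the
corrugation stiffness of high-iteration Koch septa (a pure height-field
solve leaves them spuriously compliant).  The reported energy trace is
non-increasing; the default tolerance is a relative energy change below
1e-8 (at most 500 iterations).  There is no randomness anywhere in the pipeline.  For a
planar boundary the exact minimiser (a flat disc) is recovered to
solver precision, which the tests use as an oracle, and
`curvature_map()` (cotangent mean-curvature magnitude) reproduces 1/R on
spheres and 1/(2r) on cylinders to 2% on regular grids.

Boundary grading matters scientifically, not just numerically: the
fine-scale folds of a high-iteration suture decay within roughly one
fold wavelength of the boundary (harmonic decay), so a septum meshed with
~1 mm uniform rings simply does not contain iteration-3 geometry, and the
iteration comparison degenerates.  The first interior ring sits about one
boundary-arc inside the suture.

**Assembly.** `build_shell()` constructs the annular wall (structured
theta x z x radial grid), two hemispherical caps (the same disc mesh
mapped to hemispheres, eliminating open-edge boundary conditions), and the
septa, then `tet_mesh()` splits the prism blocks into conforming
tetrahedra using the min-index diagonal rule and optionally promotes to
10-node quadratic elements (the default, matching the reference
workflow).  Fusion is exact by construction: each septum's boundary rings
are node rings of the inner wall grid, so no boolean union or mesh repair
exists anywhere.  Septa attach at full thickness (two wall rings t apart);
the wall rows refine geometrically toward every suture ring.  Koch sutures
of iteration >= 2 overhang in arc position; the wall-conformal profile
collapses overhangs by a monotone projection (the standalone curve objects
retain true Koch geometry, including for the offset-safety scan).

Axial placement centres the septa on the cylinder midlength.  The
cylinder length is `(n_septa - 1) * spacing + 2 * end_margin`.  The end
margin defaults to 20 mm: the validation protocol below samples a band
midway between the outermost septum and the cap, and both the cap
junction and the septum each shed a bending boundary layer of extent
~3 sqrt(r t) (about 5--7 mm here); a 20 mm margin is the smallest round
value that leaves a clean membrane plateau between them.  With 10 mm
margins the measured "far-field" error triples for reasons that have
nothing to do with mesh quality.

## The elastic solve

Standard displacement FEM on linear or quadratic tetrahedra (Rcpp
kernels; 4-point Gauss for quadratic stiffness), mm--MPa--N units.
Pressure is a dead load along the inward facet normals; on straight-sided
6-node facets the consistent load lands entirely on midside nodes.  Rigid
modes are removed by a 3-2-1 scheme on three well-separated nodes chosen
for conditioning of the rigid-mode restriction; for the closed,
self-equilibrated pressure load the constraint reactions vanish (checked
to 1e-6 of the total traction).  The sparse SPD system is factorised by
supernodal Cholesky (CHOLMOD through `Matrix`).  Because everything is
linear, one reference solve per geometry is rescaled exactly to the other
pressures of the series (`scale_solution()`); strain energy is
`0.5 * f'u` and scales with P^2.

Nodal stresses are recovered by volume-weighted averaging of each
adjacent element's stress field *evaluated at the node* (extrapolated
nodal stress, as FE post-processors report it).  Surface sampling
therefore reads surface-fibre values rather than mid-thickness values --
the distinction matters: through one 0.5 mm quadratic element the hoop
stress varies by ~5%.

## Validation protocol and its conventions

The thin-wall estimate `sigma_h = P*r/t` is evaluated with the nominal
(inner) radius, 36.44 MPa for the 0.5 mm wall and 182.2 MPa for the
0.1 mm wall at 2 MPa.  The measured error of the band-mean sampled hoop
stress against it lands at ~2.6% for the 0.5 mm models: the Lame solution
itself puts the outer-surface hoop at 37.46 MPa, i.e. a ~2.8% offset is
*built into the nominal-radius convention* and the observed 0.1--4% range
should be read with that in mind.  For the 0.1 mm wall the convention
costs only ~0.5%, and a refined septa-free cylinder drives the measured
error below 1% -- the mesh-convergence check.  Oracles for the solver
itself are closed-form: hydrostatic cube (-P I, exact for linear
elements), Lame thick-walled cylinder in plane strain (2%), thin
spherical shell membrane stress P r/(2t) (3%, compared against the
tangential, i.e. most negative principal, component).

## Reported quantities

* `to_cylindrical()` / `max_principal()`: cylindrical components and the
  largest principal stress (tension positive), vectorised closed-form
  eigenvalues.
* `line_probe()`: axial probe along the outer surface, default angular
  position through a primary lobe axis.
* `region_stats()`: mean +/- sd and peak of nodal maximum principal
  stress.  The shell-wall statistic is the plain mean over
  external-surface nodes within one spacing of the middle septum.  The
  septum statistic samples the *maximum-contour zone*: the top decile of
  maximum principal stress over the middle septum's nodes, the
  deterministic counterpart of reading values off the peak stress
  contours; a plain septal average is dominated by the flat, lightly
  loaded centre.
* `septum_centre_displacement()`: displacement magnitude at the septal
  disc centre, reported in micrometres.
* `depth_equivalent()`: OLS trend lines (intercept free) of mean
  shell-wall max-principal stress against pressure for two models; the
  pressure at which model B reaches model A's trend value at the
  reference pressure, converted to depth by `dP/(rho g)` with
  rho = 1025 kg/m^3, g = 9.81 m/s^2 (~99.5 m per MPa).  Applied to the
  published iteration means this reproduces the printed equivalent
  pressures of ~2.25 and ~2.38 MPa (25 and 38 m).

## Resolution tiers and problem sizes

The `coarse` tier is the working resolution used by the tests and the
analysis scripts: lobate models run 96 circumferential columns and
~39k quadratic tets (~230k dof), Koch models 160 columns and ~57k tets
(~330k dof); one model builds in ~1 s and solves in 20--60 s on a single
core, peaking at ~3 GB during factorisation (which is why the suite
driver isolates each model in its own subprocess).  The `fine` tier
doubles resolution for convergence studies.  160 columns is the floor
for the Koch family: at 144 the iteration-3 suture aliases and the
septal stress trend inverts.
Mesh sizes are the package's own accuracy choices: the validation band
error and the flat-disc/Lame/sphere oracles are the evidence that the
coarse tier is adequate for the quantities compared, while fine-scale
frill stresses remain resolution-limited (see limitations).

## What the comparisons show (and do not)

The synthetic suite emulates the study conditions exactly where they are
stated -- radii, wall thicknesses, spacings and septa counts, septal
thicknesses, pressures, material constants -- and fills the gaps
(amplitude, lengths, lobate profile shape) with the fixed defaults above.
It does not emulate real shells: no coiling, no material layering, no
growth variation, and sutures are idealised parametric curves.  Passing
tests therefore demonstrate that the *modelling system* reproduces the
reference mechanics on its own terms, not that real ammonoids behaved
accordingly.

Directional results at the coarse tier: wall thickness dominates (the
0.5 to 0.1 mm change raises probe tangential stress by ~530--650%,
versus the 400% membrane theory and a ~15% lobate complexity effect);
septal maximum-contour stress rises monotonically with Koch iteration
(14.8, 26.3, 32.3 MPa at 2 MPa, tracking the published 10.3, 20.3,
29.5); the septum centre deflects far less at iteration 3 than at
iteration 1 (80 vs 136 um here; 30 vs 77 um in the reference).  Two
reference directions are *not* reproduced at this tier and their
acceptance tests are left failing rather than re-defined: the slight
iteration-wise relief of external shell-wall stress (our external band
mean is flat to ~1%: the relief is carried by fine suture flutes that a
160-column circumference only partially resolves), and the reported
fall of strain energy with increasing septal spacing (we measure the
opposite, 16.4 to 18.2 mJ from 5 to 20 mm -- under a pure pressure load
the energy is 0.5 P dV, and closely packed septa reduce the enclosed
volume change, which is exactly the displacement-limiting effect the
same reference paragraph describes).

## Numerical choices and edge cases

* Cotangent weights clamped at 1e6; degenerate triangles are an error.
* The minimum-curvature iteration accepts only energy-decreasing steps;
  a step that would increase energy terminates the iteration (converged
  by monotonicity).
* Prism-to-tet splitting uses global min-index diagonals, so meshing is
  order-independent and bit-deterministic; repeated builds are
  `identical()`.
* Tetrahedra are re-oriented to positive volume; any residual degenerate
  element aborts meshing.
* `n_septa = 0` builds the capped hollow cylinder used for validation.
* Pressure 0 is legal and yields the zero solution.

## Known limitations

* Quadratic tetrahedra with straight edges under-resolve plate bending in
  very thin members at high aspect ratio; Koch septa (0.04 mm) deflect
  more than the reference values, and absolute septal stresses at high
  iterations are resolution-limited on a single-core budget.
* The wall-conformal height profile collapses Koch overhangs; curvature
  statistics of the standalone surfaces retain them.
* No failure criterion, no buckling, no geometric nonlinearity, no
  anisotropy -- matching the scope of the linear comparisons.
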