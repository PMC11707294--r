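---
title: "Flattening curved membranes in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening curved membranes in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memflat)
```

## The problem

Membrane proteins in cryo-electron tomograms sit on surfaces that curve
through the volume, so any single X--Y slice cuts the membrane at an
arbitrary angle: proteins appear at unpredictable orientations and depths,
which makes visual inspection, picking, and orientation assignment slow and
error-prone. `memflat` resamples the neighborhood of one membrane into a
*flattened tomogram*: a volume whose central slice is the membrane itself
and whose w-axis is the local membrane normal everywhere. In that volume a
membrane protein always sits upright at a predictable slice, the normal
supplies two of its three Euler angles for subtomogram averaging, and the
remaining in-plane angle can be estimated from 2D projections.

## Coordinate systems and the model

Three Cartesian systems are used. Raw voxel coordinates $(X,Y,Z)$ index the
tomogram (0-based; the center of voxel $(0,0,0)$ is position $(0,0,0)$).
A rigid transform $(X,Y,Z)^T = \mathbf{R}\,(x,y,z)^T + \mathbf{t}$ defines a
local frame in which the membrane is a single-valued height surface
$z = f(x,y)$. Flattened coordinates $(u,v,w)$ index the output volume.

The pipeline is:

1. **Starting points.** From a binary membrane mask, a single-voxel
   boundary is extracted (6-connected erosion, or per-slice Canny edges).
   From each user seed the boundary is traced monotonically, first in the
   seed's $x$--$z$ plane (one step in $Z$ per move, lateral window of
   $\pm 2$ voxels), then from every primary point in its $x$--$y$ plane.
   Monotone stepping cannot double back, so a folded membrane (e.g. the
   far side of a vesicle) terminates the trace instead of corrupting the
   point set. A $k$-NN statistical filter (defaults $k = 50$, threshold
   mean $+ 2$ SD of the mean neighbor distances) removes stragglers.
2. **Frame.** The local $z$-axis is the normal of the best-fit plane
   (total least squares) or, equivalently for thin sheets, the
   smallest-variance principal direction ("maximum projected area"). The
   sign is fixed toward raw $+Z$; $\mathbf{t}$ is the centroid.
3. **Height surface.** Either a bivariate polynomial
   $f(x,y) = \sum_{m+n \le N} a_{mn} x^m y^n$ (ordinary least squares), or
   a thin-plate spline with kernel $r^2 \log r$, affine part, and diagonal
   smoothing $\lambda$. The TPS is fit to grid-downsampled control points
   (one cell centroid per `downsample_spacing`, default 12 voxels, the
   spacing practitioners use at this voxel size); control points whose
   residual exceeds 3 residual SDs are dropped once and the system re-solved.
4. **Intermediate cylinder.** Projecting the surface straight down the
   $z$-axis would stretch steep regions. Instead the surface is projected
   onto a best-fit *cylinder* $z = h(y) = \sum_n a_n y^n$ — fit jointly
   with the frame rotation by nonlinear least squares — and unrolled:
   $u = x$ and $v(y) = \int_{y_{\min}}^{y} \sqrt{1 + h'(t)^2}\,dt$, so unit
   steps in $v$ are unit arc-length steps on the cylinder. Closed membranes
   (vesicle cross-sections) use an elliptic cylinder instead: the axis,
   center, semi-axes and orientation are fit from the points, and $v$ is
   circumferential arc length.
5. **Flatmap and rendering.** The surface sampled on the integer $(u,v)$
   grid gives $S(u,v) = (X,Y,Z)$; unit normals $N(u,v)$ come from the cross
   product of central differences of $S$ (one-sided at the rim). Every
   flattened voxel maps to $S(u,v) + (w - w_c)\,N(u,v)$ with
   $|w - w_c| \le w_t$ and is filled by trilinear interpolation of the raw
   tomogram; the slab has $2 w_t + 1$ slices. In this package's arrays $w$
   is 0-based with $w_c = w_t$ (the 1-based description would be
   $w_c = w_t + 1$).
6. **Distortion.** For any slice, the tangents $r_u, r_v$ of the mapped
   surface give the first fundamental form $E = r_u \cdot r_u$,
   $F = r_u\cdot r_v$, $G = r_v\cdot r_v$; the singular values
   $\sigma_{1,2}$ (square roots of the eigenvalues of
   $[[E,F],[F,G]]$) are the semi-axes of the ellipse a unit circle maps to.
   Area distortion is $\sigma_1\sigma_2$, reported reciprocally (always
   $\ge 1$) with an expansion/contraction flag; shape distortion is
   $\sigma_1/\sigma_2$. The mesh-parameterization energy
   $\sigma_1^2+\sigma_2^2+\sigma_1^{-2}+\sigma_2^{-2}$ (minimum 4 at an
   isometry) is available as a diagnostic.
7. **Particles.** Picks made in flattened space are de-duplicated greedily
   by score with a minimum spacing, mapped back to raw coordinates, and
   given the local normal. A labeled in-plane direction (or an in-plane
   angle from 2D classification) completes the orientation: the direction's
   component perpendicular to the normal becomes the local $x$-axis,
   $y = n \times x$, and the columns $(v_x, v_y, n)$ form the rotation
   matrix, exported as ZYZ-intrinsic Euler angles (STAR rot/tilt/psi; the
   third matrix column depends only on rot and tilt, so the normal pins
   those two). Projections along the normal (default $70\times70$ px,
   depth 7) and matching 2D missing-wedge weights (central slices of a
   simplified 3D weight built from the tilt list, with an optional 1D CTF
   factor) feed external 2D classification.

### UV-mesh pathway

Surfaces too complex for a height function can be supplied as a triangle
mesh whose vertices carry texture coordinates $(u,v)$ from an external
parameterizer. The three coordinate functions $X(u,v), Y(u,v), Z(u,v)$ are
fit by TPS over the texture coordinates (interpolating, $\lambda = 0$, since
mesh vertices are trusted; dense meshes are grid-downsampled to at most 700
control points) and the rest of the pipeline is unchanged. Texture
coordinates are expected in voxel units of arc; `uv_scale` rescales
normalized parameterizations. Note that $(u,v)$ parameterizations are only
defined up to an in-plane isometry, so two pathways for the same membrane
agree after aligning a translation and a possible axis reversal.

## What the phantom generator emulates — and what it does not

All tests and the acceptance script run on synthetic phantoms built by
`make_phantom()`: an analytic surface (plane, polynomial or sinusoid sheet,
circular or elliptic cylinder, sphere cap) rendered as a dark bilayer (two
Gaussian leaflets 5 voxels apart, cryoET negative contrast), optional
anisotropic dark blobs planted at a fixed offset along the true normal with
known in-plane angles (the long axis encodes the angle), optional Gaussian
noise, and an optional Fourier-space missing-wedge filter. Ground truth
(surface points, particle positions, normals, angles) is exact, which is
what makes sub-voxel error measurement possible.

The phantoms deliberately do **not** reproduce segmentation errors, crowded
or double membranes, per-tilt CTF and dose effects, or reconstruction
artifacts beyond the wedge filter. Passing tests therefore demonstrate the
geometric and numerical correctness of the method, not robustness to
segmentation failure — on real data the quality of the membrane mask and of
the seed placement remains the user's responsibility.

Default phantom conditions used by the test-suite study cases: cylinder
radius 40--48 voxels with a 100--120 degree patch, sphere radius 36 with a
65 degree cap, bilayer separation 5 and leaflet sigma 1.2 voxels, 50
particles at 8 voxels offset with blob sigmas (3, 1.5, 1.5) and spacing 12 —
sizes representative of 3-fold binned tomograms of thylakoid-like membranes.

## Numerical choices

* **Arc length** uses adaptive quadrature (`integrate`, tolerance 1e-10)
  and bracketed root finding for the inverse, rather than a precomputed
  table, so $y(v(y)) = y$ holds to ~1e-8.
* **Normals from the sampled grid.** Normals are computed from central
  differences of $S(u,v)$, not from the analytic surface gradient. The two
  agree to well under a degree on smooth fits; the grid route is what the
  rendered volume actually uses, so distortion measured from it is the
  distortion of the produced volume. The outermost grid nodes use one-sided
  differences and are flagged; for off-central slices the flag widens to a
  two-node band because neighboring nodes inherit the one-sided normals.
* **Interpolation between grid nodes** (needed by the coordinate
  converters) is bilinear in $S$ and $N$ with re-normalization of $N$; the
  unit-length contract is kept at the cost of exact linearity between
  nodes.
* **Inverse mapping** `raw_to_flat()` seeds at the nearest grid node and
  runs a damped 2D Gauss–Newton on the tangential residual; success
  requires a residual under 0.5 voxel and $|w - w_c| \le w_t + 0.5$.
  The fibration along normals is locally unambiguous only within the slab;
  points near a center of curvature would be rejected by the residual test.
* **Cylinder fit identifiability.** The joint frame/polynomial fit uses
  variable projection (the polynomial is solved linearly inside each
  residual evaluation), searching only over three rotation angles, which
  converges in a handful of iterations from the PCA frame. The bend
  direction defaults to the in-plane direction of largest curvature of a
  quadratic pre-fit and can be forced with `bend_angle`.
* **Elliptic cylinder axis.** The axis is chosen among the three principal
  directions of the point cloud as the one whose orthogonal projection is
  best explained by a fitted ellipse (smallest radial residual); the naive
  largest-variance rule fails when the cross-section outsizes the cylinder
  length. Angular coverage is assessed around the fitted center, and
  under-coverage (< 180 degrees) produces a warning recommending the open
  pathway.
* **Degenerate inputs.** Collinear points, rank-deficient polynomial
  designs, fewer than 4 TPS control points, directions parallel to the
  normal, even projection depths, and non-ellipse conic fits all raise
  informative errors; an all-empty post-processed mask returns an empty
  mask with a warning (a legitimate outcome of a high threshold).

## Design decisions that were genuinely open

* The paper's workflow delegates 3DCTF generation to external software.
  The built-in `build_3dctf()` is a deliberately simple per-tomogram model:
  the maximum over tilts of a linear slab kernel of half-width one Fourier
  voxel (max, not sum, keeping weights in $[-1,1]$), optionally multiplied
  by a 1D CTF assigned by the nearest tilt. It reproduces the geometry of
  the missing wedge exactly — which is what the 2D weighting needs — but
  not per-particle dose or defocus-gradient weighting.
* The in-plane basis attached to a projection direction
  ($e_1 = \widehat{d \times \hat z}$, $e_2 = d \times e_1$, falling back to
  $e_1 = \hat x$ near the pole) is shared between projections and 2D
  weights so in-plane angles are interpretable across both. It is
  discontinuous for directions near $\hat z$, as every such convention must
  be; angle comparisons near the pole should therefore be made between 3D
  direction vectors, which is what the end-to-end tests do.
* Duplicate removal measures distance in 3D flattened space by default
  (an option restricts it to $(u,v)$): picks of one particle on adjacent
  slices are the duplicates the step exists to remove, and both metrics are
  exposed because the choice is not documented in the method's description.
* For the end-to-end validation, external 2D classification is replaced by
  exhaustive in-plane rotational matching of each particle projection
  against the known blob template, over 1-degree steps and $\pm 2$ pixel
  shifts — the same information 2D classification supplies, without a
  neural network or classifier in the loop.

## Validation summary

The test-suite measures, among others: exactness of the plane identity
(flattening a flat membrane reproduces the raw crop bit-for-bit on the
aligned grid); distortion-freeness of the cylinder unrolling (area and
shape distortion 1 within 1% on the central slice, $(r+d)/r$ on parallel
slices within 2%); the analytic $1/\cos\varphi$ law for a sphere unrolled
onto its tangent cylinder, measured along the profile transverse to the
tangent circle where the law is exact ($\varphi \le 45^\circ$, within 3%);
sub-voxel round-trip of the coordinate maps; parameter recovery of
polynomial and TPS fits; equality of extraction steps with brute-force
oracles; machine-precision orientation algebra; the analytic support of the
missing-wedge weights; consistency of the mesh and direct pathways within
0.5 voxel; and recovery of 50 planted particles on a curved membrane within
1 voxel and ~1.5 degrees median in-plane error. `scripts/acceptance.R`
recomputes all of these from scratch and writes them as JSON.

Problem sizes in the suite (96–160 voxel phantoms, 1000-point round trips,
10^4-rotation property sweeps) were chosen so the whole suite runs in a few
minutes on one CPU while keeping every measurement in its asymptotic
regime.

## Known limitations

* One membrane per run: multi-sheet or self-intersecting surfaces must be
  handled by seeding each sheet separately or via the mesh pathway.
* The height-surface pathway cannot represent overhangs in the local
  frame; strongly curved closed membranes should use the elliptic or mesh
  pathways.
* Distortion is quantified, not minimized; the mesh parameterization
  itself comes from external tools.
* The inverse map is local: points outside the slab, or in regions where
  normals cross, are reported unmappable rather than guessed.
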