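# memflat

Membrane flattening and membrane-particle geometry for cryo-electron
tomography, in R.

Membrane proteins in a tomogram sit on curved surfaces, so ordinary X–Y
slices cut the membrane at arbitrary angles: proteins appear tilted, at
unpredictable depths, and with no usable orientation prior. `memflat`
resamples the neighborhood of one membrane into a **flattened tomogram**
whose central slice *is* the membrane and whose w-axis is the local surface
normal everywhere. That makes membrane proteins easy to see and pick, gives
every pick a normal (two of its three Euler angles), and turns the
remaining in-plane angle into a 2D problem.

For whom: cryoET practitioners doing visualization, particle picking, and
subtomogram averaging (STA) of membrane-associated complexes, and method
developers who need a scriptable, fully testable flattening pipeline with
exact synthetic ground truth.

## The model in brief

A rigid frame `(X,Y,Z)ᵀ = R (x,y,z)ᵀ + t` is chosen so the membrane is a
height surface `z = f(x,y)` (bivariate polynomial, or thin-plate spline
with kernel `r² log r` and smoothing λ). The surface is projected onto a
best-fit cylinder `z = h(y) = Σ aₙ yⁿ` (frame and polynomial optimized
jointly) and unrolled with equal arc-length sampling,

    u = x ,   v(y) = ∫ √(1 + h′(t)²) dt ,

so the central slice is distortion-free wherever the membrane is truly
cylindrical. Each flattened voxel `(u,v,w)` samples the raw tomogram at
`S(u,v) + (w − w_c)·N(u,v)` by trilinear interpolation (slab thickness
`2·w_t + 1`). Local distortion comes from the first fundamental form
`E = r_u·r_u, F = r_u·r_v, G = r_v·r_v`: the singular values σ₁ ≥ σ₂ of the
map give area distortion σ₁σ₂ (reciprocal taken when < 1, flagged
contraction) and shape distortion σ₁/σ₂. Closed membranes use an elliptic
cylinder; arbitrary surfaces can enter as UV-parameterized triangle meshes
(X, Y, Z each fit by TPS over the texture coordinates). Particle picks gain
full orientations from the normal `n` and an in-plane direction `vx`: the
rotation matrix has columns `(vx⊥, n × vx⊥, n)` and is exported as
ZYZ-intrinsic Euler angles (STAR `rlnAngleRot/Tilt/Psi`). Missing-wedge
weights for 2D classification are central slices of a 3D Fourier-space
wedge weight, taken perpendicular to each particle's projection direction.

## Worked example

Flatten a synthetic cylindrical membrane (radius 48 voxels, 50 planted
particles) starting from nothing but its mask and one seed point:

```r
library(memflat)

ph <- make_phantom("circular_cylinder", dims = c(128, 160, 112), radius = 48,
                   center = c(79.5, 24), angular_range = c(30, 150),
                   n_particles = 50, particle_offset = 8, seed = 7)

bound <- extract_boundary(ph$mask, "erosion")
pts <- extend_from_seed(bound, seed_point(c(64, 79, 75), "Z"),
                        max_extent_primary = 300, max_extent_secondary = 300)
pts <- remove_outliers(pts, knn = 50, nsd = 2)
#> <point_set 'starting_points'> 10900 points

fl <- flatten_tomogram(ph$tomo, pts, mode = "cylinder", surface_kind = "tps",
                       spacing = 6, cyl_degree = 6, wt = 18)
fl$flat
#> <voxel_volume> 127 x 100 x 37, voxel 1 A, range [-1.893, -7.084e-54]
fl$flatmap
#> <flatmap> 127 x 100 grid, slab thickness 37 (w_c = 18, 0-based)

distortion_map(fl$flatmap)
#> <distortion_map> slice 18: area distortion median 1.005 (max 1.145),
#>                  shape median 1.005 (max 1.175)
```

The flattened volume is 127 × 100 in (u, v) — the membrane patch's
footprint in surface coordinates — and 37 slices thick (w_t = 18). Median
area distortion 1.005 on the central slice means the unrolling is within
0.5% of an isometry over the fitted patch (the maximum sits at the patch
rim, where the surface fit is supported on one side only). Picks made in
the flattened volume convert back to raw coordinates with normals and
Euler angles:

```r
picks <- data.frame(u = c(30, 60), v = c(20, 50), w = c(26, 26),
                    score = c(0.9, 0.8))
geo <- attach_geometry(dedup_picks(picks, min_spacing = 6), fl$flatmap)
ang <- t(sapply(seq_len(nrow(geo)), function(i)
  matrix_to_euler(orientation_matrix(c(geo$nx[i], geo$ny[i], geo$nz[i]),
                                     c(1, 0, 0)))))
geo$rot <- ang[, 1]; geo$tilt <- ang[, 2]; geo$psi <- ang[, 3]
geo[, c("u", "v", "w", "X", "Y", "Z", "rot", "tilt", "psi")]
#>    u  v  w    X     Y     Z    rot   tilt    psi
#> 1 30 20 26 30.5 46.86 73.37 -90.01 33.742  90.01
#> 2 60 50 26 60.5 79.72 83.07  90.00  0.188 -90.00
```

Both picks were placed 8 slices above the central slice (w = 26), so their
raw positions sit 8 voxels outside the membrane along the local normal;
`tilt` is the angle between that normal and the raw Z axis — 33.7° down the
cylinder flank, 0.2° at the apex. `write_star(geo, "particles.star")`
exports STA-ready metadata (0-based coordinates; 1-based consumers shift by
one).

See the vignette (`vignettes/membrane-flattening.Rmd`) for the full model,
parameter guidance, and numerical details.

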