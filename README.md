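# voxelkit

Unified, extensible access to large chunked volumetric neuroimagery from R.

Connectomics and other volumetric-imaging fields store petavoxel-scale 3D
image and segmentation data in a zoo of backends — in-memory arrays, chunked
files on disk, HTTP cutout services backed by cloud stores. Each backend has
its own dialect, so analysis code written against one store rarely ports to
another. `voxelkit` standardizes *in abstraction* rather than in format: it
defines three trait interfaces and implements them over interchangeable
backends, so the same analysis runs against any of them by changing one line.

- **Remotes** are data stores. Every remote supports at least volumetric
  reads; it may declare `write`, `create`, `list`, or `mesh_server_side`
  capabilities. Bundled: `memory_remote()`, `file_chunk_remote()` (a
  documented zarr-like chunk-file dialect), `http_remote()` plus a bundled
  reference server (`serve_reference()`) speaking a BossDB-flavored cutout
  REST dialect, and `caching_relay()` — a daisy-chainable LRU chunk cache
  that itself serves the same dialect.
- **Resources** address data inside a remote: hierarchical
  `bosslike://collection/experiment/channel` triples or flat
  `instance://name` data instances, each carrying a dtype (`uint8`/`uint16`
  images, `uint64` annotation labels) and a coordinate frame with physical
  voxel sizes.
- **Services** are computations over remote data that run server-side when a
  remote offers the capability and fall back to a local surrogate otherwise.
  The bundled mesh service (`mesh_for_id()`) extracts per-label isosurfaces
  with marching cubes and writes Wavefront OBJ or Neuroglancer legacy
  precomputed mesh fragments.

## The core machinery

A cutout request is a half-open box `[x0,x1) × [y0,y1) × [z0,z1)` at a
resolution level. Chunked stores hold volumes as fixed-shape cuboids
(default 512 × 512 × 16), so `decompose()` splits a request into
chunk-aligned blocks, remotes fetch blocks serially or in parallel, and
`stitch()` reassembles the dense array. Requests aligned to chunk
boundaries avoid downloading the cuboid periphery;
`periphery_fraction()` quantifies the overhead of unaligned requests as
(downloaded − requested) / downloaded voxels.

The mesher binarizes one label, contours at iso-level 0.5 with linear
interpolation on a generated 256-case cube table (derived from a
translation-consistent tetrahedral decomposition, so surfaces are watertight
and consistently oriented by construction), welds shared vertices exactly,
and reports `mesh_stats()`: V, E, F, Euler characteristic χ = V − E + F,
watertightness, and enclosed volume via the signed tetrahedron sum
|Σ v₁·(v₂×v₃)|/6.

## Worked example

```r
library(voxelkit)

# a chunked on-disk store holding a synthetic segmentation volume
store <- file_chunk_remote(tempfile("demo"), chunks = chunk_shape(32, 32, 8))
frame <- coordinate_frame(c(64, 64, 32), voxel_size = c(4, 4, 40))  # nm
seg   <- channel_resource("demo", "worm", "seg", "annotation", frame = frame)
create_resource(store, seg)

ball <- make_ball_volume(c(31, 31, 31), radius = 10)
post_cutout(store, cutout_request(seg, c(10, 41), c(10, 41), c(0, 31)),
            as.array(ball))

mesh <- mesh_for_id(store, seg, label = 1,
                    box = cutout_request(seg, c(0, 64), c(0, 64), c(0, 32)))
mesh_stats(mesh)
#> <vk_mesh_stats> V=5666 E=16992 F=11328 (chi=2), watertight=TRUE, volume=2.66016e+06
write_obj(mesh, "ball.obj")
```

The mesh is watertight with Euler characteristic 2 (a topological sphere).
Its enclosed volume, 2.660 × 10⁶ nm³, is within 1% of the analytic value:
a radius-10-voxel ball occupies 4/3·π·10³ ≈ 4188.8 voxels, and each
anisotropic voxel is 4 × 4 × 40 = 640 nm³, giving 2.681 × 10⁶ nm³.

A caching relay in front of any remote answers repeated requests from its
LRU chunk cache with zero upstream traffic:

```r
relay <- caching_relay(store, capacity_bytes = 64 * 1024^2)
box <- cutout_request(seg, c(0, 64), c(0, 64), c(0, 32))
invisible(get_cutout(relay, box))   # cold: misses fetch upstream
invisible(get_cutout(relay, box))   # warm: served entirely from cache
relay_stats(relay)[c("hits", "misses", "upstream_fetches")]
#> $hits    [1] 16
#> $misses  [1] 16
#> $upstream_fetches [1] 16
```

A command-line interface wraps the same functions
(`inst/cli/vk.R`; subcommands `cutout`, `upload`, `mesh`, `transfer`,
`fixture`, `serve`, `relay`, `resources`).

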