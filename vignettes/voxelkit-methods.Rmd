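---
title: "voxelkit: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxelkit: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelkit)
```

`voxelkit` provides uniform access to large 3D image and segmentation
volumes across interchangeable storage backends, plus the computations a
connectomics workflow hangs off that access: chunk-aligned cutouts, local
marching-cubes meshing, a composable caching relay, and remote-to-remote
transfer. This vignette records the models the package implements, the
conventions it fixes, and the reasoning behind the choices that were
genuinely open.

## The trait model

Three interfaces organize everything:

* **Remote** — a volumetric data store. The minimum contract is cutout
  *reads*; a remote may further declare `write`, `create`, `list`, and
  `mesh_server_side` capabilities. `memory_remote()`, `file_chunk_remote()`,
  `http_remote()` and `caching_relay()` all implement the same S3 generics
  (`get_cutout()`, `post_cutout()`, `create_resource()`, `list_resources()`,
  `get_metadata()`), so they are drop-in replacements for one another.
* **Resource** — an addressable unit of data: either the hierarchical
  collection/experiment/channel triple used by cloud-scale stores, or a flat
  data-instance name. Channels and instances carry a channel kind
  (image/annotation), a dtype, and a coordinate frame.
* **Service** — a computation over remote data. A service declares the
  capabilities it requires (`service_contract()`), and `capability_check()`
  decides whether a given remote can run it. The mesh service dispatches
  server-side when a remote declares `mesh_server_side` and otherwise runs
  its local surrogate, so the caller's code is identical either way. The
  operational meaning of the trait model — identical voxels in, identical
  service output out, regardless of backend — is asserted directly by
  `check_remote_equivalence()` and by the suite's cross-remote mesh tests.

## Coordinates, dtypes, and wire formats

Conventions fixed once, used everywhere:

* **Ranges** are 0-based, half-open `[start, stop)`, given in X, Y, Z order
  — in the API, the REST dialect and the CLI box syntax alike. Half-open
  intervals compose cleanly under chunk arithmetic (a chunk is itself the
  half-open box `[i·c, (i+1)·c)`) and eliminate ±1 bookkeeping.
* **Arrays** are dimensioned `(X, Y, Z)` and indexed `[x, y, z]`. In R,
  the first index varies fastest, so the linearized memory is exactly the
  C-order `(z, y, x)` little-endian layout that numpy-style tools and the
  wire format use; serialization is a straight `writeBin()`.
* **Dtypes**: `uint8`/`uint16` image intensities are held in R integer
  arrays; `uint64` annotation labels in doubles, exact up to 2^53 — far
  above any label id in practice, and encoded/decoded to true 8-byte
  little-endian words at the storage and wire boundaries. Writes with a
  mismatched dtype are rejected, never cast: a silent cast can corrupt a
  label volume irreversibly.
* **Resolution pyramids** halve X and Y per level (`ceiling(extent / 2^r)`)
  and leave Z untouched by default, matching the anisotropic
  serial-section EM convention; `isotropic = TRUE` includes Z.

## Chunked cutouts

Chunked stores serve fixed-shape cuboids, so an arbitrary request is
decomposed along the chunk grid (`decompose()`), fetched, and stitched
(`stitch()`). The decomposition satisfies an exact partition invariant —
the per-chunk intersection boxes are pairwise disjoint and tile the request
— and the closed form for the number of touched chunks,
`prod(floor((stop-1)/c) - floor(start/c) + 1)`, always equals the plan
length. Plan order is fixed (k-major, then j, then i) so logs and tests are
deterministic; stitching matches blocks by chunk key, so arrival order is
irrelevant.

`periphery_fraction()` quantifies the cost of unaligned requests: the share
of downloaded voxels that lie outside the request and must be cropped
locally. Chunks clipped by the volume extents are counted at their clipped
size — nothing beyond the volume crosses the wire — so a request aligned to
chunk boundaries *or* volume edges scores exactly 0.

The default chunk shape is (512, 512, 16) in (X, Y, Z), the cuboid shape
common to cloud-scale stores; it is configurable per remote, and the test
suite mostly uses (32, 32, 8) so that multi-chunk behavior is exercised on
small volumes.

**Parallel fetch.** Callers may fetch plan entries concurrently with any
worker count; output must be — and is asserted to be — bit-identical to
serial execution. The mechanism differs by backend: file remotes fork
workers (`parallel::mclapply`), while the HTTP remote multiplexes
concurrent transfers on curl's multi interface in a single process. The
single-process design was chosen for the network path because forking a
process with live connection state is a classic source of rare, unreproducible
response interleaving; an event loop gives the same bandwidth saturation
with none of that risk. The default worker count is 4.

**On-disk dialect.** `file_chunk_remote()` stores
`root/<path>/meta.json` plus `res{r}/{i}_{j}_{k}.bin` chunk files of raw
little-endian voxels. Edge chunks are stored truncated to the clipped shape
and presented zero-padded. An absent chunk file *is* an all-zero chunk:
writers delete files whose content becomes all zeros, so sparse volumes
cost proportionally little disk.

**REST dialect.** The reference server (`serve_reference()`) and the relay
speak `GET/POST /v1/cutout/{path}/{res}/{x0}:{x1}/{y0}:{y1}/{z0}:{z1}/`
with gzip-compressed raw payloads, plus `/v1/resource`, `/v1/list`,
`/v1/capabilities` and (relays) `/v1/cache/stats`. Gzip was chosen as the
payload compression because it is universally available; error responses
are JSON `{error, message}` pairs whose `error` field round-trips into the
same classed R condition on the client, so error behavior is also
backend-independent. Data-instance resources are served as a single path
component — a documented extension of the three-component channel form.

## The mesh service

`marching_cubes()` extracts the isosurface of one label from a binarized
mask (`voxel == label`) at iso-level 0.5 with linear interpolation. The
256-entry per-cube case table is *generated at load time* rather than
transcribed: the unit cube is split into the six Kuhn tetrahedra around its
main diagonal, each tetrahedron is contoured by the 16-case
marching-tetrahedra analysis, and the resulting triangles are concatenated
per corner configuration. Because the Kuhn subdivision tiles space
consistently (face diagonals of adjacent cubes coincide), the surface is
watertight and consistently oriented *by construction*, and there are no
ambiguous configurations to special-case. On a binary mask every
interpolated vertex is an edge midpoint, so table entries are constant
offsets and extraction vectorizes over all cubes sharing a case. A
hand-transcribed classic table would risk silent transcription errors that
no in-repo evidence could catch; the generated table is verified instead by
construction-time orientation checks and by the suite's brute-force
per-cube walker, watertightness, Euler-characteristic and volume oracles.

Conventions and numerical choices:

* Vertices are `(global voxel index) × voxel_size`, so meshes from
  different cutouts of one volume land in a common physical frame (units:
  the frame's, nanometers by default — also the unit the precomputed
  format expects).
* Vertices shared between adjacent cubes are welded by exact coordinate
  match (coordinates are multiples of 1/4 in index space, so exact integer
  keys suffice; no tolerance is needed). This is what makes edge-incidence
  statistics meaningful.
* The mask is zero-padded by one voxel before contouring (default
  `pad = TRUE`), so objects touching the box face still close; with
  `pad = FALSE` a user-clipped face is left open and `mesh_stats()`
  reports the mesh as non-watertight. Padding is the right default for
  "mesh this object from this cutout"; the flag exists because a clipped,
  open mesh is the honest answer when the clip itself is the object of
  study.
* `mesh_stats()` computes the Euler characteristic V − E + F, watertightness
  (every edge borders exactly two triangles), and enclosed volume by the
  signed tetrahedron sum `|Σ v1 · (v2 × v3)| / 6` — exact for watertight,
  consistently oriented surfaces.

On voxelized balls the enclosed volume converges to the analytic
4/3·π·r³ as the radius grows (the deficit is a surface effect, so the
relative error scales like 1/r); the suite pins this at radii 5, 10 and 20.

Export formats: Wavefront OBJ (`v`/`f` records, 6 significant digits,
1-based indices) and the Neuroglancer *legacy* single-fragment precomputed
mesh — `uint32` vertex count, `float32` x/y/z triples in nanometers,
`uint32` 0-based triangle indices, exactly `4 + 12V + 12T` bytes. The
sharded multi-LOD precomputed variant, mesh simplification and
skeletonization are out of scope.

## The caching relay

`caching_relay()` answers the cutout dialect from a chunk-addressed LRU
cache, fetching misses from an upstream remote — which may itself be a
relay, so relays daisy-chain into multi-tier caches. Decisions:

* **Cache granularity = upstream chunk shape** (queried from upstream
  metadata). Cache keys then align with the server's cuboids, which is the
  same alignment argument that motivates chunk-aligned requests in the
  first place: a warm cache answers chunk traffic with zero upstream
  contact, which the tests assert via the relay's upstream-fetch counter.
* **LRU eviction** with hit/miss/byte counters exposed for inspection
  (`relay_stats()`, `GET /v1/cache/stats`). A single chunk larger than the
  entire capacity is served but not cached (pass-through), so a degenerate
  capacity can never wedge the relay.
* **Write-through coherence**: a write through the relay first invalidates
  every cached chunk intersecting the written box, then forwards upstream —
  reads through the relay are never stale. Writes that bypass the relay
  are declared out of contract (no invalidation protocol exists for them).
* If the upstream is unreachable, a request whose chunks are all cached is
  served; anything else raises an upstream-unavailable error. The relay
  never silently serves partial data.

## Transfers

`transfer_subvolume()` streams a box from one remote to another along the
*destination's* chunk grid (minimizing destination read-modify-write
amplification), block at a time, with strict dtype equality checked before
any write. Per-block failures are recorded without aborting the rest;
because completed blocks are plain last-writer-wins writes, re-running a
job is idempotent and completes a partial transfer.
`verify_transfer()` re-reads a seeded deterministic sample of blocks from
both sides. Transfers compose exactly: A→B→C equals direct A→C bit for bit,
which the suite checks via content hashes of the destination chunk files.

## Synthetic fixtures

The generators in `fixtures.R` stand in for external datasets so every
operation is testable offline, and they are designed as *oracles*, not just
data: the ramp volume `(x + 10y + 100z) mod m` makes any sub-box
recomputable independently of the read path; voxelized balls (voxel centers
at integer + 0.5, inside iff center distance ≤ r) have voxel counts within
2% of 4/3·π·r³ for r ≥ 8 and the full 48-fold octahedral symmetry when
centered; Voronoi label fields are a pure function of their seed, and the
generators save and restore the session RNG state so nothing leaks. What
they do *not* emulate: EM texture, imaging noise, anisotropic morphology,
or segmentation errors — so a passing suite certifies the data plumbing and
geometry engines, not robustness to realistic image content.

Problem sizes were chosen so that every multi-chunk, multi-tier and
multi-remote behavior is exercised while the whole suite stays interactive:
test volumes are typically 96 × 96 × 24 voxels over 32 × 32 × 8 chunks
(27 chunks), the randomized cross-backend script runs 200 steps, the
partition audit 1000 random request/chunk pairs, and mesh checks use balls
up to radius 20 (≈33,000 foreground voxels).

## Known limitations

* `uint64` labels are exact only below 2^53 (double storage).
* The reference server and relay are single-threaded httpuv loops —
  correct and adequate for local relaying and testing, not tuned for
  production concurrency; no authentication or TLS.
* One stored version per resource: version tags on data instances are
  accepted syntactically but there is no history or branching.
* The mesher is per-label (one watertight surface per id); multi-label
  boundary meshes, simplification, and skeletons are out of scope.
* Cache coherence assumes all writes flow through the relay.
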