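Package: voxelkit
Title: Unified Access to Chunked Volumetric Neuroimagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A trait-based toolkit for reading, writing and processing large
    three-dimensional image and segmentation volumes across interchangeable
    storage backends ("remotes"): in-memory arrays, an on-disk chunked-file
    store, and an HTTP cutout service with a bundled reference server.
    Arbitrary axis-aligned subvolume ("cutout") requests are decomposed into
    chunk-aligned blocks, fetched serially or in parallel, and stitched back
    into dense arrays.  Services run against any remote that satisfies their
    capability contract: a local marching-cubes mesh service extracts
    per-label isosurfaces in physical units and writes Wavefront OBJ or
    Neuroglancer legacy precomputed mesh fragments; a daisy-chainable caching
    relay answers the cutout dialect from a least-recently-used chunk cache;
    and a transfer engine copies subvolumes between remotes with post-copy
    verification.  Seeded synthetic fixtures (balls, tubes, ramps, Voronoi
    label fields) make every operation testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    curl,
    httpuv,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    callr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
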