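Package: tagscope
Title: Reconstruction of Images and Volumes from Time-Tagged Photon-Counting Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Offline reconstruction of 2D images and continuous 3D volumes from
    time-tagged photon-counting event streams, as produced by fast multichannel
    digitizers attached to two-photon microscopes. Photons are allocated to
    pixels or voxels through a precomputed "snake" of cell end-times, interleaved
    excitation beams are separated by temporal demultiplexing against the laser
    pulse train, and a varifocal (TAG) lens phase map extends the mapping to
    continuous volumes. A virtual-microscope simulator generates realistic
    synthetic tag streams with a ground-truth emission ledger so the whole
    pipeline can be exercised and validated without acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    arrow
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
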