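Package: cryoMAE
Title: Self-Supervised Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised particle picking for cryo-electron microscopy
    micrographs. Micrographs are background-normalized with FFT local
    statistics under a particle-sized circular mask, denoised and
    contrast-enhanced (Wiener, CLAHE, guided filtering), and tiled into
    small images on which a masked autoencoder is trained with a
    reconstruction objective only. Particles are segmented from background
    by clustering the per-token latent representations: a train-set k-means
    model anchored by a reference micrograph mask, followed by
    micrograph-specific hierarchical refinement. Post-processing converts
    the latent-space segmentation into particle coordinates with adaptive
    area thresholding and diameter, radius and border filters. Includes
    detection metrics (box IoU, unique matching, precision/recall/F1), a
    seeded synthetic-micrograph generator for fully offline testing, and
    readers/writers for MRC images and STAR/EMAN box coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
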