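Package: cbpdetect
Title: Egg Phenotyping and Detection of Conspecific Brood Parasitism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies avian egg phenotypes from calibrated UV-visible
    photographs and identifies conspecific parasitic eggs. Extracts colour,
    luminance, granularity pattern, spot and shape measurements from
    multichannel reflectance images (Phansalkar local thresholding for spot
    segmentation, difference-of-Gaussians granularity spectra, solid-of-
    revolution shape metrics); condenses them into nine PCA phenotypic
    traits; quantifies individual identity signal (within/between-clutch
    variance, Beecher's information statistic); and flags parasitized
    clutches and parasitic eggs with the maximum-Euclidean-distance
    statistic, importance-weighted distance ranking, and a supervised
    same/different random-forest vote classifier validated under
    leave-one-clutch-out and leave-one-egg-out schemes. Includes synthetic
    generators for trait tables and rendered egg images so every stage can
    be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
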