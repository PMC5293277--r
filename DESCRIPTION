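Package: scaffoldtrack
Title: Quantitative Image Analysis of 3D Cell Migration and Hydrogel
    Microarchitecture in Microfluidic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipelines for quantifying three-dimensional cancer-cell
    migration and collagen-Matrigel hydrogel microarchitecture imaged in
    microfluidic devices. Includes fluorescent cell segmentation by
    Chan-Vese energy minimization solved exactly with a graph min-cut,
    gated nearest-neighbour tracking, migration statistics (accumulated
    distance, speed, SVD-based polarity), confocal-reflection fiber
    network reconstruction (medial-axis tracing, persistence length,
    covering-radius pore sizing), SEM morphometry (statistical region
    merging, porosity, fiber diameter with intersection correction),
    diffusion-front quantification against the one-dimensional erfc
    solution, and a ground-truthed synthetic data generator emulating
    every acquisition modality.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
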