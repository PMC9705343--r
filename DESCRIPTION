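Package: epiScarMap
Title: Scar Compartment Mapping and Epicardial Electrophysiology
    Quantification for Post-Infarction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification chain for porcine post-infarction remodeling
    studies. Builds endocardial and epicardial half-wall signal-intensity maps
    from late gadolinium enhancement volumes and classifies healthy myocardium,
    heterogeneous tissue and dense scar by remote-SD thresholds; derives
    activation, APD80 and conduction-velocity maps from voltage-dye optical
    movies with isochrone-gradient velocity estimation; computes bipolar-voltage
    scar areas on electroanatomic surface meshes; converts semi-quantitative
    histology scores into area-weighted percentages; and provides exact
    nonparametric rank tests valid in the presence of ties. A synthetic-data
    generator with closed-form ground truth makes every stage testable
    end-to-end, including a two-arm in-silico study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    pracma,
    RNifti,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
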