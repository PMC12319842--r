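Package: atlasforge
Title: Hierarchical Region-Wise Brain Atlas Registration and Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for constructing 3D mouse brain reference
    atlases from multimodal imaging data. Implements ontology-driven
    region-by-region deformable registration between annotation versions of a
    common coordinate framework, rostral and caudal tissue extension with
    junction blending, per-lobule Otsu-based cerebellar layer segmentation with
    Purkinje-layer synthesis at fine resolution, slice-to-volume population
    average template construction, and the associated evaluation metrics:
    normalized mutual information, target registration error, Dice overlap,
    and per-region voxel and volume accounting. Ships a synthetic phantom-brain
    generator with recorded ground truth so the full pipeline can be exercised
    end-to-end without external atlas downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
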