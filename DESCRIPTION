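Package: oscillonet
Title: Mapping Dominant Cortical Rhythms to Brain Networks and Molecular Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify intracranial EEG channels by their dominant
    oscillatory rhythm using periodic/aperiodic spectral parameterisation
    (Morlet-wavelet power spectra decomposed into a 1/f background plus
    Gaussian peaks), to map channel locations onto whole-brain functional
    and structural networks with seed-based normative connectomics
    (spherical seeds, Gaussian smoothing, grey-matter masking, voxel-wise
    two-sample contrasts with permutation-based family-wise error control),
    and to quantify spatial overlap between those networks and molecular
    (PET) uptake maps via parcel-wise Spearman correlations with permutation
    nulls. Includes a synthetic-data module that generates every input with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
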