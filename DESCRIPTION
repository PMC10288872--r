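Package: callosum
Title: Sulci- and Connectivity-Based Parcellation of the Corpus Callosum
    Midsagittal Section
Version: 0.1.0
Authors@R:
    person("Marc", "Villard", , "marc.villard@example.org", role = c("aut", "cre"))
Description: Parcellates the midsagittal section of the corpus callosum into
    seven anterior-posterior parcels (frontopolar to occipital) by selecting
    transcallosal streamlines from a whole-brain tractogram, labelling them by
    the homologous cortical parcels they connect, and running a regularized
    majority vote on per-bundle fiber density maps restricted to the section.
    Includes readers and writers for NIfTI-1 volumes, TCK/TRK tractograms,
    labelled surface meshes and cohort tables; callosal and cortical parcel
    morphometry; group-comparison linear models with one-tailed diagnosis
    tests, eta-squared effect sizes and Benjamini-Hochberg FDR control; a
    percentile-based normative analysis; and seeded synthetic phantom and
    cohort generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
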