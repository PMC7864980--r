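Package: lungdecon
Title: Negative-Control Based Decontamination of Low-Biomass 16S OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the contaminant-aware analysis of low-biomass (lung)
    16S rRNA amplicon OTU tables built around a single negative control per
    patient. Implements ratio-based removal of contaminant OTUs from paired
    cancerous/healthy tissue samples, control-association diagnostics
    (Pearson correlation, percent of OTUs remaining), per-extraction-kit core
    contaminant profiling with a Venn partition, mock-community spike-in
    recovery scoring at the genus rank, and the supporting diversity
    statistics (Shannon index, weighted and unweighted Bray-Curtis, principal
    coordinates analysis, one-way permutation ADONIS, exact paired Wilcoxon
    signed-rank tests). Readers and writers for mothur shared and
    cons.taxonomy tables are included, together with a synthetic study
    generator with ground-truth contaminant labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
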