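Package: proxiglyco
Title: Proximity-Labelling Proteomics for Lectin Counter-Receptor Discovery
    and Permethylated Glycan Mass Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies lectin counter-receptors from proximity-labelling
    label-free quantitative (LFQ) proteomics by a four-stage filtration:
    per-dataset log2 fold-change computation with noise-floor imputation,
    detection of the membrane-protein "proximity labelling tail" by a
    hypergeometric enrichment test, paired t-test volcano selection with
    Benjamini-Hochberg correction, glycosylation/plasma-membrane annotation
    filtering, and back-mapping of candidates to every retained fold-change
    histogram. Downstream characterization covers membrane-proteome assembly
    from replicated identifications, counter-receptor abundance fractions,
    histone-ruler protein copy numbers per cell, N-glycosylation sequon
    scanning and density comparison, and glycogene-panel summaries of
    normalized RNA-Seq counts. A companion glycomics module computes
    monoisotopic [M+Na]+ m/z values of permethylated glycans from elemental
    residue formulas, enumerates N-glycan and glycolipid-glycan compositions
    under biosynthetic constraints, annotates centroided MALDI-TOF peak
    lists, and compares NeuAc/NeuGc counterpart intensities. A seeded
    synthetic-data generator with known spiked ground truth makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
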