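Package: pollenomics
Title: Quantification Workflows for Pollen Tube Heat-Stress Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-acquisition quantification workflows for targeted
    lipidomics, GC-based absolute quantification, and transcript-level
    aggregation in heat-stress experiments on in vitro grown pollen tubes.
    Implements lipid shorthand-nomenclature parsing with a configurable
    subclass registry, 13C isotopic correction of multiple-reaction-monitoring
    (MRM) peak areas, transition summation, reference-normalized subclass
    abundances, mol percent species profiles, acyl-chain saturation classes,
    and sphingolipid modification-occurrence profiles; internal-standard
    absolute quantification of triacylglycerols (GC-FID fatty acid methyl
    esters) and central metabolites (GC-MS); one-way ANOVA with post hoc
    Tukey HSD and compact letter displays; counts-per-million detection
    filtering, RPKM, and GO-term summed-RPKM fold-change statistics; and a
    seeded synthetic-data generator with recorded ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Matrix,
    withr
Config/testthat/edition: 3
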