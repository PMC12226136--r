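Package: cleavemap
Title: Protease Cleavage-Site Mapping from Comparative E/EQ Degradomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies protease cleavage sites from label-free quantitative
    comparisons of active (E) versus catalytically inactive (EQ) protease
    digests. Semi-specific (semi-tryptic / semi-GluC) peptides are classified
    by terminal specificity, candidate sites are called by z-scores on log2
    E/EQ abundance ratios, stratified by Tukey fences on peptide abundance,
    and corroborated by fully specific spanning peptides enriched in the
    inactive control. Includes site cataloguing across substrates and
    enzymes (deduplication, domain annotation, cross-enzyme sharing,
    isoform position mapping), iceLogo-style subsite specificity scoring,
    an enzyme-kinetics layer (Michaelis-Menten fitting, active-site
    titration, progress-curve specificity constants), and a synthetic E/EQ
    experiment generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
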