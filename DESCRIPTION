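Package: mtrscape
Title: Residue-Resolution Missense Constraint Across Protein Structural States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-residue Missense Tolerance Ratio (MTR) profiles
    from observed population variants and exhaustively enumerated possible
    single-nucleotide substitutions over a sliding window, flags
    significantly intolerant regions with FDR-adjusted exact binomial tests,
    consolidates curated and predicted disorder annotations into four
    structural states per residue, and runs the downstream statistical
    battery: amino-acid composition enrichment (Fisher exact tests with the
    Haldane-Anscombe correction), biophysical and segment-level patterning
    contrasts, clinical-class enrichment by structural state, Kruskal-Wallis
    with Dunn post hoc comparisons and compact letter displays, Wilson
    intervals and two-proportion z-tests. Includes a deterministic
    synthetic-data generator with planted constraint and enrichment effects
    so every stage is testable without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
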