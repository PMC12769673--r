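Package: sigmascreen
Title: Pooled CRISPR Suppressor-Screen Scoring, Simulation and 13C Tracing Arithmetic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genome-wide pooled CRISPR knockout fitness
    screens that use growth under drug treatment as the selection readout.
    Implements guide quantification from FASTQ, normalized log2 fold-change
    scoring, per-condition gene-level Z-scores, condition Z-differences
    (sigma plots) with fixed-threshold suppressor and synthetic-sick hit
    calling, and right-tailed Fisher gene-set enrichment. Ships a generative
    simulator of the pooled screen (latent abundance trajectories under
    exponential competition, multinomial sequencing, FASTQ emission with
    ground-truth labels) so every stage is testable without external data.
    Also provides growth-kinetics bookkeeping (population doublings,
    infection efficiency, Poisson MOI) and [1,2-13C2]-glucose isotope-tracing
    arithmetic: natural-abundance and tracer-purity correction of mass
    isotopomer distributions, total-intensity normalization, and the lactate
    m+1/m+2 pentose-phosphate-pathway index with a two-pathway labeling
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
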