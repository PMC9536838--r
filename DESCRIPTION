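Package: pgcmt
Title: Germline Mitochondrial DNA Quantity and Quality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial DNA (mtDNA) copy number and
    deletion heteroplasmy in sorted Caenorhabditis elegans primordial germ
    cells (PGCs) and germline stem cells. Implements Poisson inversion of
    droplet digital PCR (ddPCR) droplet counts into absolute template
    concentrations with delta-method confidence intervals, ploidy-corrected
    per-cell mtDNA copy number with an empirical ploidy estimator for cycling
    cells, deletion heteroplasmy and paired embryo-to-larva heteroplasmy
    shifts, 3D image measurements (colocalization-masked nucleoid focus
    counting, Manders coefficient, green/red acidification ratios with a
    twofold rule, cell-body mitochondrial fraction, geometric volumes), and
    hierarchical superplot statistics that test across biological replicates
    only. A stochastic simulator of germline mtDNA population dynamics
    (binomial segregation through reductive divisions, proportional and
    selective genome elimination, replication to a per-cell set point) and of
    droplet-level ddPCR readouts and synthetic image stacks provides
    ground-truthed inputs for validating every step of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
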