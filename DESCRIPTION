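Package: ptmdelta
Title: Detection of Protein Post-Translational Modifications from 13C
    Chemical-Shift Deviations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a protein residue carries a
    post-translational modification (lysine/arginine methylation, lysine
    acetylation, serine/threonine/asparagine glycosylation) from the
    deviation (Delta) of a 13C chemical shift from the mean shift of the
    unmodified residue.  Provides paired conformational-ensemble
    generation for capped model tripeptides from torsion-angle libraries,
    a synthetic shielding surrogate with calibrated additive modification
    effects, preprocessing of experimental-style chemical-shift tables
    (DSS re-referencing, Tukey-fence outlier removal, per-residue
    reference statistics), Delta-distribution statistics with kernel
    density summaries, and a Bayesian two-state model yielding posterior
    probability profiles P(state | Delta) with uncertainty bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rjags,
    coda,
    igraph
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
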