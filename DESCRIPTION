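Package: craclab
Title: Modeling and Quantification of ORAI Heteromeric CRAC Channel Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying store-operated calcium entry (SOCE) through
    CRAC channels assembled from ORAI1/2/3 subunits. Solves the mass-action
    equilibrium of ORAI dimer formation and the resulting population calcium
    influx across knockout genotypes; estimates dimer binding constants from
    genotype influx targets by algebraic elimination, one-dimensional root
    scanning with feasibility continuation, and least-squares fitting;
    simulates whole-cell calcium oscillations under agonist-staircase and
    thapsigargin protocols with influx supplied by the dimer model; counts and
    enumerates distinct hexameric channel arrangements by Burnside's Lemma;
    classifies single-cell calcium traces (oscillating, plateau,
    non-responding) with per-coverslip summaries; and computes three-cube
    FRET efficiency, NFAT translocation ratios, SOCE magnitude, and
    calcium-dependent inactivation fractions. Includes a synthetic-data
    generator producing ground-truth-labeled trace populations, FRET triples,
    and influx calibrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
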