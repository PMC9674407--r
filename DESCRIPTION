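Package: markerArray
Title: Pangenome Genotyping with a Smeared Marker Array over an FM-Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds an FM-index over a concatenated haplotype panel (a
    reference plus phased alternative haplotypes derived from a VCF) and
    attaches a run-length-compressed "smeared" marker array that maps
    Burrows-Wheeler rows to alleles at polymorphic sites. Short reads are
    genotyped by a heuristic backward search that periodically queries the
    marker array, with exact FL-stepping and locate-based marker queries
    available as internal oracles, and diploid genotypes are called from
    per-site allele counts with a standard genotype-likelihood model.
    Includes a deterministic synthetic-fixture generator (toy references,
    phased panels, error-bearing diploid read sets) so the whole pipeline
    runs at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'alphabet.R'
    'bundle.R'
    'evaluate.R'
    'fm-index.R'
    'genotype-caller.R'
    'genotype-query.R'
    'marker-codec.R'
    'marker-index.R'
    'markerArray-package.R'
    'panel.R'
    'reference.R'
    'show-methods.R'
    'simulate.R'
    'vcf-writer.R'
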