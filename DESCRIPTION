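Package: pedsandwich
Title: Mendelian Consistency Checking, Simulation and Sandwich Layouts for
    Genotyped Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking genotyped pedigrees for Mendelian
    inheritance inconsistencies. Parses and validates pedigree and genotype
    tables (native TSV dialects and PLINK PED), infers missing genotypes by
    nuclear-family genotype elimination (constraint propagation to fixpoint,
    per marker), classifies every observed genotype into three error
    categories (no allele from sire, no allele from dam, novel allele) with
    support for sex-linked hemizygous null alleles, and aggregates error and
    incompleteness statistics per individual, marker and family. Includes a
    gene-dropping simulator with parameterizable pedigree generation, marker
    templates, generation-level data erasure and a catalogue of 25 pedigree
    and genotype error-injection categories with invertible ground truth, a
    packaged scenario suite with machine-checkable expected error patterns,
    and a generational "sandwich" layout model (sires above, dams below each
    offspring generation) serializable to JSON and static SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
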