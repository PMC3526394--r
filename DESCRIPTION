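Package: bsamap
Title: Bulk Segregant Analysis Mapping from Pooled Exome Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps recessive mutations from pooled (bulk segregant) exome
    sequencing of an intercross. Reads samtools pileup files for a wildtype
    and a mutant pool, calls putative SNPs from per-base allele counts using
    wildtype major-allele-fraction criteria, scans scaffolds or 0.5 Mb
    windows for loss of heterozygosity via the homozygosity ratio r = nh/nt,
    designs CAPS/RFLP markers whose restriction sites are created or
    abolished by a SNP, converts recombinant counts to genetic distance, and
    flags candidate genome misassemblies from multi-scaffold LOH signal.
    A built-in intercross simulator (Haldane recombination, pooled
    binomial sequencing with base-call error) generates standard pileups
    with known truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
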