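Package: mtPopGen
Title: Population Genetics of Human mtDNA Control-Region Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses rCRS-relative control-region variant strings (HVRI/HVRII
    plus typed coding segments), classifies haplotypes into haplogroups by
    motif best match against a user-supplied tree, and computes the classic
    mtDNA population-genetic summaries: haplotype and nucleotide diversity,
    mean pairwise differences, Tajima's D and Fu's Fs with coalescent
    p-values, distance-based AMOVA and pairwise Phi-ST with permutation
    tests, rho-statistic founder ages with Saillard-type standard errors,
    inverse-distance-weighted haplogroup-frequency surfaces, and Moran's I
    distance-class correlograms with cline detection. Ships an 81-sample
    Moroccan control-region survey as a worked fixture together with
    coalescent, clade and spatial-field simulators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, geosphere
Suggests: testthat (>= 3.0.0), ape, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
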