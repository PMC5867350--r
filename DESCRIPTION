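Package: karyevol
Title: Comparative Cytogenetics and Chromosome-Number Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative cytogenetic analysis of karyotype
    evolution: parsing of karyotype formulas and constitutive
    heterochromatin band annotations, pairwise karyotype divergence
    indices and UPGMA phenograms, maximum-likelihood Brownian-motion
    ancestral reconstruction of diploid number with Pagel's lambda and
    Blomberg's K phylogenetic-signal statistics, a family of gain/loss/
    duplication continuous-time Markov chain models of haploid
    chromosome-number evolution with AIC model selection, marginal
    ancestral states and stochastic mapping of fusion/fission events,
    and parsimony-style inference of Robertsonian fusions and
    pericentric inversions along a phylogeny. Ships a worked example
    data set for the Neotropical electric knifefish genus
    Brachyhypopomus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
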