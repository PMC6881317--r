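Package: retroselect
Title: Branch and Branch-Site Codon Models for Positive Selection in
    Retrogene Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood analysis of positive selection in
    duplicate gene pairs, built around the chimeric retrogene / parental
    gene setting in Oryza. Implements the 61-state codon substitution
    model with branch-specific dN/dS classes, a stepwise search for the
    optimal branch-specific model (three search strategies with
    likelihood-ratio and AIC guards), branch-site site-class models (M1a,
    Model A and its fixed-omega null) with Bayes empirical Bayes
    identification of positively selected sites, Tajima's D under
    complete deletion, Nei-Gojobori (1986) Ka/Ks with synonymous-clock
    dating, evolutionary-pattern classification of retrogene pairs, and a
    codon-sequence simulator with known per-branch and per-site truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
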