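Package: callspace
Title: Sender-Receiver Decoupling Analysis of Frog Advertisement Call
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether an acoustic signal and its recognition
    evolve in a coupled or decoupled fashion across populations, built
    around the Allobates femoralis call system. Fits per-population
    recognition surfaces (penalized B-spline logistic regression of binary
    phonotaxis on stimulus mid-frequency and call note number) with a
    likelihood-ratio note-effect test and Bonferroni correction; computes
    the relative-response statistic (area under the predicted response
    curve for each note variant as a proportion of the own-call area);
    reconstructs ancestral call note number under an equal-rates Mk model
    by marginal (rerooting-equivalent) likelihood across single trees or
    posterior tree samples; counts state changes; and synthesizes the two
    analyses into a coupled/decoupled verdict with a permutation test of
    whether ancestral states predict contemporary responses. Includes a
    fully seeded synthetic-data generator (Yule trees, Mk characters,
    Bernoulli phonotaxis trials) emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    Matrix,
    mgcv,
    phangorn,
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
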