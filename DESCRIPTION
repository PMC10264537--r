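Package: sweardar
Title: Sound Patterns in Profanity: Resampling, Forced-Choice and
    Minced-Oath Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cross-linguistic sound symbolism in
    profanity. Tokenizes and classifies ASJP-coded wordlists into six
    consonant groups (plosives, affricates, approximants, sibilant and
    non-sibilant fricatives, nasals), builds Monte-Carlo resampling nulls
    for phoneme-group over/under-representation of a swear-word lexicon
    against a Swadesh-style control list, analyses two-alternative
    forced-choice "sweardar" experiments (participant and trial exclusion
    machinery, an exact dynamic-programming run-length false-exclusion
    probability, and an intercept-only logistic mixed model with crossed
    participant and item random effects), and runs a Wilcoxon signed-rank
    test with Pratt zero handling on paired approximant counts of swear
    words and their minced oaths. A synthetic-data generator with known
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    optparse
Config/testthat/edition: 3
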