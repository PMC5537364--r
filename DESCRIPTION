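Package: patwas
Title: Pattern-Wide Association Scanning of Case-Labelled Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines conserved text patterns from case-labelled clinical
    document collections and ranks them by univariate association with
    binary or numeric outcomes, by analogy with genome-wide association
    scans. Documents are segmented into sentences and word tokens, and
    optionally annotated at the token level (cardinal numbers, Porter
    stems, part-of-speech tags) and at the sequence level (vocabulary
    concepts, parse-derived groups). All sufficiently supported n-grams,
    token/tag sub-sequences, and numeric "A <NUMBER> B" constructs are
    enumerated exhaustively within sentence boundaries, tested with exact
    or rank-based statistics (Fisher's exact test and odds ratios,
    Mann-Whitney AUC, Spearman's rho), filtered, and reduced. Syntactically
    similar n-grams can be consolidated into linear token-level regular
    expressions by Needleman-Wunsch alignment and re-scored. Top-ranked
    patterns can serve as covariates for bootstrap-evaluated case
    classification with UPGMA-decorrelated feature selection. A synthetic
    corpus generator with planted associations supports end-to-end
    validation without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
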