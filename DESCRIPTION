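Package: sweeptm
Title: Vector Text Mining of Literature Corpora via Spaced-Word Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A vector text-mining environment for literature corpora. Documents
    (title plus abstract) are re-expressed over a biological alphabet with the
    AMINOcode and DNAbits codecs, indexed by spaced words into a sparse
    high-dimensional count vector, and compressed through a seeded random
    orthonormal projection (the SWeeP representation). Words, documents, boolean
    substring queries (LOGEXP) and free-form queries are co-embedded in one
    vector space by averaging, supporting k-nearest-neighbour semantic search,
    Neighbor-Joining dendrograms with Newick output, relevance-filtered
    vocabularies against a background word-frequency table, static HTML
    navigation reports, and synthetic corpora with planted topic structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
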