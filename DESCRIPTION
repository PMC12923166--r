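Package: mbcprimer
Title: Host-Exclusive Metabarcoding Primer Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and evaluate discriminative ("host-exclusive")
    metabarcoding primers from a multiple sequence alignment of a target
    taxon set and an exclusion (host) set. Slides a primer-length window
    over the alignment, builds edit-distance mismatch profiles of both
    sets against the most abundant target variant, ranks windows with a
    cumulative discriminative score, and filters and groups candidate
    sites into a tab-separated report. Downstream evaluation covers GC
    content, melting temperature, 3'-end discrimination, degenerate
    consensus proposal, in-silico probe coverage at 0-2 mismatches, and
    primer-pair compatibility. Includes a seedable simulator that plants
    discriminative sites with known mismatch profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
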