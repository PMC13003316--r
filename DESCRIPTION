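Package: longdustr
Title: Statistical Detection of Low-Complexity DNA with the Longdust Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies low-complexity (LC) DNA regions such as homopolymers,
    short tandem repeats and long satellite arrays. String complexity is
    defined through a multinomial bag-of-words model of k-mer counts whose
    expectation under the null is removed with a Poisson-approximated scaling
    function, giving a score that stays near zero on random sequence and grows
    on compositionally repetitive sequence. LC intervals are located with an
    efficient backward/forward candidate scan over long context windows, with
    optional X-drop splitting, and strand-symmetric output is produced by
    taking the union of calls on both strands. Includes the SDUST and Shannon
    entropy scoring functions for comparison, a brute-force interval oracle
    for validation, FASTA/BED input and output, soft/hard masking, a synthetic
    tandem-repeat sequence simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
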