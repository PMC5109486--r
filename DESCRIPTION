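Package: tipf
Title: Target Interaction Profile Fingerprints for Multi-Target Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Curates compound-target bioactivity tables into a reference
    standard of positive interactions, encodes each compound as a sparse
    binary target-interaction profile fingerprint (TIPF), compares compounds
    by the Tanimoto coefficient of their profiles, scores every
    compound-target combination by its maximum similarity to known binders
    of the target, and evaluates recovery of known interactions with
    threshold metric curves, random hold-out validation and a two-sided
    Fisher exact test. Includes a deterministic synthetic-data generator
    that emulates pharmacological families of compounds sharing targets,
    so every stage is testable without a database download.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
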