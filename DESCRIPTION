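Package: dcnfl
Title: Feature-Learnability of Nerve-Evoked Brainstem Surface Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-electrode evoked surface potentials of the dorsal
    column nuclei (DCN), extracts low- and high-frequency signal features from
    seven-electrode recordings, and quantifies "feature-learnability": the
    classification accuracy with which a small feed-forward neural network can
    recover the stimulated hindlimb nerve (left/right sural or peroneal) from
    chosen feature/electrode inputs. Includes three data-partitioning schemes
    (within-animal, pooled-population, leave-one-animal-out), an adapted
    sequential forward search for input minimization, thin-plate-spline
    mapping of learnability over the brainstem surface, and a statistical
    validation layer (non-significant loci, side dominance, and their
    relationships to classification error).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
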