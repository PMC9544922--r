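Package: mepkit
Title: Quantification of Evoked and Voluntary Forelimb EMG After Cervical
    Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying forelimb muscle function from
    intramuscular electromyography (EMG) in rodent cervical spinal cord
    injury studies. Implements the full analysis chain for motor evoked
    potentials (MEPs) elicited by epidural cortical stimulation
    (stimulus-triggered sweep epoching, automated clean-sweep selection,
    rectification, 5-point smoothing, steep zero-phase low-pass filtering,
    DC-offset correction, baseline-relative onset/offset detection and
    area-under-curve measurement) and for maximum voluntary contraction
    (MVC) recordings acquired during a grip-strength task. Includes a
    seeded synthetic EMG session generator with known ground truth, a
    statistics layer (one-way ANOVA with Tukey/Bonferroni/Dunnett
    post-hocs, split-plot repeated-measures ANOVA with Greenhouse-Geisser
    correction, exact Mann-Whitney U by full enumeration) and a
    motor-neuron pool-mapping analysis of cholera-toxin-B traced biceps
    motor neuron counts across spinal levels C2-T2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
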