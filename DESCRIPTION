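Package: mouseEEG
Title: Auditory EEG Biomarkers for Rodent Pharmaco-EEG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wireless mouse EEG biomarkers of
    NMDA-receptor hypofunction: auditory event-related potentials (N1
    amplitude and paired-click sensory gating), basal and evoked gamma and
    theta oscillation power from a complex Morlet wavelet decomposition,
    40 Hz auditory steady-state response power and intertrial coherence,
    and mismatch negativity from a flip-flop oddball paradigm, together
    with the linear mixed-model treatment-contrast layer with Bonferroni
    families.  A synthetic-EEG generator with parameterized drug effects
    provides ground truth for every stage, and recordings are read and
    written in the European Data Format (EDF) with trigger-channel event
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
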