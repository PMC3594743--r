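Package: actiondiscovery
Title: Embodied Basal-Ganglia Model of Intrinsically Motivated Action Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an embodied agent that discovers action-outcome
    contingencies without extrinsic reward. The biomimetic core couples a
    rate-coded basal-ganglia action-selection network (with thalamocortical
    loops and tonic-dopamine modulation of cortico-striatal transmission), a
    phenomenological model of phasic-outcome prediction that generates novelty
    salience and habituation dynamics, a phasic dopamine signal computed as a
    sensory prediction error via superior-colliculus and canceling pathways,
    and a dopamine-blended BCM rule for cortico-striatal plasticity at D1- and
    D2-expressing medium spiny neurons. A kinematic two-dimensional arena with
    an active (red) and inactive (white) block embeds the core in a
    differential-drive agent performing a two-block operant task under
    variable-interval or fixed-ratio reinforcement schedules, with multi-day
    protocol running, replicate averaging and response/weight metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
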