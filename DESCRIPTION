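Package: groupweight
Title: Group-Weight Bio-Feedback Brain-Machine Interface Decoder and
    Closed-Loop Task Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the group-weight bio-feedback decoder for
    intracortical brain-machine interfaces: four groups of motor-cortical
    units drive the four cardinal directions of a 2D cursor through
    normalized, rectified summed firing rates (action values).  Provides
    the decoder with its normalization-constant estimation, preferred
    direction estimation and sector-based neuron grouping, a closed-loop
    center-out task simulator in two variants (fixed cardinal targets with
    cursor reset and a pre-movement freeze period, or alternating
    center/periphery targets at random angles), a synthetic cosine-tuned
    Poisson population whose preferred directions rotate toward their
    assigned directions across practice sessions, a shuffled-bin chance
    baseline procedure, and behavioral/neural learning analyses
    (success-rate logistic trends, trajectory straightness scores, cursor
    occupancy maps, output-potent/output-null group activity, direction
    tuning fits, and normalized preferred-direction/assigned-direction
    distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
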