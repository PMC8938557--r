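Package: affectbandit
Title: Affect-Primed Probabilistic Gambling: Task Simulation, Hierarchical
    Bayesian Reinforcement-Learning Models and ERP Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how affective primes modulate reward-based
    decision making in a two-choice probabilistic gambling task. Simulates
    block-structured bandit sessions, generates choices from delta-rule /
    softmax agents, fits a hierarchical Bayesian reinforcement-learning
    model (learning rate and choice consistency) by MCMC, computes
    win-stay/lose-shift strategy rates split by rich and poor decks,
    extracts N170, P200 and feedback-related negativity (FRN) components
    from multichannel EEG, and correlates subject-level measures with
    PANSS symptom factors under Holm-Bonferroni sequential correction.
    Includes a synthetic-cohort generator (behavior, EEG, PANAS, symptom
    scores) so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
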