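Package: wintermurre
Title: Winter Biologging Pipeline for Diving Seabirds: Behaviour, Energetics
    and Thermal Habitat States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing winter temperature-depth-immersion logger
    data from diving seabirds such as thick-billed murres. Detects dives,
    flight and leg-tucked resting from 10-s multichannel records, estimates
    bird-detected sea surface temperature from thermally stable at-surface
    intervals, builds daily activity budgets and activity-based daily energy
    expenditure and apparent energy intake, classifies dive timing by solar
    light category, and fits a three-state Gaussian hidden Markov model with
    multinomial-logit covariate-dependent transition probabilities to daily
    SST to decode thermal habitat states. Includes a ground-truth simulator
    of multi-bird winter logger datasets so the full pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
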