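Package: ciccea
Title: Markov Cohort Cost-Effectiveness Model for Chronic Idiopathic
    Constipation Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model comparing the societal costs and
    constipation-specific quality of life (PAC-QoL) of three pharmacological
    treatments for chronic idiopathic constipation in Japan (elobixibat 10 mg,
    linaclotide 0.5 mg, lubiprostone 48 ug). Accumulates discounted medical,
    caregiving and productivity costs over a configurable horizon, estimates
    responder proportions from synthesized bowel-movement summaries, and
    provides deterministic (one-way, +/-20%) and probabilistic (Monte Carlo)
    sensitivity analyses, six scenario analyses including a tunnel-state
    add-on-treatment extension, an individual-level microsimulation oracle,
    and table writers mirroring the published result layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
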