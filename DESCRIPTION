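Package: shiftload
Title: Forward-Time Simulation of Expansion Load During Range Expansions
    and Range Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based, forward-time simulation of diploid
    populations expanding or shifting their range across a stepping-stone
    landscape, tracking the accumulation of deleterious mutation load
    ("expansion load") at the moving front. Demes undergo logistic growth
    under soft or hard selection, nearest-neighbour migration, multiplicative
    multilocus selection with configurable dominance and distributions of
    fitness effects, and free or absent recombination. Range shifts move a
    constant-width habitable window at a fixed speed v = 1/T; range
    expansions open the whole landscape at once. A companion analytic model
    propagates expected front fitness through serial founder events via
    diffusion fixation probabilities, yielding closed-form and numerical
    predictions for the shift speed maximising fitness loss per deme, the
    speed at which load accumulation vanishes, and extinction under hard
    selection. Observables include front and core fitness, fixed mutation
    counts, neutral heterozygosity and realized expansion speed, aggregated
    over replicate simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
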