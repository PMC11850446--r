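Package: fwb
Title: Mass-Balance Food-Web Models and Ecological Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construct, balance, and analyse trophic mass-balance
    (Ecopath-type) food-web models. Solves the linear production balance
    for ecotrophic efficiencies or biomasses, derives per-group energy
    budgets, aggregates flows onto the discrete trophic levels of the
    Lindeman spine with producer- and detritus-origin transfer
    efficiencies, and computes the standard ecological network analysis
    suite: total system throughput, Finn's cycling index and path
    lengths, connectance, system omnivory, Shannon diversity, ascendency
    and development capacity, mixed trophic impacts, and keystoneness.
    Includes pedigree scoring with Monte Carlo uncertainty propagation
    under mass-balance acceptance constraints, and a synthetic food-web
    generator with disturbance scenarios (pollution-driven truncation,
    overfishing, species invasion) for testing analysis pipelines
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
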