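Package: jellyom
Title: Carbon and Nitrogen Budgets of Microbial Jellyfish-Detritus Degradation
Version: 0.1.0
Authors@R: person("Piran", "Bench", email = "piran.bench@example.org", role = c("aut", "cre"))
Description: Tools for analysing batch-culture degradation experiments of
    jellyfish detrital organic matter (jelly-OM): normalisation of leaching
    time series to per-dry-mass release rates and their C:N stoichiometry,
    exponential-phase growth kinetics and the bacterial carbon budget (carbon
    demand, production, respiration, growth efficiency), dissolved free and
    combined amino-acid pool bookkeeping, label-free proteome turnover from
    peptide spectrum matches per residue, and reads-per-million community
    abundance. Includes a synthetic batch-culture generator with known ground
    truth for parameter-recovery testing and a small pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
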