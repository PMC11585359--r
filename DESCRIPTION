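Package: crownscale
Title: Leaf-to-Canopy Scaling of Photosynthetic Temperature Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-tree canopy photosynthesis from coupled leaf-level
    gas exchange (Farquhar-von Caemmerer-Berry biochemistry, Medlyn optimal
    stomatal conductance, iterative leaf energy balance) scaled to tree crowns
    with single big-leaf, sunlit/shaded two-leaf, and multilayer crown-grid
    radiation schemes. Includes within-crown photosynthetic capacity profiles,
    seasonal thermal acclimation of Vcmax and Jmax to growth temperature, eight
    canonical parameterization scenarios, temperature-response fitting tools
    (quadratic optimum, peaked Arrhenius, A/Ci curves, stomatal slope g1,
    penalized-spline optima), model-observation evaluation, and a synthetic
    whole-tree-chamber data generator so the full leaf-versus-canopy
    temperature-optimum analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
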