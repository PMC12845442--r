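Package: oralpbpk
Title: Mini-PBPK Simulation of Local Drug Delivery in the Oral Cavity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physiologically based simulator of local drug delivery to the
    oral cavity. Couples a library of drug release kinetics models (Higuchi,
    Korsmeyer-Peppas, Peppas-Sahlin, Hixson-Crowell, Baker-Lonsdale, Weibull,
    and a biphasic burst/zero-order form) to a reduced five-region
    pharmacokinetic transport model comprising saliva, a Langmuir-type
    pellicle binding layer, mucosal tissue, a one-dimensional diffusing
    biofilm slab, and the periodontal pocket with gingival crevicular fluid
    wash-out. Provides release-curve fitting with AIC/BIC model selection,
    classical compartmental pharmacokinetics for any systemically absorbed
    fraction, antimicrobial exposure indices (time above MIC, AUC/MIC,
    Cmax/MIC), effect-compartment and indirect-response pharmacodynamics,
    case-study scenario presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
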