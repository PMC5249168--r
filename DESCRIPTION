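Package: RotamerEnsembles
Title: Comparing Side-Chain Rotamer Ensembles Between Crystal and Solution
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discretizes side-chain chi-angle trajectories into rotamer
    states and compares the resulting per-residue rotamer probability
    distributions between two simulation conditions (typically crystal and
    solution molecular dynamics of the same protein). Implements a
    null-model-normalized likelihood score against the X-ray side-chain
    conformations, the histogram overlap coefficient, Kullback-Leibler
    divergence, and configurational-entropy differences reported as
    T*dS at 300 K, together with crystal-contact detection using
    space-group symmetry expansion, Shrake-Rupley relative solvent
    accessibility, a two-segment uncertainty estimate, and a synthetic
    trajectory generator with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
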