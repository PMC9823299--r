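Package: gierc
Title: Reversible Graph-Embedded Relative Coordinates for Molecular
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes molecular 3D conformations into a translation-,
    rotation- and atom-exchange-invariant tensor of local-frame relative
    coordinates embedded with 2D molecular-graph information, and decodes
    the tensor back to Cartesian coordinates losslessly through consensus
    internal coordinates. Includes baseline Cartesian and internal
    coordinate (Z-matrix) representations with a percentage-noise
    robustness benchmark, a graph-conditioned autoencoder over per-atom
    features for conformer generation by latent-space interpolation, a
    naive whole-tensor autoencoder baseline, torsion-space conformer
    clustering, and a synthetic conformer-ensemble generator with
    controlled multi-modal torsion distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
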