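Package: lhcircuit
Title: Connectomic, Morphometric and Behavioral Analysis of Lateral Horn
    Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational pipeline used to characterize
    mushroom-body-to-lateral-horn circuitry in the adult Drosophila brain:
    a registered expression-pattern voxel-overlap screen with
    peduncle-background normalization, neuron-skeleton polarity analysis via
    centrifugal synapse flow centrality and the axon-dendrite segregation
    index, NBLAST-style morphology similarity scoring with Ward clustering,
    connector-table connectivity analytics (input fractions, polyadic
    fan-out, excitatory-share bounds), calcium-imaging dF/F0 response
    quantification, and T-maze performance/avoidance/attraction indices.
    Includes a synthetic-data module that generates every input with planted
    ground truth, so the whole pipeline is testable without raw imagery or an
    EM volume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    RANN,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'constructors.R'
    'behavior.R'
    'connectivity.R'
    'io-skeletons.R'
    'io-volumes.R'
    'morphometry.R'
    'physiology.R'
    'polarity.R'
    'screen.R'
    'simulate.R'
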