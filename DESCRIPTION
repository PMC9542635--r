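Package: capscan
Title: Ensemble Computational Alanine Scanning and Photocaged Binder Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computationally guided paratope engineering of
    protein binders such as anti-GFP nanobodies. Reads multi-model PDB/mmCIF
    ensembles of a two-partner complex, computes an empirical cross-interface
    binding free energy with a fully specified surrogate pair potential,
    performs per-residue alanine-truncation scans averaged over the ensemble
    to rank hot-spot residues, annotates interface contacts (distance,
    hydrogen-bond proxy, cation-pi), converts affinity fold-changes to
    binding free-energy differences, models equilibrium occupancy and the
    nuclear/cytoplasmic localisation read-out of an intracellular binding
    assay, fits one-site specific binding curves to ELISA-style data, and
    plans caged-OFF/uncaged-ON photoswitchable variants combining a
    photocaged tyrosine with secondary alanine mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
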