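Package: enzdes
Title: Desk-Scale De Novo Enzyme Design by Theozyme Matching and Constrained Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grafting minimal model active sites ("theozymes") into
    protein scaffolds and designing the surrounding residues, following the
    classic four-stage enzyme-design protocol: a geometric-constraint (cstfile)
    representation of catalytic interactions, classic and secondary matching
    with 6D pose hashing, restrained sequence design over a documented
    simplified energy model, and per-design evaluation metrics (restraint
    scores, buried unsatisfied polar atoms, packing proxy, interface score)
    with cutoff-based ranking. Ships deterministic synthetic fixtures (toy
    pocket scaffolds, a DHAP-like ligand, a triosephosphate-isomerase-like
    theozyme) so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
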