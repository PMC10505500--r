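Package: commchem
Title: Chemical Metrics for Community Reference Proteomes from 16S rRNA Taxonomic Classifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts taxonomic classifications of 16S rRNA amplicon data
    (RDP Classifier hierarchical output files or generic OTU/ASV count
    tables with taxonomy assignments) into community reference proteomes:
    abundance-weighted mean amino acid compositions drawn from a per-taxon
    reference proteome database. Computes chemical metrics for these
    inferred proteomes, including carbon oxidation state (Zc),
    stoichiometric oxidation and hydration state (nO2, nH2O) from a
    basis-species projection, elemental ratios (H/C, N/C, O/C, S/C),
    protein length, residue molecular weight, GRAVY, and isoelectric
    point. Includes a builder for reference proteome databases from
    protein FASTA files with GTDB-style taxonomy strings, deterministic
    synthetic-fixture generators with known ground truth, and ggplot2
    visualization of metrics against sample variables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    withr,
    ggplot2,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
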