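# Shared builders for toy inputs; everything is generated in code.

# Write an RDP hierarchical TSV from a list of rows; each row is
# list(lineage, name, rank, counts). Returns the file path.
write_rdp_file <- function(rows, samples = "s1") {
  lines <- paste(c("taxid", "lineage", "name", "rank", samples),
                 collapse = "\t")
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    lines <- c(lines, paste(c(i, r$lineage, r$name, r$rank, r$counts),
                            collapse = "\t"))
  }
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# The cumulative toy hierarchy used in several ingestion tests:
# Root 10 > Bacteria 10 > Proteobacteria 8 > Gammaproteobacteria 6 >
# Escherichia 5 (counts per extra sample appended as-is)
toy_rdp_rows <- function(counts = list(c(10), c(10), c(8), c(6), c(5))) {
  lin <- c(
    "Root;rootrank",
    "Root;rootrank;Bacteria;domain",
    "Root;rootrank;Bacteria;domain;Proteobacteria;phylum",
    "Root;rootrank;Bacteria;domain;Proteobacteria;phylum;Gammaproteobacteria;class",
    "Root;rootrank;Bacteria;domain;Proteobacteria;phylum;Gammaproteobacteria;class;Escherichia;genus"
  )
  nm <- c("Root", "Bacteria", "Proteobacteria", "Gammaproteobacteria",
          "Escherichia")
  rk <- c("rootrank", "domain", "phylum", "class", "genus")
  purrr::map(seq_along(nm), function(i) {
    list(lineage = lin[i], name = nm[i], rank = rk[i], counts = counts[[i]])
  })
}

# Write a protein FASTA file from named sequences
write_faa <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".faa",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# A refdb where every taxon has the same composition (handy oracle)
uniform_refdb <- function(comp = aa_composition(Gly = 2, Ala = 1, Lys = 1),
                          taxa = c("Genus_A1", "Genus_A2")) {
  rows <- purrr::map_dfr(taxa, function(tx) {
    dplyr::bind_cols(
      tibble::tibble(rank = "genus", name = tx, n_genomes = 1L,
                     n_proteins = 10),
      comp[, setdiff(names(comp), "chains")]
    )
  })
  rows
}

# Independent net-charge oracle for pI tests (same model, separate code)
net_charge <- function(counts3, chains, ph) {
  pk <- c(Cterm = 3.55, Asp = 4.05, Glu = 4.45, His = 5.98, Nterm = 7.5,
          Cys = 9.0, Tyr = 10.0, Lys = 10.0, Arg = 12.0)
  basic <- c("His", "Lys", "Arg", "Nterm")
  n <- c(counts3, Nterm = chains, Cterm = chains)
  q <- 0
  for (g in names(pk)) {
    ng <- if (g %in% names(n)) n[[g]] else 0
    if (ng == 0) next
    q <- q + if (g %in% basic) ng / (1 + 10^(ph - pk[[g]]))
    else -ng / (1 + 10^(pk[[g]] - ph))
  }
  q
}
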