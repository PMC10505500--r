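test_that("lowest-level decomposition of the cumulative toy hierarchy", {
  path <- write_rdp_file(toy_rdp_rows())
  ct <- read_rdp_hierarchy(path)
  expect_setequal(ct$name,
                  c("Escherichia", "Gammaproteobacteria", "Proteobacteria"))
  got <- stats::setNames(ct$s1, ct$name)
  expect_equal(got[["Escherichia"]], 5)
  expect_equal(got[["Gammaproteobacteria"]], 1)
  expect_equal(got[["Proteobacteria"]], 2)
  # Bacteria's residual 2 dropped as domain-level
  smry <- classification_summary(ct)
  expect_equal(smry$dropped_above_phylum, 2)
  expect_equal(smry$total, 10)
  expect_equal(smry$retained + smry$dropped_above_phylum + smry$filtered,
               smry$total)
})

test_that("filter terms remove whole lineages and their counts", {
  rows <- c(toy_rdp_rows(counts = list(13, 13, 8, 6, 5)), list(
    list(lineage = "Root;rootrank;Bacteria;domain;Cyanobacteria;phylum",
         name = "Cyanobacteria", rank = "phylum", counts = 3),
    list(lineage = paste0("Root;rootrank;Bacteria;domain;Cyanobacteria;",
                          "phylum;Chloroplast;class"),
         name = "Chloroplast", rank = "class", counts = 3)
  ))
  path <- write_rdp_file(rows)
  ct <- read_rdp_hierarchy(path)
  expect_false(any(grepl("Chloroplast", ct$lineage)))
  # Cyanobacteria's residual is zero once its chloroplasts are removed
  expect_false("Cyanobacteria" %in% ct$name)
  smry <- classification_summary(ct)
  expect_equal(smry$filtered, 3)
  expect_equal(smry$retained + smry$dropped_above_phylum + smry$filtered,
               smry$total)
})

test_that("an all-zero sample column is retained without error", {
  counts <- list(c(10, 0), c(10, 0), c(8, 0), c(6, 0), c(5, 0))
  path <- write_rdp_file(toy_rdp_rows(counts), samples = c("s1", "s2"))
  ct <- read_rdp_hierarchy(path)
  expect_true("s2" %in% names(ct))
  expect_equal(sum(ct$s2), 0)
})

test_that("species counts collapse upward into genus by default", {
  rows <- c(toy_rdp_rows(), list(
    list(lineage = paste0("Root;rootrank;Bacteria;domain;Proteobacteria;",
                          "phylum;Gammaproteobacteria;class;Escherichia;",
                          "genus;Escherichia coli;species"),
         name = "Escherichia coli", rank = "species", counts = 4)
  ))
  path <- write_rdp_file(rows)
  ct <- read_rdp_hierarchy(path)
  expect_equal(ct$s1[ct$name == "Escherichia"], 5)
  expect_false("species" %in% ct$rank)
  # species retention splits the genus into its residual and the species
  ct_sp <- read_rdp_hierarchy(path, lowest_rank = "species")
  expect_equal(ct_sp$s1[ct_sp$name == "Escherichia coli"], 4)
  expect_equal(ct_sp$s1[ct_sp$name == "Escherichia"], 1)
})

test_that("malformed hierarchies and unknown ranks are rejected", {
  rows <- toy_rdp_rows(counts = list(10, 10, 8, 9, 5))  # class > phylum
  expect_error(read_rdp_hierarchy(write_rdp_file(rows)),
               "Proteobacteria")
  rows <- toy_rdp_rows()
  rows[[5]]$rank <- "subgenus"
  rows[[5]]$lineage <- sub("Escherichia;genus", "Escherichia;subgenus",
                           rows[[5]]$lineage)
  expect_error(read_rdp_hierarchy(write_rdp_file(rows)), "rank")
})

test_that("count conservation holds on generated fixtures", {
  db <- make_refdb(seed = 5, n_phyla = 3, genera_per_phylum = 4)
  for (seed in 1:3) {
    fx <- make_rdp_fixture(db, n_samples = 2, seed = seed,
                           unmapped_fraction = 0.15,
                           filtered_fraction = 0.1)
    ct <- read_rdp_hierarchy(fx$rdp_path)
    smry <- classification_summary(ct)
    expect_equal(smry$retained + smry$dropped_above_phylum + smry$filtered,
                 smry$total)
    expect_equal(smry$total, as.numeric(fx$ground_truth$total))
    expect_equal(smry$filtered, as.numeric(fx$ground_truth$filtered))
    # decomposed counts match the construction exactly
    gt <- fx$ground_truth$lowest_counts
    got <- dplyr::arrange(ct, name)
    expect_equal(got$rank, gt$rank)
    expect_equal(got$name, gt$name)
    expect_equal(as.matrix(got[, c("sample1", "sample2")]),
                 as.matrix(gt[, c("sample1", "sample2")]),
                 ignore_attr = TRUE)
  }
})

test_that("OTU/taxonomy tables pool at the lowest filled rank", {
  otu <- tibble::tibble(
    asv = c("a1", "a2", "a3", "a4", "a5"),
    s1 = c(5, 3, 2, 7, 4)
  )
  tax <- tibble::tibble(
    asv = c("a1", "a2", "a3", "a4", "a5"),
    domain = "Bacteria",
    phylum = c("Bacteroidota", "Bacteroidota", "Bacteroidota",
               "Firmicutes", ""),
    class = c("", "", "", "Bacilli", ""),
    order = "", family = "",
    genus = c("Muribaculum", "Muribaculum", "Muribaculum", "", ""),
    species = ""
  )
  expect_message(ct <- taxa_counts_from_tables(otu, tax), "no assignment")
  # three ASVs pooled into one genus row
  expect_equal(ct$s1[ct$name == "Muribaculum"], 10)
  expect_equal(ct$rank[ct$name == "Muribaculum"], "genus")
  # deepest filled rank wins for the partially classified ASV
  expect_equal(ct$rank[ct$name == "Bacilli"], "class")
  # fully unassigned ASV dropped and tallied
  expect_equal(as.numeric(attr(ct, "unassigned")), 4)
  expect_error(
    taxa_counts_from_tables(otu, dplyr::mutate(tax, asv = paste0("x", asv))),
    "identifier")
  expect_error(
    taxa_counts_from_tables(dplyr::mutate(otu, s1 = -s1), tax),
    "non-negative")
})

test_that("pooling is idempotent and the TSV round trip is exact", {
  db <- make_refdb(seed = 2)
  fx <- make_rdp_fixture(db, n_samples = 2, seed = 3)
  ct <- taxa_counts_from_tables(fx$otu_counts, fx$taxonomy)
  # re-pool: feed the pooled table back through as one-"OTU"-per-row input
  again <- taxa_counts_from_tables(
    dplyr::select(ct, id = "name", dplyr::all_of(c("sample1", "sample2"))),
    tibble::tibble(id = ct$name, phylum = "", genus = ct$name)
  )
  expect_equal(dplyr::select(again, "rank", "name",
                             dplyr::all_of(c("sample1", "sample2"))),
               dplyr::select(ct, "rank", "name",
                             dplyr::all_of(c("sample1", "sample2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(ct, path)
  expect_equal(read_classification(path),
               ct, ignore_attr = TRUE)
})
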