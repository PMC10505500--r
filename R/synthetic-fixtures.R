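# Deterministic generators of toy reference databases and classification
# inputs with ground truth known by construction. The fixtures are clearly
# synthetic (Phylum_A, Genus_A1, ...) and encode no real taxon.

#' Generate a synthetic reference proteome database
#'
#' Genus compositions are Dirichlet(1)-random amino acid frequencies
#' scaled to a mean protein length of 300 residues, which spans a
#' realistic range of protein carbon oxidation state; phylum entries are
#' the unweighted means of their member genera, mirroring
#' [build_reference_proteomes()]. Reproducible for a given seed.
#'
#' @param seed Integer RNG seed.
#' @param n_phyla,genera_per_phylum Database dimensions (each >= 1).
#' @return A reference database tibble as in [read_refdb()], with an
#'   additional attribute `genus_phylum` (tibble `genus`, `phylum`) used
#'   by the fixture writers.
#' @export
make_refdb <- function(seed, n_phyla = 2, genera_per_phylum = 3) {
  stopifnot(n_phyla >= 1, genera_per_phylum >= 1)
  withr::with_seed(seed, {
    phyla <- paste0("Phylum_", LETTERS[seq_len(n_phyla)])
    rows <- purrr::map_dfr(seq_len(n_phyla), function(p) {
      purrr::map_dfr(seq_len(genera_per_phylum), function(g) {
        x <- stats::rgamma(20, shape = 1)
        comp <- 300 * x / sum(x)
        out <- aa_row(comp)
        dplyr::bind_cols(
          tibble::tibble(rank = "genus",
                         name = paste0("Genus_", LETTERS[p], g),
                         n_genomes = 1L, n_proteins = 1000),
          out
        )
      })
    })
    phylum_rows <- purrr::map_dfr(seq_len(n_phyla), function(p) {
      members <- rows[((p - 1) * genera_per_phylum + 1):(p * genera_per_phylum), ]
      comp <- colMeans(as.matrix(members[, aa_codes()]))
      dplyr::bind_cols(
        tibble::tibble(rank = "phylum", name = phyla[p],
                       n_genomes = as.integer(genera_per_phylum),
                       n_proteins = sum(members$n_proteins)),
        aa_row(comp)
      )
    })
    db <- dplyr::bind_rows(phylum_rows, rows)
    attr(db, "genus_phylum") <- tibble::tibble(
      genus = rows$name,
      phylum = rep(phyla, each = genera_per_phylum)
    )
    db
  })
}

#' Generate an RDP-style fixture with known ground truth
#'
#' Writes a cumulative RDP-style hierarchy file (plus matching OTU/ASV
#' count and taxonomy tables) whose lowest-level decomposition, filter
#' losses, unmapped percentage and per-sample community metrics are all
#' recorded as ground truth by construction — the ground-truth metrics
#' come from an independent weighted-mean computation inside the
#' generator, not from running the ingestion/mapping pipeline under test.
#'
#' Genus abundance weights are log-normal (a realistic skewed rank
#' abundance); `unmapped_fraction` of the retained counts is assigned to
#' a novel genus absent from the reference database, and
#' `filtered_fraction` to a chloroplast lineage that ingestion removes.
#'
#' @param refdb A database from [make_refdb()].
#' @param n_samples Number of samples.
#' @param seed Integer RNG seed.
#' @param unmapped_fraction,filtered_fraction Target fractions in
#'   \[0, 1) of retained (resp. classified) counts; realized fractions are
#'   exact integers and are recorded in the ground truth.
#' @return A list with `rdp_path` and `rdp_lines` (the hierarchy file),
#'   `otu_counts` and `taxonomy` tibbles, `refdb`, and `ground_truth`:
#'   `lowest_counts` (expected classification table), `unmapped_percent`
#'   (overall), `unmapped_by_sample`, `filtered`, `total`, and `metrics`
#'   (expected per-sample Zc/nO2/nH2O).
#' @export
make_rdp_fixture <- function(refdb, n_samples = 3, seed = 1,
                             unmapped_fraction = 0, filtered_fraction = 0) {
  stopifnot(unmapped_fraction >= 0, unmapped_fraction < 1,
            filtered_fraction >= 0, filtered_fraction < 1)
  gp <- attr(refdb, "genus_phylum")
  if (is.null(gp)) stop("refdb must come from make_refdb()")
  samples <- paste0("sample", seq_len(n_samples))

  withr::with_seed(seed, {
    n_gen <- nrow(gp)
    counts <- matrix(
      pmax(1, round(stats::rlnorm(n_gen * n_samples,
                                  meanlog = log(100), sdlog = 1))),
      nrow = n_gen, ncol = n_samples,
      dimnames = list(gp$genus, samples)
    )
    mapped_total <- colSums(counts)

    unmapped <- if (unmapped_fraction > 0) {
      round(unmapped_fraction / (1 - unmapped_fraction) * mapped_total)
    } else {
      stats::setNames(rep(0, n_samples), samples)
    }
    retained_total <- mapped_total + unmapped
    filtered <- if (filtered_fraction > 0) {
      round(filtered_fraction / (1 - filtered_fraction) * retained_total)
    } else {
      stats::setNames(rep(0, n_samples), samples)
    }

    # --- RDP hierarchy lines (cumulative counts) ---
    fmt <- function(x) paste(x, collapse = "\t")
    phyla <- unique(gp$phylum)
    phylum_counts <- rowsum(counts, gp$phylum)[phyla, , drop = FALSE]
    novel_phylum <- phyla[1]
    lines <- character(0)
    taxid <- 0
    add <- function(lineage, name, rank, cts) {
      taxid <<- taxid + 1
      c(lines, fmt(c(taxid, lineage, name, rank, cts)))
    }
    root_counts <- colSums(phylum_counts) + unmapped + filtered
    lines <- add("Root;rootrank", "Root", "rootrank", root_counts)
    dom_lin <- "Root;rootrank;Bacteria;domain"
    lines <- add(dom_lin, "Bacteria", "domain", root_counts)
    for (p in phyla) {
      pc <- phylum_counts[p, ]
      if (p == novel_phylum) pc <- pc + unmapped
      p_lin <- paste0(dom_lin, ";", p, ";phylum")
      lines <- add(p_lin, p, "phylum", pc)
      for (g in gp$genus[gp$phylum == p]) {
        g_lin <- paste0(p_lin, ";", g, ";genus")
        lines <- add(g_lin, g, "genus", counts[g, ])
      }
      if (p == novel_phylum && any(unmapped > 0)) {
        g_lin <- paste0(p_lin, ";Genus_novel;genus")
        lines <- add(g_lin, "Genus_novel", "genus", unmapped)
      }
    }
    if (any(filtered > 0)) {
      cy_lin <- paste0(dom_lin, ";Cyanobacteria;phylum")
      lines <- add(cy_lin, "Cyanobacteria", "phylum", filtered)
      lines <- add(paste0(cy_lin, ";Chloroplast;class"), "Chloroplast",
                   "class", filtered)
    }
    header <- fmt(c("taxid", "lineage", "name", "rank", samples))
    rdp_lines <- c(header, lines)
    rdp_path <- tempfile(fileext = ".tsv")
    writeLines(rdp_lines, rdp_path)

    # --- OTU/ASV tables: split each genus count over 1-2 ASVs ---
    asv_rows <- purrr::map_dfr(seq_len(n_gen), function(i) {
      n_asv <- 1 + (i %% 2)
      first <- floor(counts[i, ] / n_asv)
      parts <- if (n_asv == 1) list(counts[i, ]) else
        list(first, counts[i, ] - first)
      purrr::map_dfr(seq_len(n_asv), function(k) {
        dplyr::bind_cols(
          tibble::tibble(asv = sprintf("ASV_%03d_%d", i, k),
                         genus = gp$genus[i], phylum = gp$phylum[i]),
          tibble::as_tibble(as.list(stats::setNames(parts[[k]], samples)))
        )
      })
    })
    if (any(unmapped > 0)) {
      asv_rows <- dplyr::bind_rows(asv_rows, dplyr::bind_cols(
        tibble::tibble(asv = "ASV_novel_1", genus = "Genus_novel",
                       phylum = novel_phylum),
        tibble::as_tibble(as.list(stats::setNames(unmapped, samples)))
      ))
    }
    otu_counts <- dplyr::select(asv_rows, "asv", dplyr::all_of(samples))
    taxonomy <- tibble::tibble(
      asv = asv_rows$asv,
      domain = "Bacteria",
      phylum = asv_rows$phylum,
      class = "", order = "", family = "",
      genus = asv_rows$genus,
      species = ""
    )

    # --- ground truth, by construction ---
    lowest <- tibble::tibble(
      rank = "genus",
      name = c(gp$genus, if (any(unmapped > 0)) "Genus_novel"),
      lineage = paste("Bacteria",
                      c(gp$phylum, if (any(unmapped > 0)) novel_phylum),
                      c(gp$genus, if (any(unmapped > 0)) "Genus_novel"),
                      sep = ";")
    )
    low_counts <- rbind(counts, if (any(unmapped > 0)) unmapped)
    lowest <- dplyr::bind_cols(lowest, tibble::as_tibble(low_counts)) |>
      dplyr::arrange(.data$name)

    unmapped_percent <- 100 * sum(unmapped) / sum(retained_total)
    unmapped_by_sample <- 100 * unmapped / retained_total

    # independent weighted-mean community composition per sample
    ref_gen <- refdb[refdb$rank == "genus", ]
    ref_gen <- ref_gen[match(gp$genus, ref_gen$name), ]
    comp_mat <- as.matrix(ref_gen[, aa_codes()])
    comm <- t(vapply(samples, function(s) {
      w <- counts[, s] / sum(counts[, s])
      colSums(comp_mat * w)
    }, numeric(20)))
    colnames(comm) <- aa_codes()
    comm_aa <- tibble::as_tibble(comm)
    comm_aa$chains <- 1
    gt_metrics <- dplyr::bind_cols(
      tibble::tibble(sample = samples),
      calc_metrics(comm_aa, metrics = c("Zc", "nO2", "nH2O"))
    )

    list(
      rdp_path = rdp_path,
      rdp_lines = rdp_lines,
      otu_counts = otu_counts,
      taxonomy = taxonomy,
      refdb = refdb,
      ground_truth = list(
        lowest_counts = lowest,
        unmapped_percent = unmapped_percent,
        unmapped_by_sample = unmapped_by_sample,
        filtered = filtered,
        total = root_counts,
        metrics = gt_metrics
      )
    )
  })
}

#' Write a fixture bundle to a directory
#'
#' Writes the reference database, RDP hierarchy, OTU/ASV count and
#' taxonomy tables, and the ground-truth tables of a
#' [make_rdp_fixture()] bundle as plain TSV files.
#'
#' @param bundle A list from [make_rdp_fixture()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_refdb(bundle$refdb, file.path(dir, "refdb.tsv"))
  writeLines(bundle$rdp_lines, file.path(dir, "rdp.tsv"))
  readr::write_tsv(bundle$otu_counts, file.path(dir, "otu_counts.tsv"))
  readr::write_tsv(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(bundle$ground_truth$lowest_counts,
                   file.path(dir, "ground_truth_counts.tsv"))
  readr::write_tsv(bundle$ground_truth$metrics,
                   file.path(dir, "ground_truth_metrics.tsv"))
  invisible(dir)
}
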