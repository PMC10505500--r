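#' Total amino acid composition of a protein FASTA file
#'
#' Reads a protein FASTA file (standard one-letter codes; strict alphabet,
#' so ambiguity codes like B, Z, X or U are rejected rather than silently
#' dropped) and sums residue counts over all records.
#'
#' @param path Path to a protein FASTA file with at least one record.
#' @return A one-row tibble with the 20 amino acid count columns,
#'   `chains` = number of records, and `n_proteins` (same value).
#' @export
count_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("FASTA file has no records: ", path)
  cst <- aa_constants()
  cst <- cst[!cst$code3 %in% c("Nterm", "Cterm"), ]
  freq <- Biostrings::alphabetFrequency(seqs)
  standard <- cst$code1
  other <- setdiff(colnames(freq), standard)
  bad <- freq[, other, drop = FALSE]
  if (any(bad > 0)) {
    ij <- which(bad > 0, arr.ind = TRUE)[1, ]
    stop("non-standard residue \"", other[ij[2]], "\" in record \"",
         names(seqs)[ij[1]], "\" of ", path)
  }
  totals <- colSums(freq[, standard, drop = FALSE])
  out <- stats::setNames(as.list(as.numeric(totals)),
                         cst$code3[match(standard, cst$code1)])
  out <- out[aa_codes()]
  out$chains <- length(seqs)
  out$n_proteins <- length(seqs)
  tibble::as_tibble(out)
}

#' Parse a GTDB-style taxonomy string
#'
#' Splits a string like
#' `"d__Bacteria;p__Bacteroidota;c__Bacteroidia;...;g__Muribaculum;s__"`
#' into a (rank, name) tibble. Empty rank fields (a bare prefix such as
#' `s__`) are skipped, not treated as names.
#'
#' @param taxonomy A single taxonomy string.
#' @return A tibble with columns `rank` and `name`, domain downward.
#' @export
parse_gtdb_taxonomy <- function(taxonomy) {
  prefixes <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")
  parts <- trimws(strsplit(taxonomy, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop("empty taxonomy string")
  pre <- sub("__.*$", "", parts)
  if (!all(grepl("^[a-z]__", parts)) || !all(pre %in% names(prefixes))) {
    bad <- parts[!grepl("^[a-z]__", parts) | !pre %in% names(prefixes)]
    stop("unknown rank prefix in taxonomy field(s): ",
         paste(bad, collapse = ", "))
  }
  name <- sub("^[a-z]__", "", parts)
  out <- tibble::tibble(rank = unname(prefixes[pre]), name = name)
  out <- out[nzchar(out$name), , drop = FALSE]
  if (nrow(out) == 0) stop("taxonomy string has no named ranks: ", taxonomy)
  out
}

#' Build a reference proteome database from genomes
#'
#' For each genome, the per-genome composition is the mean per-protein
#' amino acid composition (total residue counts divided by the number of
#' proteins). For every taxon at every rank named in a genome's lineage,
#' the reference composition is the mean of its member genomes'
#' per-genome compositions — unweighted by default, so heavily sequenced
#' species do not dominate a genus; `weight = "protein"` weights genomes
#' by their protein counts instead.
#'
#' @param genomes Data frame with columns `genome_id`, `fasta` (path to a
#'   protein FASTA file) and `taxonomy` (GTDB-style string, see
#'   [parse_gtdb_taxonomy()]).
#' @param weight `"genome"` (unweighted mean across genomes, default) or
#'   `"protein"` (protein-count-weighted mean).
#' @param source Free-text source label stored in the db metadata.
#' @param version Free-text version stored in the db metadata.
#' @return A reference database tibble with columns `rank`, `name`,
#'   `n_genomes`, `n_proteins`, then the 20 amino acid columns
#'   (per-protein mean counts; one implicit chain per protein). Attributes
#'   `source` and `version` carry the metadata.
#' @export
build_reference_proteomes <- function(genomes, weight = c("genome", "protein"),
                                      source = "local", version = "") {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1)
  need <- c("genome_id", "fasta", "taxonomy")
  miss <- setdiff(need, names(genomes))
  if (length(miss) > 0) {
    stop("genomes table is missing column(s): ", paste(miss, collapse = ", "))
  }

  per_genome <- purrr::map(seq_len(nrow(genomes)), function(i) {
    tot <- count_fasta_proteins(genomes$fasta[i])
    n_prot <- tot$n_proteins
    if (n_prot == 0 || sum(as.matrix(tot[, aa_codes()])) == 0) {
      stop("genome ", genomes$genome_id[i], " has no proteins")
    }
    comp <- as.numeric(tot[1, aa_codes()]) / n_prot
    lineage <- parse_gtdb_taxonomy(genomes$taxonomy[i])
    list(comp = comp, n_proteins = n_prot, lineage = lineage)
  })

  rows <- purrr::map_dfr(seq_along(per_genome), function(i) {
    g <- per_genome[[i]]
    dplyr::mutate(g$lineage, genome = i)
  })
  entries <- rows |>
    dplyr::group_by(.data$rank, .data$name) |>
    dplyr::summarise(members = list(.data$genome), .groups = "drop")

  comp_mat <- do.call(rbind, purrr::map(per_genome, "comp"))
  n_prot <- vapply(per_genome, `[[`, numeric(1), "n_proteins")

  aa <- purrr::map_dfr(entries$members, function(m) {
    w <- if (weight == "genome") rep(1, length(m)) else n_prot[m]
    mean_comp <- colSums(comp_mat[m, , drop = FALSE] * w) / sum(w)
    aa_row(mean_comp)
  })
  out <- tibble::tibble(
    rank = entries$rank,
    name = entries$name,
    n_genomes = vapply(entries$members, length, integer(1)),
    n_proteins = vapply(entries$members, function(m) sum(n_prot[m]),
                        numeric(1))
  )
  out <- dplyr::bind_cols(out, aa) |>
    dplyr::arrange(rank_depth(.data$rank), .data$name)
  attr(out, "source") <- source
  attr(out, "version") <- version
  out
}

refdb_columns <- function() {
  c("rank", "name", "n_genomes", "n_proteins", aa_codes())
}

#' Write / read a reference proteome database as TSV
#'
#' The on-disk layout is one header line and the columns `rank`, `name`,
#' `n_genomes`, `n_proteins`, then the 20 amino acid columns `Ala` ...
#' `Val` (alphabetical by three-letter code), UTF-8 encoded. The round
#' trip is lossless; unknown or missing columns and duplicate
#' (rank, name) keys are rejected.
#'
#' @param db Reference database tibble (see [build_reference_proteomes()]).
#' @param path File path.
#' @return `write_refdb()` returns `db` invisibly; `read_refdb()` returns
#'   the tibble.
#' @export
write_refdb <- function(db, path) {
  miss <- setdiff(refdb_columns(), names(db))
  if (length(miss) > 0) {
    stop("reference database is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  readr::write_tsv(db[, refdb_columns()], path)
  invisible(db)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(path) {
  db <- readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_character(),
    name = readr::col_character(),
    .default = readr::col_double()
  ))
  miss <- setdiff(refdb_columns(), names(db))
  if (length(miss) > 0) {
    stop("reference database file is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(db), refdb_columns())
  if (length(extra) > 0) {
    stop("reference database file has unknown column(s): ",
         paste(extra, collapse = ", "))
  }
  key <- paste(db$rank, db$name)
  if (anyDuplicated(key)) {
    stop("duplicate (rank, name) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(db$n_genomes < 1)) stop("n_genomes must be >= 1")
  aa_count_matrix(db)
  db
}
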