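#' @importFrom rlang .data
NULL

# Default nonprokaryotic lineage filter, user-extensible at call time
default_filter_terms <- function() {
  c("Chloroplast", "Mitochondria", "Eukaryota")
}

rank_depth <- function(rank) {
  match(rank, c("rootrank", tax_ranks()))
}

# Split an RDP lineage string ("Root;rootrank;Bacteria;domain;...") into
# a list(names=..., ranks=...); validates alternation and descending ranks.
parse_rdp_lineage <- function(lineage) {
  parts <- strsplit(sub(";$", "", lineage), ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) %% 2 != 0) {
      stop("malformed lineage (odd number of fields): ",
           paste(p, collapse = ";"))
    }
    nm <- p[seq(1, length(p), by = 2)]
    rk <- p[seq(2, length(p), by = 2)]
    d <- rank_depth(rk)
    if (anyNA(d)) {
      stop("unknown rank label(s) in lineage: ",
           paste(rk[is.na(d)], collapse = ", "))
    }
    if (any(diff(d) <= 0)) {
      stop("lineage ranks do not strictly descend: ",
           paste(rk, collapse = ";"))
    }
    list(names = nm, ranks = rk)
  })
}

#' Read an RDP Classifier hierarchical count file
#'
#' Reads the tab-separated hierarchical output of the RDP Classifier
#' (columns `taxid`, `lineage`, `name`, `rank`, then one count column per
#' sample; counts are cumulative down the taxonomy; `lineage` is a
#' semicolon-delimited alternating name/rank path ending at the row's own
#' node). Counts are decomposed so each read is counted once, at the
#' lowest (deepest) retained rank: the lowest-level count of a node is its
#' cumulative count minus the cumulative counts of its retained direct
#' children. Domain- and root-level residuals are dropped, as are nodes
#' whose lineage contains any of `filter_terms` (nonprokaryotic
#' classifications such as chloroplasts). Ranks deeper than `lowest_rank`
#' are not decomposed, so e.g. species counts collapse upward into genus
#' by default; pass `lowest_rank = "species"` to retain species rows (for
#' GTDB-style references that include species).
#'
#' @param path Path to the RDP hierarchical TSV file.
#' @param filter_terms Lineage names whose subtrees are removed; matching
#'   is exact and case-sensitive after whitespace trimming.
#' @param lowest_rank Deepest rank to retain, one of `"species"`,
#'   `"genus"` (default), `"family"`, `"order"`, `"class"`.
#' @return A classification table: a tibble with columns `rank`, `name`,
#'   `lineage` (semicolon-joined names, domain downward) and one numeric
#'   column per sample, holding lowest-level counts. Rows that are zero in
#'   every sample are dropped. Attributes `total`, `dropped_above_phylum`
#'   and `filtered` record the per-sample count bookkeeping (see
#'   [classification_summary()]).
#' @export
read_rdp_hierarchy <- function(path,
                               filter_terms = default_filter_terms(),
                               lowest_rank = "genus") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    taxid = readr::col_character(),
    lineage = readr::col_character(),
    name = readr::col_character(),
    rank = readr::col_character(),
    .default = readr::col_double()
  ))
  need <- c("taxid", "lineage", "name", "rank")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("RDP file is missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- setdiff(names(raw), need)
  if (length(samples) == 0) stop("RDP file has no sample count columns")
  counts <- as.matrix(raw[, samples, drop = FALSE])
  if (any(is.na(counts))) stop("RDP file has missing counts")
  if (any(counts < 0)) stop("RDP file has negative counts")
  d <- rank_depth(raw$rank)
  if (anyNA(d)) {
    stop("unknown rank label(s): ",
         paste(unique(raw$rank[is.na(d)]), collapse = ", "))
  }
  lin <- parse_rdp_lineage(raw$lineage)
  # the lineage must end at the row's own node
  ok <- vapply(seq_along(lin), function(i) {
    nm <- lin[[i]]$names
    rk <- lin[[i]]$ranks
    nm[length(nm)] == trimws(raw$name[i]) &&
      rk[length(rk)] == raw$rank[i]
  }, logical(1))
  if (any(!ok)) {
    stop("lineage does not end at the row's own name/rank for taxid(s): ",
         paste(raw$taxid[!ok], collapse = ", "))
  }

  path_key <- vapply(lin, function(x) paste(x$names, collapse = ";"),
                     character(1))
  if (anyDuplicated(path_key)) {
    stop("duplicated taxon path(s): ",
         paste(unique(path_key[duplicated(path_key)]), collapse = "; "))
  }
  parent_key <- vapply(lin, function(x) {
    paste(x$names[-length(x$names)], collapse = ";")
  }, character(1))

  if (!lowest_rank %in% c("species", "genus", "family", "order", "class")) {
    stop("lowest_rank must be one of species, genus, family, order, class")
  }
  keep_ranks <- tax_ranks()[seq(match("phylum", tax_ranks()),
                                match(lowest_rank, tax_ranks()))]

  filtered_node <- vapply(lin, function(x) {
    any(x$names %in% filter_terms)
  }, logical(1))

  # maximal filtered nodes: filtered, with no filtered ancestor; their
  # whole subtrees are removed and tallied once, at the maximal node
  filtered_top <- filtered_node & !vapply(lin, function(x) {
    any(x$names[-length(x$names)] %in% filter_terms)
  }, logical(1))
  filtered_counts <- colSums(counts[filtered_top, , drop = FALSE])

  # effective cumulative counts: filtered subtrees removed from every
  # ancestor, so the decomposition below never re-counts them
  eff <- counts
  for (j in which(filtered_top)) {
    anc <- startsWith(path_key[j], paste0(path_key, ";"))
    eff[anc, ] <- sweep(eff[anc, , drop = FALSE], 2, counts[j, ], "-")
  }

  # residual (lowest-level) count = effective count minus the effective
  # counts of direct children that are counted elsewhere: decomposed ranks
  # (phylum..lowest_rank) and domains. Children deeper than lowest_rank
  # are not subtracted, so their counts collapse upward into the parent.
  decomposed <- raw$rank %in% keep_ranks
  subtracts <- (decomposed | raw$rank == "domain") & !filtered_node
  child_of <- split(seq_len(nrow(raw)), parent_key)
  residual <- eff
  for (i in seq_len(nrow(raw))) {
    kids <- child_of[[path_key[i]]]
    kids <- kids[subtracts[kids]]
    if (length(kids) > 0) {
      residual[i, ] <- eff[i, ] - colSums(eff[kids, , drop = FALSE])
    }
  }
  bad <- which(residual < -1e-8 & !filtered_node)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(residual))[1]
    stop("malformed hierarchy: child counts exceed parent count at node \"",
         raw$name[i], "\"")
  }

  above <- raw$rank %in% c("rootrank", "domain")
  dropped_above <- colSums(residual[above & !filtered_node, , drop = FALSE])

  keep <- decomposed & !filtered_node
  out <- tibble::tibble(
    rank = raw$rank[keep],
    name = trimws(raw$name[keep]),
    lineage = vapply(lin[keep], function(x) {
      paste(x$names[x$ranks != "rootrank"], collapse = ";")
    }, character(1))
  )
  res <- residual[keep, , drop = FALSE]
  out <- dplyr::bind_cols(out, tibble::as_tibble(res))
  # drop rows with zero counts in every sample
  out <- out[rowSums(res) > 0, , drop = FALSE]
  out <- dplyr::arrange(out, rank_depth(.data$rank), .data$name)

  total <- if (any(raw$rank == "rootrank")) {
    colSums(counts[raw$rank == "rootrank", , drop = FALSE])
  } else {
    colSums(counts[raw$rank == "domain", , drop = FALSE])
  }
  attr(out, "total") <- total
  attr(out, "dropped_above_phylum") <- dropped_above
  attr(out, "filtered") <- filtered_counts
  out
}

#' Per-sample count bookkeeping of a classification table
#'
#' @param ct A classification table from [read_rdp_hierarchy()] or
#'   [taxa_counts_from_tables()].
#' @return A tibble with one row per sample: retained lowest-level count,
#'   counts dropped above phylum level, filtered (nonprokaryotic) counts,
#'   unassigned counts (OTU path), and the classified total.
#' @export
classification_summary <- function(ct) {
  samples <- sample_columns(ct)
  retained <- colSums(as.matrix(ct[, samples, drop = FALSE]))
  get_attr <- function(nm) {
    v <- attr(ct, nm)
    if (is.null(v)) stats::setNames(rep(0, length(samples)), samples) else v
  }
  tibble::tibble(
    sample = samples,
    retained = as.numeric(retained),
    dropped_above_phylum = as.numeric(get_attr("dropped_above_phylum")[samples]),
    filtered = as.numeric(get_attr("filtered")[samples]),
    unassigned = as.numeric(get_attr("unassigned")[samples]),
    total = as.numeric(get_attr("total")[samples])
  )
}

# Sample (count) columns of a classification table
sample_columns <- function(ct) {
  setdiff(names(ct), c("rank", "name", "lineage"))
}

#' Lowest-level taxon counts from OTU/ASV count and taxonomy tables
#'
#' Combines a per-OTU (or per-ASV) count table with a per-OTU taxonomy
#' matrix, as exported from amplicon pipelines. Each OTU is classified at
#' its deepest non-empty rank between phylum and `lowest_rank`; OTUs
#' sharing that (rank, name) are pooled by summing counts. OTUs with no
#' assignment at phylum or below are dropped and tallied in the
#' `unassigned` attribute.
#'
#' @param otu_counts Data frame whose first column is the OTU/ASV
#'   identifier, followed by one numeric count column per sample.
#' @param taxonomy Data frame whose first column is the OTU/ASV identifier
#'   followed by rank columns among `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`; empty strings or `NA` mean unassigned.
#' @param lowest_rank Deepest rank to use (default `"genus"`).
#' @param filter_terms Lineage names whose OTUs are removed entirely
#'   (default chloroplast/mitochondria/eukaryote labels).
#' @return A classification table tibble (`rank`, `name`, `lineage`, one
#'   column per sample) with bookkeeping attributes as in
#'   [read_rdp_hierarchy()].
#' @export
taxa_counts_from_tables <- function(otu_counts, taxonomy,
                                    lowest_rank = "genus",
                                    filter_terms = default_filter_terms()) {
  stopifnot(is.data.frame(otu_counts), is.data.frame(taxonomy))
  id_col <- names(otu_counts)[1]
  ids <- as.character(otu_counts[[id_col]])
  tax_ids <- as.character(taxonomy[[1]])
  if (length(intersect(ids, tax_ids)) == 0) {
    stop("count and taxonomy tables share no OTU/ASV identifiers")
  }
  miss <- setdiff(ids, tax_ids)
  if (length(miss) > 0) {
    stop("OTU/ASV identifier(s) missing from the taxonomy table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  samples <- names(otu_counts)[-1]
  counts <- as.matrix(otu_counts[, samples, drop = FALSE])
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")

  rank_cols <- intersect(tax_ranks(), names(taxonomy))
  if (length(intersect(rank_cols, tax_ranks()[-1])) == 0) {
    stop("taxonomy table has no rank columns at phylum level or below")
  }
  tax <- taxonomy[match(ids, tax_ids), , drop = FALSE]
  usable <- intersect(
    tax_ranks()[seq(match("phylum", tax_ranks()),
                    match(lowest_rank, tax_ranks()))],
    rank_cols
  )

  per_otu <- purrr::map(seq_along(ids), function(i) {
    vals <- vapply(rank_cols, function(rc) {
      v <- tax[[rc]][i]
      if (is.na(v)) "" else trimws(as.character(v))
    }, character(1))
    lineage_names <- vals[vals != ""]
    filled <- names(vals)[vals != "" & names(vals) %in% usable]
    if (any(lineage_names %in% filter_terms)) {
      return(list(status = "filtered"))
    }
    if (length(filled) == 0) {
      return(list(status = "unassigned"))
    }
    deepest <- filled[which.max(rank_depth(filled))]
    keep_lin <- vals[vals != "" &
                       rank_depth(names(vals)) <= rank_depth(deepest)]
    list(status = "ok", rank = deepest, name = vals[[deepest]],
         lineage = paste(keep_lin, collapse = ";"))
  })
  status <- vapply(per_otu, `[[`, character(1), "status")

  unassigned <- colSums(counts[status == "unassigned", , drop = FALSE])
  filtered <- colSums(counts[status == "filtered", , drop = FALSE])
  if (any(unassigned > 0)) {
    message("dropped ", sum(status == "unassigned"),
            " OTU/ASV(s) with no assignment at phylum or below (",
            sum(unassigned), " counts)")
  }

  ok <- which(status == "ok")
  if (length(ok) == 0) stop("no OTU/ASV has a usable classification")
  keyed <- tibble::tibble(
    rank = vapply(per_otu[ok], `[[`, character(1), "rank"),
    name = vapply(per_otu[ok], `[[`, character(1), "name"),
    lineage = vapply(per_otu[ok], `[[`, character(1), "lineage")
  )
  keyed <- dplyr::bind_cols(keyed, tibble::as_tibble(counts[ok, , drop = FALSE]))
  out <- keyed |>
    dplyr::group_by(.data$rank, .data$name) |>
    dplyr::summarise(
      lineage = .data$lineage[1],
      dplyr::across(dplyr::all_of(samples), sum),
      .groups = "drop"
    ) |>
    dplyr::relocate("rank", "name", "lineage") |>
    dplyr::arrange(rank_depth(.data$rank), .data$name)

  attr(out, "total") <- colSums(counts)
  attr(out, "unassigned") <- unassigned
  attr(out, "filtered") <- filtered
  out
}

#' Write / read a classification table as TSV
#'
#' Lossless round trip of the tibble form (`rank`, `name`, `lineage`,
#' sample columns). Bookkeeping attributes are not persisted.
#'
#' @param ct Classification table tibble.
#' @param path File path.
#' @return `write_classification()` returns `ct` invisibly;
#'   `read_classification()` returns the tibble.
#' @export
write_classification <- function(ct, path) {
  stopifnot(all(c("rank", "name", "lineage") %in% names(ct)))
  readr::write_tsv(ct[, c("rank", "name", "lineage", sample_columns(ct))],
                   path)
  invisible(ct)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_character(),
    name = readr::col_character(),
    lineage = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!all(c("rank", "name", "lineage") %in% names(out))) {
    stop("not a classification table: needs rank, name, lineage columns")
  }
  out
}
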