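#' Default manual mapping ledger
#'
#' A small starter set of manual mapping rules reconciling RDP-style
#' classifier names with NCBI-style reference names (e.g. the combined
#' "Escherichia/Shigella" genus). The ledger is a tibble with columns
#' `source_rank`, `source_name`, `target_rank`, `target_name`, `note`;
#' rules may change rank (e.g. map an unplaced genus to a family-level
#' reference). Users extend or replace it at call time, or load one from
#' TSV with [read_ledger()].
#'
#' @return The ledger tibble.
#' @export
default_ledger <- function() {
  path <- system.file("extdata", "default_mapping_ledger.tsv",
                      package = "commchem", mustWork = TRUE)
  read_ledger(path)
}

#' @rdname default_ledger
#' @param path Path to a ledger TSV with the five columns above.
#' @export
read_ledger <- function(path) {
  led <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  need <- c("source_rank", "source_name", "target_rank", "target_name",
            "note")
  miss <- setdiff(need, names(led))
  if (length(miss) > 0) {
    stop("ledger is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(led$source_rank, led$source_name)
  if (anyDuplicated(key)) {
    stop("duplicate ledger source key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  led
}

#' Map classified taxa to reference-proteome taxa
#'
#' For each row of a classification table, tries an exact (rank, name)
#' match in the reference database (names compared case-sensitively after
#' whitespace trimming; no fuzzy matching); failing that, applies the
#' first matching ledger rule and matches its target; failing that, the
#' row is unmapped. Unmapped rows are excluded from downstream
#' aggregation, and their count-weighted percentage makes the loss
#' visible.
#'
#' @param ct Classification table (see [read_rdp_hierarchy()]).
#' @param refdb Reference proteome database tibble (see [read_refdb()]).
#' @param ledger Manual mapping ledger tibble; rules supplied here extend
#'   and override the packaged defaults in [default_ledger()]. A rule that
#'   fires must point at a taxon present in `refdb`.
#' @param quiet If `TRUE`, suppress messages about manual mappings and
#'   unmapped taxa.
#' @return A `taxon_mapping` object: a tibble with one row per `ct` row
#'   (`rank`, `name`, `target_rank`, `target_name`, `mapped`, `via_rule`,
#'   `count`) carrying attributes `unmapped_percent` (overall,
#'   count-weighted), `unmapped_by_sample`, and `top_unmapped` (most
#'   abundant unmapped taxa with their percentages). See also
#'   [glance.taxon_mapping()].
#' @export
map_taxa <- function(ct, refdb, ledger = default_ledger(), quiet = FALSE) {
  stopifnot(is.data.frame(ct), is.data.frame(refdb))
  if (nrow(refdb) == 0) stop("reference database is empty")
  samples <- sample_columns(ct)
  counts <- as.matrix(ct[, samples, drop = FALSE])

  ref_key <- paste(refdb$rank, trimws(refdb$name))
  src_rank <- ct$rank
  src_name <- trimws(ct$name)
  auto <- paste(src_rank, src_name) %in% ref_key

  tgt_rank <- ifelse(auto, src_rank, NA_character_)
  tgt_name <- ifelse(auto, src_name, NA_character_)
  via_rule <- rep(FALSE, nrow(ct))

  if (!is.null(ledger) && nrow(ledger) > 0) {
    led_key <- paste(ledger$source_rank, trimws(ledger$source_name))
    hit <- match(paste(src_rank, src_name), led_key)
    use <- !auto & !is.na(hit)
    for (i in which(use)) {
      rule <- ledger[hit[i], ]
      tkey <- paste(rule$target_rank, trimws(rule$target_name))
      if (!tkey %in% ref_key) {
        stop("ledger rule (", rule$source_rank, " ", rule$source_name,
             ") -> (", rule$target_rank, " ", rule$target_name,
             ") points to a taxon absent from the reference database")
      }
      tgt_rank[i] <- rule$target_rank
      tgt_name[i] <- trimws(rule$target_name)
      via_rule[i] <- TRUE
      if (!quiet) {
        message("manual mapping: ", rule$source_rank, " ",
                rule$source_name, " -> ", rule$target_rank, " ",
                rule$target_name,
                if (!is.na(rule$note) && nzchar(rule$note))
                  paste0(" (", rule$note, ")") else "")
      }
    }
  }

  mapped <- !is.na(tgt_name)
  taxon_total <- rowSums(counts)
  grand_total <- sum(taxon_total)
  unmapped_counts <- colSums(counts[!mapped, , drop = FALSE])
  unmapped_pct <- if (grand_total > 0) {
    100 * sum(taxon_total[!mapped]) / grand_total
  } else 0
  by_sample <- tibble::tibble(
    sample = samples,
    unmapped_percent = ifelse(colSums(counts) > 0,
                              100 * unmapped_counts / colSums(counts), 0)
  )
  top_unmapped <- tibble::tibble(
    rank = src_rank[!mapped],
    name = src_name[!mapped],
    percent = if (grand_total > 0) {
      100 * taxon_total[!mapped] / grand_total
    } else numeric(sum(!mapped))
  ) |> dplyr::arrange(dplyr::desc(.data$percent))
  if (!quiet && nrow(top_unmapped) > 0) {
    shown <- utils::head(top_unmapped, 5)
    message(sprintf("unmapped: %.1f%% of counts; most abundant unmapped taxa: %s",
                    unmapped_pct,
                    paste(sprintf("%s %s (%.1f%%)", shown$rank, shown$name,
                                  shown$percent), collapse = ", ")))
  }

  out <- tibble::tibble(
    rank = src_rank, name = src_name,
    target_rank = tgt_rank, target_name = tgt_name,
    mapped = mapped, via_rule = via_rule,
    count = taxon_total
  )
  attr(out, "unmapped_percent") <- unmapped_pct
  attr(out, "unmapped_by_sample") <- by_sample
  attr(out, "top_unmapped") <- top_unmapped
  class(out) <- c("taxon_mapping", class(out))
  out
}

#' @export
print.taxon_mapping <- function(x, ...) {
  cat(sprintf("<taxon_mapping> %d taxa, %d mapped (%d via manual rules), %.2f%% of counts unmapped\n",
              nrow(x), sum(x$mapped), sum(x$via_rule),
              attr(x, "unmapped_percent")))
  NextMethod()
}

#' One-row summary of a taxon mapping
#'
#' Broom-style `glance()` method: numbers of taxa, mapped taxa, rule
#' usages, and the overall count-weighted unmapped percentage.
#'
#' @param x A `taxon_mapping` from [map_taxa()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.taxon_mapping <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x),
    n_mapped = sum(x$mapped),
    n_via_rule = sum(x$via_rule),
    unmapped_percent = attr(x, "unmapped_percent")
  )
}

#' Per-taxon mapping results as a plain tibble
#'
#' @inheritParams glance.taxon_mapping
#' @return The per-taxon mapping tibble without the `taxon_mapping` class.
#' @export
tidy.taxon_mapping <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "taxon_mapping")
  out
}

#' @importFrom generics glance tidy
#' @export
generics::glance

#' @export
generics::tidy
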