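#' Community reference proteome of one sample
#'
#' The abundance-weighted mean of the per-protein mean amino acid
#' compositions of the mapped taxa in a sample. The weighted mean (rather
#' than a raw sum) keeps length and molecular weight interpretable as
#' per-protein expectations; carbon oxidation state and elemental ratios
#' are unaffected by that choice. Unmapped taxa are excluded, not
#' redistributed.
#'
#' @param ct Classification table (see [read_rdp_hierarchy()]).
#' @param refdb Reference proteome database (see [read_refdb()]).
#' @param mapping A `taxon_mapping` from [map_taxa()] for `ct` against
#'   `refdb`.
#' @param sample Sample (column) name in `ct`.
#' @return A one-row amino acid composition tibble with `chains = 1`
#'   (a per-protein mean of the virtual community proteome).
#' @export
community_composition <- function(ct, refdb, mapping, sample) {
  samples <- sample_columns(ct)
  if (!sample %in% samples) {
    stop("sample \"", sample, "\" not found in the classification table")
  }
  if (nrow(mapping) != nrow(ct)) {
    stop("mapping does not match the classification table (row counts differ)")
  }
  w <- ct[[sample]]
  use <- mapping$mapped & w > 0
  if (!any(use)) {
    stop("sample \"", sample, "\" has no mapped, nonzero counts; ",
         "the community composition is empty")
  }
  ref_key <- paste(refdb$rank, trimws(refdb$name))
  idx <- match(paste(mapping$target_rank[use], mapping$target_name[use]),
               ref_key)
  if (anyNA(idx)) {
    stop("mapping targets absent from the reference database: ",
         paste(unique(mapping$target_name[use][is.na(idx)]), collapse = ", "))
  }
  comp <- as.matrix(refdb[idx, aa_codes(), drop = FALSE])
  wt <- w[use] / sum(w[use])
  mean_comp <- colSums(comp * wt)
  out <- aa_row(mean_comp)
  out$chains <- 1
  out
}

#' Chemical metrics of community reference proteomes
#'
#' For each sample of a classification table, combines the abundances of
#' mapped taxa with the reference proteome compositions to obtain the
#' community reference proteome, then computes the requested chemical
#' metrics. This is the one-call pipeline entry point: mapping (with
#' manual-rule and unmapped-percentage messages) is performed internally
#' unless a precomputed `mapping` is supplied.
#'
#' @inheritParams community_composition
#' @param ledger Manual mapping ledger passed to [map_taxa()] when
#'   `mapping` is `NULL`.
#' @param mapping Optional precomputed `taxon_mapping`.
#' @param metrics Metric names for [calc_metrics()]; default
#'   `c("Zc", "nO2", "nH2O")`.
#' @param metadata Optional data frame of per-sample variables with a
#'   `sample` column; joined onto the result. Metadata rows whose sample
#'   is absent from `ct` raise an error listing the strays.
#' @param terminal_water Terminal-water convention for [calc_metrics()].
#' @param quiet Passed to [map_taxa()].
#' @return A [tibble][tibble::tibble] with a `sample` column, one column
#'   per requested metric, and any metadata columns. Samples with no
#'   mapped counts are dropped with a warning rather than aborting the
#'   table.
#' @export
#' @examples
#' db <- make_refdb(seed = 1, n_phyla = 2, genera_per_phylum = 2)
#' fx <- make_rdp_fixture(db, n_samples = 2, seed = 1)
#' ct <- read_rdp_hierarchy(fx$rdp_path)
#' get_metrics(ct, db, quiet = TRUE)
get_metrics <- function(ct, refdb, ledger = default_ledger(),
                        mapping = NULL,
                        metrics = c("Zc", "nO2", "nH2O"),
                        metadata = NULL, terminal_water = FALSE,
                        quiet = FALSE) {
  if (is.null(mapping)) {
    mapping <- map_taxa(ct, refdb, ledger = ledger, quiet = quiet)
  }
  samples <- sample_columns(ct)
  comps <- purrr::map(samples, function(s) {
    tryCatch(community_composition(ct, refdb, mapping, s),
             error = function(e) NULL)
  })
  empty <- vapply(comps, is.null, logical(1))
  if (any(empty)) {
    warning("sample(s) with no mapped counts dropped from the metrics table: ",
            paste(samples[empty], collapse = ", "))
  }
  if (all(empty)) stop("no sample has any mapped counts")
  aa <- dplyr::bind_rows(comps[!empty])
  aa <- dplyr::bind_cols(tibble::tibble(sample = samples[!empty]), aa)
  out <- calc_metrics(aa, metrics = metrics,
                      terminal_water = terminal_water)
  if (!is.null(metadata)) {
    if (!"sample" %in% names(metadata)) {
      stop("metadata must have a \"sample\" column")
    }
    strays <- setdiff(metadata$sample, samples)
    if (length(strays) > 0) {
      stop("metadata sample name(s) not present in the classification table: ",
           paste(strays, collapse = ", "))
    }
    out <- dplyr::left_join(out, metadata, by = "sample")
  }
  out
}
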