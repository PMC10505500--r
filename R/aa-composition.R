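#' Build an amino acid composition table
#'
#' Amino acid compositions are the universal currency of the package: a
#' tibble with one column per standard amino acid (three-letter codes,
#' `Ala` ... `Val`, alphabetical) giving non-negative, possibly fractional
#' residue counts, plus a `chains` column giving the number of polypeptide
#' chains. Fractional counts arise naturally from per-taxon means and
#' community-weighted means.
#'
#' @param ... Named residue counts using three-letter codes, e.g.
#'   `Gly = 2, Ala = 1`. Unknown codes are rejected.
#' @param chains Number of polypeptide chains (default 1).
#' @return A one-row tibble with the 20 amino acid columns and `chains`.
#' @export
#' @examples
#' aa_composition(Gly = 1, Ala = 1)
aa_composition <- function(..., chains = 1) {
  counts <- c(...)
  if (length(counts) > 0 && is.null(names(counts))) {
    stop("residue counts must be named with three-letter amino acid codes")
  }
  bad <- setdiff(names(counts), aa_codes())
  if (length(bad) > 0) {
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0)) stop("residue counts must be non-negative")
  out <- stats::setNames(as.list(rep(0, 20)), aa_codes())
  out[names(counts)] <- as.numeric(counts)
  out$chains <- chains
  tibble::as_tibble(out)
}

#' Count a protein sequence into an amino acid composition
#'
#' @param sequence Character vector of protein sequences in standard
#'   one-letter code. Each sequence becomes one chain; all sequences are
#'   summed into a single composition with `chains = length(sequence)`.
#' @return A one-row amino acid composition tibble.
#' @export
#' @examples
#' aa_from_sequence("GAG")  # 2 Gly + 1 Ala, one chain
aa_from_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) >= 1)
  cst <- aa_constants()
  code1 <- cst$code1[!cst$code3 %in% c("Nterm", "Cterm")]
  code3 <- cst$code3[!cst$code3 %in% c("Nterm", "Cterm")]
  chars <- strsplit(toupper(paste(sequence, collapse = "")), "")[[1]]
  bad <- setdiff(unique(chars), code1)
  if (length(bad) > 0) {
    stop("non-standard residue code(s) in sequence: ",
         paste(bad, collapse = ", "))
  }
  n <- table(factor(chars, levels = code1))
  out <- stats::setNames(as.list(as.numeric(n)), code3)
  out <- out[order(names(out))]
  out$chains <- length(sequence)
  tibble::as_tibble(out)
}

# Validate an aa-composition data frame; returns the count matrix
# (rows x 20, canonical column order) and checks non-negativity.
aa_count_matrix <- function(aa, require_positive = TRUE) {
  stopifnot(is.data.frame(aa))
  miss <- setdiff(aa_codes(), names(aa))
  if (length(miss) > 0) {
    stop("composition is missing amino acid column(s): ",
         paste(miss, collapse = ", "))
  }
  m <- as.matrix(aa[, aa_codes()])
  if (!is.numeric(m)) stop("amino acid counts must be numeric")
  if (any(m < 0)) stop("amino acid counts must be non-negative")
  if (require_positive && any(rowSums(m) <= 0)) {
    stop("composition has zero total residue count; metrics are undefined")
  }
  m
}

# chains column with default 1
aa_chains <- function(aa) {
  if ("chains" %in% names(aa)) {
    ch <- aa$chains
    if (any(ch < 0)) stop("chains must be non-negative")
    ch
  } else {
    rep(1, nrow(aa))
  }
}

# One-row tibble of 20 amino acid counts from a numeric vector in
# canonical (alphabetical code3) order
aa_row <- function(vec) {
  stopifnot(length(vec) == 20)
  tibble::as_tibble(as.list(stats::setNames(as.numeric(vec), aa_codes())))
}

# Identifier columns carried through metric calculations
aa_id_cols <- function(aa) {
  setdiff(names(aa), c(aa_codes(), "chains"))
}
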