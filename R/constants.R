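# Package-level cache for constants read from extdata
.commchem <- new.env(parent = emptyenv())

#' Amino acid constants table
#'
#' Returns the packaged table of per-amino-acid constants: elemental formula
#' of the free amino acid (C, H, N, O, S), Kyte--Doolittle hydropathy value,
#' and side-chain pK with its charge class (acidic/basic). Two extra rows,
#' `Nterm` and `Cterm`, carry the pK values of the terminal amino and
#' carboxyl groups. The table is shipped as a plain TSV under
#' `inst/extdata/` so the constants are auditable and swappable.
#'
#' Residue (in-chain) formulas are the free formulas minus one H2O.
#'
#' @return A tibble with columns `code3`, `code1`, `C`, `H`, `N`, `O`, `S`,
#'   `hydropathy`, `pK`, `charge_class`.
#' @export
#' @examples
#' aa_constants()
aa_constants <- function() {
  if (is.null(.commchem$constants)) {
    path <- system.file("extdata", "amino_acid_constants.tsv",
                        package = "commchem", mustWork = TRUE)
    tab <- utils::read.delim(path, na.strings = "NA",
                             stringsAsFactors = FALSE)
    .commchem$constants <- tibble::as_tibble(tab)
  }
  .commchem$constants
}

# The 20 standard amino acids, alphabetical by three-letter code.
# This is the canonical column order for compositions and refdb files.
aa_codes <- function() {
  cst <- aa_constants()
  cst$code3[!cst$code3 %in% c("Nterm", "Cterm")]
}

# Standard average atomic masses (g/mol)
atomic_masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

# Element matrix (rows = amino acids, cols = C,H,N,O,S) for free amino acids
aa_formula_matrix <- function() {
  cst <- aa_constants()
  cst <- cst[!cst$code3 %in% c("Nterm", "Cterm"), ]
  m <- as.matrix(cst[, c("C", "H", "N", "O", "S")])
  rownames(m) <- cst$code3
  m
}

#' The QEC basis set
#'
#' Default set of basis species (thermodynamic components) used to project
#' protein elemental compositions onto chemical compositions: glutamine,
#' glutamic acid, cysteine, water, and dioxygen. The per-residue
#' coefficients on H2O and O2 in this projection are the stoichiometric
#' hydration state (nH2O) and oxidation state (nO2).
#'
#' @return A tibble with columns `species`, `C`, `H`, `N`, `O`, `S`: five
#'   rows whose 5x5 element matrix is nonsingular.
#' @export
#' @examples
#' basis_qec()
basis_qec <- function() {
  tibble::tibble(
    species = c("glutamine", "glutamic acid", "cysteine", "H2O", "O2"),
    C = c(5, 5, 3, 0, 0),
    H = c(10, 9, 7, 2, 0),
    N = c(2, 1, 1, 0, 0),
    O = c(3, 4, 2, 1, 2),
    S = c(0, 0, 1, 0, 0)
  )
}

# Validate a basis set and return its 5x5 element matrix (species x element)
basis_matrix <- function(basis) {
  stopifnot(is.data.frame(basis))
  need <- c("species", "C", "H", "N", "O", "S")
  miss <- setdiff(need, names(basis))
  if (length(miss) > 0) {
    stop("basis set is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(basis) != 5) {
    stop("basis set must contain exactly 5 species, got ", nrow(basis))
  }
  m <- as.matrix(basis[, c("C", "H", "N", "O", "S")])
  rownames(m) <- basis$species
  if (abs(det(m)) < 1e-12) {
    stop("basis element matrix is singular; choose independent species")
  }
  m
}

# Canonical taxonomic ranks, domain downward
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}
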