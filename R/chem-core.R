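#' Elemental composition of an amino acid composition
#'
#' Sums residue elemental formulas over an amino acid composition. By
#' default the residue (in-chain) formulas are used, i.e. terminal H2O is
#' excluded, so elemental ratios and nH2O are per-residue quantities;
#' setting `terminal_water = TRUE` adds `chains` molecules of H2O. The
#' carbon oxidation state is provably identical under either convention.
#'
#' @param aa Data frame with the 20 amino acid count columns (and
#'   optionally `chains`); see [aa_composition()].
#' @param terminal_water If `TRUE`, include `chains` x H2O for the
#'   terminal groups (free-protein formulas).
#' @return A tibble with one row per input row and columns `C`, `H`, `N`,
#'   `O`, `S` (atom counts) and `Z` (formal charge, 0).
#' @export
#' @examples
#' aa_to_elements(aa_composition(Gly = 1))                        # C2H3NO
#' aa_to_elements(aa_composition(Gly = 1), terminal_water = TRUE) # C2H5NO2
aa_to_elements <- function(aa, terminal_water = FALSE) {
  counts <- aa_count_matrix(aa, require_positive = TRUE)
  chains <- aa_chains(aa)
  free <- aa_formula_matrix()[aa_codes(), ]
  elem <- counts %*% free
  # residue = free form minus one H2O each; add back chains x H2O if wanted
  n_res <- rowSums(counts)
  water <- if (terminal_water) chains else 0
  elem[, "H"] <- elem[, "H"] - 2 * n_res + 2 * water
  elem[, "O"] <- elem[, "O"] - n_res + water
  out <- tibble::as_tibble(elem)
  out$Z <- rep(0, nrow(out))
  out
}

#' Carbon oxidation state
#'
#' Average formal oxidation state of carbon, Zc = (Z - H + 3N + 2O + 2S) / C,
#' computed from an elemental composition. Zc is invariant under adding or
#' removing whole H2O units, so the terminal-water convention does not
#' affect it.
#'
#' @param elements Data frame with numeric columns `C`, `H`, `N`, `O`, `S`
#'   and optionally `Z` (formal charge, default 0), as returned by
#'   [aa_to_elements()].
#' @return Numeric vector of Zc values, one per row.
#' @export
#' @examples
#' zc(data.frame(C = 2, H = 5, N = 1, O = 2, S = 0))  # glycine: 1
#' zc(data.frame(C = 1, H = 0, N = 0, O = 2, S = 0))  # CO2: 4
zc <- function(elements) {
  stopifnot(is.data.frame(elements))
  miss <- setdiff(c("C", "H", "N", "O", "S"), names(elements))
  if (length(miss) > 0) {
    stop("elemental composition is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  z <- if ("Z" %in% names(elements)) elements$Z else 0
  if (any(elements$C <= 0)) {
    stop("carbon oxidation state is undefined for compositions with no carbon")
  }
  (z - elements$H + 3 * elements$N + 2 * elements$O + 2 * elements$S) /
    elements$C
}

#' Basis-species coefficients of an elemental composition
#'
#' Solves the five-equation element balance (C, H, N, O, S) expressing a
#' composition as a unique linear combination of the five basis species.
#' The coefficients reconstruct the input composition exactly.
#'
#' @param elements Data frame with columns `C`, `H`, `N`, `O`, `S`.
#' @param basis Basis set tibble; default [basis_qec()].
#' @return A tibble of coefficients, one column per basis species.
#' @export
basis_coefficients <- function(elements, basis = basis_qec()) {
  m <- basis_matrix(basis)
  e <- as.matrix(elements[, c("C", "H", "N", "O", "S")])
  # t(m) is elements x species; solve for species coefficients
  coef <- t(solve(t(m), t(e)))
  colnames(coef) <- rownames(m)
  tibble::as_tibble(coef)
}

#' Stoichiometric hydration and oxidation state
#'
#' Projects an elemental composition onto the basis species and returns the
#' per-residue coefficients on H2O (stoichiometric hydration state, nH2O)
#' and O2 (stoichiometric oxidation state, nO2).
#'
#' @inheritParams basis_coefficients
#' @param n_residues Number of residues to normalize by (positive; may be
#'   fractional for community compositions).
#' @return A tibble with columns `nH2O` and `nO2`, one row per input row.
#' @export
#' @examples
#' # glutamine is itself a basis species: both coefficients are zero
#' basis_projection(data.frame(C = 5, H = 10, N = 2, O = 3, S = 0), 1)
basis_projection <- function(elements, n_residues, basis = basis_qec()) {
  if (any(n_residues <= 0)) stop("n_residues must be positive")
  if (!all(c("H2O", "O2") %in% basis$species)) {
    stop("basis set must contain species named \"H2O\" and \"O2\"")
  }
  coef <- basis_coefficients(elements, basis)
  tibble::tibble(
    nH2O = coef[["H2O"]] / n_residues,
    nO2 = coef[["O2"]] / n_residues
  )
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Count-weighted mean of the Kyte--Doolittle hydropathy scale over an
#' amino acid composition, as in the ProtParam tool.
#'
#' @inheritParams aa_to_elements
#' @return Numeric vector in \[-4.5, 4.5\], one value per row.
#' @export
#' @examples
#' gravy(aa_composition(Ala = 5))  # 1.8
gravy <- function(aa) {
  counts <- aa_count_matrix(aa)
  cst <- aa_constants()
  scale <- stats::setNames(cst$hydropathy, cst$code3)[aa_codes()]
  as.numeric(counts %*% scale / rowSums(counts))
}

#' Isoelectric point
#'
#' pH at which the modeled net charge of the composition is zero. Ionizable
#' groups are the side chains of Asp, Glu, Cys, Tyr, His, Lys and Arg plus
#' `chains` amino and `chains` carboxyl termini, with a Bjellqvist-style pK
#' set (see [aa_constants()]). The net charge
#' \deqn{Q(pH) = \sum_{basic} n_i/(1+10^{pH-pK_i}) -
#'       \sum_{acidic} n_i/(1+10^{pK_i-pH})}
#' is strictly decreasing in pH; the root is found by bisection on
#' \[0, 14\] to |Q| < 1e-4 (at most 100 iterations).
#'
#' @inheritParams aa_to_elements
#' @param pk Optional replacement pK table in the layout of
#'   [aa_constants()] (columns `code3`, `pK`, `charge_class`).
#' @return Numeric vector of pI values in \[0, 14\].
#' @export
#' @examples
#' isoelectric_point(aa_composition(Gly = 3))  # midpoint of the termini pKs
isoelectric_point <- function(aa, pk = aa_constants()) {
  counts <- aa_count_matrix(aa)
  chains <- aa_chains(aa)
  pk <- pk[!is.na(pk$pK), c("code3", "pK", "charge_class")]
  vapply(seq_len(nrow(counts)), function(i) {
    n <- c(counts[i, ], Nterm = chains[i], Cterm = chains[i])
    grp <- pk[n[pk$code3] > 0, ]
    ngrp <- n[grp$code3]
    if (nrow(grp) == 0) {
      stop("composition has no ionizable groups; pI is undefined")
    }
    q <- function(ph) {
      sum(ngrp[grp$charge_class == "basic"] /
            (1 + 10^(ph - grp$pK[grp$charge_class == "basic"]))) -
        sum(ngrp[grp$charge_class == "acidic"] /
              (1 + 10^(grp$pK[grp$charge_class == "acidic"] - ph)))
    }
    lo <- 0
    hi <- 14
    mid <- (lo + hi) / 2
    for (iter in seq_len(100)) {
      mid <- (lo + hi) / 2
      qm <- q(mid)
      if (abs(qm) < 1e-4) break
      if (qm > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
}

# Canonical metric names and accepted aliases
metric_names <- function() {
  c("Zc", "nO2", "nH2O", "length", "MW", "HC", "NC", "OC", "SC",
    "GRAVY", "pI")
}

normalize_metric_names <- function(metrics) {
  alias <- c(
    "ZC" = "Zc", "zc" = "Zc", "Zc" = "Zc",
    "nO2" = "nO2", "nH2O" = "nH2O",
    "length" = "length", "Length" = "length",
    "MW" = "MW", "mw" = "MW",
    "H/C" = "HC", "N/C" = "NC", "O/C" = "OC", "S/C" = "SC",
    "HC" = "HC", "NC" = "NC", "OC" = "OC", "SC" = "SC",
    "GRAVY" = "GRAVY", "gravy" = "GRAVY",
    "pI" = "pI", "pi" = "pI"
  )
  out <- unname(alias[metrics])
  bad <- metrics[is.na(out)]
  if (length(bad) > 0) {
    stop("unknown metric name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(metric_names(), collapse = ", "))
  }
  out
}

#' Chemical metrics of amino acid compositions
#'
#' Computes the requested chemical metrics for each row of an amino acid
#' composition table. Available metrics: `Zc` (carbon oxidation state),
#' `nO2` and `nH2O` (per-residue stoichiometric oxidation and hydration
#' state from the basis-species projection), `length` (residues per
#' chain), `MW` (mean residue molecular weight, g/mol), the elemental
#' ratios `HC`, `NC`, `OC`, `SC` (aliases `"H/C"` etc. accepted), `GRAVY`
#' and `pI`.
#'
#' Elemental ratios and nH2O follow the configured terminal-water
#' convention (per-residue, terminal water excluded, by default); Zc and
#' nO2 are unaffected by it.
#'
#' @inheritParams aa_to_elements
#' @param metrics Character vector of metric names; default
#'   `c("Zc", "nO2", "nH2O")`.
#' @param basis Basis set for the nO2/nH2O projection; default
#'   [basis_qec()].
#' @return A tibble with any identifier columns of `aa` (columns that are
#'   not amino acid counts or `chains`) followed by one column per
#'   requested metric.
#' @export
#' @examples
#' calc_metrics(aa_composition(Gly = 10), metrics = c("Zc", "length", "MW"))
calc_metrics <- function(aa, metrics = c("Zc", "nO2", "nH2O"),
                         terminal_water = FALSE, basis = basis_qec()) {
  metrics <- normalize_metric_names(metrics)
  counts <- aa_count_matrix(aa)
  chains <- aa_chains(aa)
  n_res <- rowSums(counts)
  elem <- aa_to_elements(aa, terminal_water = terminal_water)

  vals <- list()
  for (m in metrics) {
    vals[[m]] <- switch(
      m,
      Zc = zc(elem),
      nO2 = basis_projection(elem, n_res, basis)$nO2,
      nH2O = basis_projection(elem, n_res, basis)$nH2O,
      length = n_res / chains,
      MW = as.numeric(
        as.matrix(elem[, c("C", "H", "N", "O", "S")]) %*%
          atomic_masses[c("C", "H", "N", "O", "S")]
      ) / n_res,
      HC = elem$H / elem$C,
      NC = elem$N / elem$C,
      OC = elem$O / elem$C,
      SC = elem$S / elem$C,
      GRAVY = gravy(aa),
      pI = isoelectric_point(aa)
    )
  }
  out <- tibble::as_tibble(vals)
  ids <- aa_id_cols(aa)
  if (length(ids) > 0) {
    out <- dplyr::bind_cols(aa[, ids, drop = FALSE], out)
  }
  out
}
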