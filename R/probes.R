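#' @keywords internal
"_PACKAGE"

# Molar mass of glucose, the dextran monomer, in g/mol.
GLUCOSE_MOLAR_MASS <- 180.16

# Avogadro's number, 1/mol (2019 SI exact value).
AVOGADRO <- 6.02214076e23

#' Degree of polymerization of a linear polymer
#'
#' Number of monomer units in a chain of the given molecular weight.
#' Dextrans are glucose polymers, so the default monomer molar mass is
#' that of glucose (180.16 g/mol).
#'
#' @param molecular_weight Polymer molecular weight in g/mol.
#' @param monomer_molar_mass Monomer molar mass in g/mol.
#' @return The (unrounded) monomer count `molecular_weight / monomer_molar_mass`.
#' @examples
#' degree_of_polymerization(3000)   # ~16.7 for the 3 kDa dextran
#' @export
degree_of_polymerization <- function(molecular_weight,
                                     monomer_molar_mass = GLUCOSE_MOLAR_MASS) {
  if (any(!is.finite(molecular_weight)) || any(molecular_weight <= 0))
    stop("'molecular_weight' must be positive and finite")
  if (any(!is.finite(monomer_molar_mass)) || any(monomer_molar_mass <= 0))
    stop("'monomer_molar_mass' must be positive and finite")
  molecular_weight / monomer_molar_mass
}

#' Flory coil radius of an ideal polymer chain
#'
#' Radius of gyration of a random-coil polymer in solution,
#' \deqn{R_g = \frac{a N^{\nu}}{\sqrt{6}},}
#' where `a` is the monomer size, `N` the degree of polymerization and
#' \eqn{\nu} the Flory exponent (3/5 in a good solvent). For dextran the
#' monomer is glucose, with a hydrodynamic size of about 0.35 nm.
#'
#' @param N Degree of polymerization (>= 1).
#' @param a Monomer size in nm.
#' @param nu Flory exponent, in (0, 1]. Default 3/5 (good solvent).
#' @return Coil radius in nm (full precision; round for display).
#' @examples
#' coil_radius(16.7)              # ~0.77 nm, the 3 kDa dextran
#' coil_radius(55.5)              # ~1.59 nm, the 10 kDa dextran
#' @export
coil_radius <- function(N, a = 0.35, nu = 3 / 5) {
  if (any(!is.finite(N)) || any(N < 1))
    stop("'N' must be >= 1 (at least one monomer)")
  if (any(!is.finite(a)) || any(a <= 0))
    stop("'a' (monomer size) must be positive")
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu > 1))
    stop("'nu' (Flory exponent) must lie in (0, 1]")
  a * N^nu / sqrt(6)
}

#' Build a dextran probe ladder
#'
#' Characterizes a set of FITC-dextran probes by degree of polymerization
#' and Flory coil radius, returning them sorted by ascending coil radius.
#' Probes are labelled by their nominal molecular weight ("3 kDa", ...),
#' the vocabulary used to report size-exclusion results.
#'
#' @param molecular_weights Numeric vector of probe molecular weights in g/mol.
#' @param working_concentrations Optional numeric vector of assay
#'   concentrations in uM, recycled against `molecular_weights`.
#' @param monomer_molar_mass,a,nu Passed to
#'   [degree_of_polymerization()] and [coil_radius()].
#' @return A `dextran_ladder` data frame with columns `label`,
#'   `molecular_weight`, `N`, `rg_nm` and `working_concentration`.
#' @examples
#' build_ladder(c(3000, 10000, 40000, 70000))
#' @export
build_ladder <- function(molecular_weights,
                         working_concentrations = NULL,
                         monomer_molar_mass = GLUCOSE_MOLAR_MASS,
                         a = 0.35, nu = 3 / 5) {
  if (length(molecular_weights) == 0)
    stop("'molecular_weights' must be non-empty")
  N <- degree_of_polymerization(molecular_weights, monomer_molar_mass)
  rg <- coil_radius(N, a = a, nu = nu)
  conc <- if (is.null(working_concentrations)) NA_real_ else
    rep_len(as.numeric(working_concentrations), length(molecular_weights))
  out <- data.frame(
    label = probe_label(molecular_weights),
    molecular_weight = as.numeric(molecular_weights),
    N = N,
    rg_nm = rg,
    working_concentration = conc,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rg_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dextran_ladder", "data.frame")
  out
}

probe_label <- function(mw) {
  kda <- mw / 1000
  ifelse(kda == round(kda),
         sprintf("%d kDa", as.integer(round(kda))),
         sprintf("%.3g kDa", kda))
}

#' @export
print.dextran_ladder <- function(x, digits = 3, ...) {
  cat("Dextran probe ladder (", nrow(x), " probes)\n", sep = "")
  y <- data.frame(
    label = x$label,
    `MW (g/mol)` = x$molecular_weight,
    N = round(x$N, 1),
    `Rg (nm)` = round(x$rg_nm, 2),
    `conc (uM)` = x$working_concentration,
    check.names = FALSE
  )
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Dextran molecules available per cell
#'
#' Dosing arithmetic for the uptake assay: how many probe molecules are
#' present per cell at a given concentration and cell density.
#'
#' @param concentration Probe concentration in uM.
#' @param cell_density Cell density in cells/mL.
#' @return Dimensionless molecules-per-cell ratio.
#' @examples
#' molecules_per_cell(50, 1e7)    # ~3e9
#' molecules_per_cell(2.5, 1e7)   # ~1.5e8
#' @export
molecules_per_cell <- function(concentration, cell_density) {
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("'concentration' must be positive")
  if (any(!is.finite(cell_density)) || any(cell_density <= 0))
    stop("'cell_density' must be positive")
  concentration * 1e-6 * AVOGADRO / 1000 / cell_density
}

#' Read/write a probe ladder as CSV
#'
#' @param ladder A `dextran_ladder` from [build_ladder()].
#' @param path File path.
#' @return `read_ladder` returns a `dextran_ladder`; `write_ladder`
#'   returns `path` invisibly.
#' @export
write_ladder <- function(ladder, path) {
  stopifnot(inherits(ladder, "data.frame"))
  out <- data.frame(
    label = ladder$label,
    molecular_weight_da = ladder$molecular_weight,
    N = ladder$N,
    rg_nm = ladder$rg_nm,
    working_concentration_um = ladder$working_concentration
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ladder
#' @export
read_ladder <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "molecular_weight_da", "N", "rg_nm")
  if (!all(need %in% names(x)))
    stop("ladder CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    label = x$label,
    molecular_weight = x$molecular_weight_da,
    N = x$N,
    rg_nm = x$rg_nm,
    working_concentration =
      if ("working_concentration_um" %in% names(x))
        x$working_concentration_um else NA_real_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rg_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dextran_ladder", "data.frame")
  out
}
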