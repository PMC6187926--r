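#' @useDynLib aggtrap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats approx
#' @importFrom utils write.csv
NULL

# Internal unit system is SI: m, s, kg, Pa, mol/m^3.  Because 1 mM == 1 mol/m^3,
# concentrations read from configs in mM need no conversion; lengths given in
# micrometres and flow rates in uL/min are converted at load time.

#' Unit conversion helpers
#'
#' Small named conversions used at the config boundary.  Everything internal
#' is SI; `1 mM == 1 mol/m^3` so molar concentrations pass through unchanged.
#'
#' @param x numeric value(s).
#' @return numeric value(s) in SI units.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
ul_per_min_to_m3_per_s <- function(x) x * 1e-9 / 60

#' Oxygen concentration equivalent to a 10 mmHg partial pressure
#'
#' Hypoxia threshold used throughout: tissue below this dissolved-oxygen
#' concentration is counted as hypoxic.  Stored as the printed constant;
#' the underlying Henry coefficient is not reconstructed.
#' @export
HYPOXIA_THRESHOLD_MM <- 0.01322

#' Physical parameters of the culture medium
#'
#' Container for the bulk medium properties and the imposed inlet flow rate.
#' The culture medium is treated as water at 37 degrees C.
#'
#' @param rho medium density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param Q inlet volumetric flow rate, m^3/s.
#' @param T_label descriptive temperature tag (not used in computations).
#' @return an object of class `physical_params`.
#' @export
physical_params <- function(rho, mu, Q, T_label = "37C") {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(Q), length(Q) == 1L, Q > 0)
  structure(list(rho = rho, mu = mu, Q = Q, T_label = T_label),
            class = "physical_params")
}

#' Default medium properties
#'
#' Water at 37 degrees C (rho = 993.3 kg/m^3, mu = 6.92e-4 Pa s) and an inlet
#' flow rate of 5 uL/min converted to SI.
#'
#' @return a [physical_params] object.
#' @export
default_physical_params <- function() {
  physical_params(rho = 993.3, mu = 0.000692,
                  Q = ul_per_min_to_m3_per_s(5), T_label = "37C")
}

#' Species transport properties
#'
#' Diffusivities per material region, solubility (partition) ratios relative
#' to the medium, Michaelis-Menten uptake parameters and the inlet
#' concentration.  Glucose does not penetrate the elastomer: it carries no
#' PDMS diffusivity and `pdms_permeable = FALSE`; the transport assembly then
#' treats PDMS as a no-flux exterior rather than a region of zero diffusivity.
#'
#' @param name species identifier, `"oxygen"` or `"glucose"`.
#' @param D_medium,D_tissue diffusion coefficients, m^2/s.
#' @param D_pdms diffusion coefficient in PDMS, m^2/s (`NA` when impermeable).
#' @param S_pdms,S_tissue dimensionless solubility ratios vs the medium.
#' @param Vmax maximum consumption rate, mol/(m^3 s) (numerically equal to mM/s).
#' @param Km Michaelis constant, mol/m^3.
#' @param c_inlet inlet concentration, mol/m^3.
#' @param pdms_permeable logical; does the species diffuse through PDMS?
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, D_medium, D_tissue, D_pdms = NA_real_,
                         S_pdms = NA_real_, S_tissue, Vmax, Km, c_inlet,
                         pdms_permeable = !is.na(D_pdms)) {
  stopifnot(is.character(name), length(name) == 1L,
            D_medium > 0, D_tissue > 0, S_tissue > 0,
            Vmax >= 0, Km > 0, c_inlet > 0,
            is.logical(pdms_permeable))
  if (pdms_permeable) stopifnot(!is.na(D_pdms), D_pdms > 0, !is.na(S_pdms), S_pdms > 0)
  structure(list(name = name, D_medium = D_medium, D_pdms = D_pdms,
                 D_tissue = D_tissue, S_pdms = S_pdms, S_tissue = S_tissue,
                 Vmax = Vmax, Km = Km, c_inlet = c_inlet,
                 pdms_permeable = pdms_permeable),
            class = "species_spec")
}

#' Default species definitions
#'
#' Literature constants for dissolved oxygen and glucose in culture medium,
#' PDMS and cancerous tissue at 37 degrees C.
#'
#' @param name `"oxygen"` or `"glucose"`.
#' @return a [species_spec] object.
#' @export
default_species <- function(name = c("oxygen", "glucose")) {
  name <- match.arg(name)
  switch(name,
    oxygen = species_spec("oxygen",
      D_medium = 2.6e-9, D_pdms = 3.4e-9, D_tissue = 1.83e-9,
      S_pdms = 6, S_tissue = 4.81,
      Vmax = 0.0203, Km = 0.00463, c_inlet = 0.2,
      pdms_permeable = TRUE),
    glucose = species_spec("glucose",
      D_medium = 9.27e-10, D_tissue = 2.7e-10,
      S_tissue = 1,
      Vmax = 0.01076, Km = 0.04, c_inlet = 11,
      pdms_permeable = FALSE)
  )
}

#' Knudsen number
#'
#' Ratio of the molecular mean free path to a characteristic device length.
#' Continuum flow (and hence the continuity/momentum description used here)
#' requires Kn well below 1e-3.
#'
#' @param lambda_mfp mean free path, m.
#' @param L characteristic length, m.
#' @return dimensionless Knudsen number.
#' @export
knudsen_number <- function(lambda_mfp, L) {
  if (!is.numeric(lambda_mfp) || !is.numeric(L) ||
      any(lambda_mfp <= 0) || any(L <= 0)) {
    stop("knudsen_number(): both arguments must be positive lengths")
  }
  lambda_mfp / L
}

## --- config (de)serialization -----------------------------------------------

#' @export
as.list.physical_params <- function(x, ...) unclass(x)

#' @export
as.list.species_spec <- function(x, ...) unclass(x)

physical_params_from_list <- function(lst) {
  known <- c("rho", "mu", "Q", "T_label")
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) stop("unknown physical parameter key(s): ",
                            paste(unknown, collapse = ", "))
  base <- as.list(default_physical_params())
  base[names(lst)] <- lst
  physical_params(rho = base$rho, mu = base$mu, Q = base$Q,
                  T_label = base$T_label)
}

species_from_list <- function(lst) {
  if (is.null(lst$name)) stop("species config requires a 'name'")
  known <- c("name", "D_medium", "D_pdms", "D_tissue", "S_pdms", "S_tissue",
             "Vmax", "Km", "c_inlet", "pdms_permeable")
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) stop("unknown species key(s): ",
                            paste(unknown, collapse = ", "))
  base <- as.list(default_species(lst$name))
  lst2 <- lst
  lst2$name <- NULL
  base[names(lst2)] <- lst2
  do.call(species_spec, base)
}

#' @export
print.physical_params <- function(x, ...) {
  cat(sprintf("medium: rho = %g kg/m^3, mu = %g Pa.s, Q = %g m^3/s (%s)\n",
              x$rho, x$mu, x$Q, x$T_label))
  invisible(x)
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("species '%s': D_med = %g, D_tis = %g m^2/s, S_tis = %g\n",
              x$name, x$D_medium, x$D_tissue, x$S_tissue))
  if (x$pdms_permeable)
    cat(sprintf("  PDMS-permeable: D_pdms = %g, S_pdms = %g\n",
                x$D_pdms, x$S_pdms))
  cat(sprintf("  Vmax = %g mM/s, Km = %g mM, inlet = %g mM\n",
              x$Vmax, x$Km, x$c_inlet))
  invisible(x)
}
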