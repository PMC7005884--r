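#' Shipped standard free energies of formation
#'
#' Standard Gibbs free energies of formation (kJ/mol, 25 degC) for the species
#' of the nitrifier catabolic reactions, aqueous standard state at 1 mol/L
#' except: water enters at unit activity, H+ via pH, and O2 carries the
#' gas-reference value 0 while its dissolved concentration is used as
#' activity. The O2 convention is deliberate: it is the convention under
#' which the nitrite-oxidation free energy at the study-site conditions
#' evaluates to about -65 kJ/mol; an aqueous-state ΔGf°(O2) of +16.4 kJ/mol
#' would shift all oxygenase reactions by -8.2 kJ per half-mole of O2.
#' Fully overridable per reaction.
#'
#' @return Named numeric vector, kJ/mol.
#' @export
default_dgf <- function() {
  c("NO2-" = -32.2, "NO3-" = -111.3, "NH4+" = -79.31, "NH3" = -26.5,
    "O2" = 0, "H2O" = -237.18, "H+" = 0)
}

# elemental composition and charge used for the balance check
.species_composition <- function() {
  # rows: N, H, O, charge
  list("NO2-" = c(N = 1, H = 0, O = 2, z = -1),
       "NO3-" = c(N = 1, H = 0, O = 3, z = -1),
       "NH4+" = c(N = 1, H = 4, O = 0, z = +1),
       "NH3"  = c(N = 1, H = 3, O = 0, z = 0),
       "O2"   = c(N = 0, H = 0, O = 2, z = 0),
       "H2O"  = c(N = 0, H = 2, O = 1, z = 0),
       "H+"   = c(N = 0, H = 1, O = 0, z = +1))
}

#' Define a catabolic reaction
#'
#' Stoichiometry as a named vector of signed coefficients (products positive,
#' reactants negative). Mass and charge balance are checked at construction
#' for species with known composition; unknown species skip the check but
#' must carry a formation energy.
#'
#' @param name Reaction label.
#' @param stoichiometry Named numeric vector, species -> signed coefficient.
#' @param dgf Named vector of formation energies (kJ/mol); defaults to
#'   [default_dgf()], overridable entry-wise.
#' @return A `reaction` object.
#' @examples
#' nitrite_oxidation()
#' @export
reaction <- function(name, stoichiometry, dgf = default_dgf()) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  miss <- setdiff(names(stoichiometry), names(dgf))
  if (length(miss))
    stop("no formation free energy for species: ", paste(miss, collapse = ", "))
  comp <- .species_composition()
  known <- intersect(names(stoichiometry), names(comp))
  if (length(known) == length(stoichiometry)) {
    bal <- Reduce(`+`, Map(function(sp, nu) nu * comp[[sp]],
                           known, stoichiometry[known]))
    if (any(abs(bal) > 1e-9))
      stop("reaction '", name, "' not balanced: ",
           paste(names(bal)[abs(bal) > 1e-9], collapse = ", "))
  }
  structure(list(name = name, stoichiometry = stoichiometry,
                 dgf = dgf[names(stoichiometry)]),
            class = "reaction")
}

#' Canonical nitrite-oxidation reaction
#'
#' NO2- + 1/2 O2 -> NO3-.
#' @param dgf Formation-energy table.
#' @return A [reaction()].
#' @export
nitrite_oxidation <- function(dgf = default_dgf()) {
  reaction("nitrite_oxidation",
           c("NO2-" = -1, "O2" = -0.5, "NO3-" = 1), dgf)
}

#' Canonical ammonia-oxidation reaction
#'
#' NH4+ + 3/2 O2 -> NO2- + H2O + 2 H+. A speciation toggle selects NH3 as
#' the substrate instead (NH3 + 3/2 O2 -> NO2- + H2O + H+).
#'
#' @param substrate `"NH4+"` (default) or `"NH3"`.
#' @param dgf Formation-energy table.
#' @return A [reaction()].
#' @export
ammonia_oxidation <- function(substrate = c("NH4+", "NH3"),
                              dgf = default_dgf()) {
  substrate <- match.arg(substrate)
  if (substrate == "NH4+")
    reaction("ammonia_oxidation",
             c("NH4+" = -1, "O2" = -1.5, "NO2-" = 1, "H2O" = 1, "H+" = 2), dgf)
  else
    reaction("ammonia_oxidation_nh3",
             c("NH3" = -1, "O2" = -1.5, "NO2-" = 1, "H2O" = 1, "H+" = 1), dgf)
}

#' In situ thermodynamic conditions
#'
#' Temperature, species concentrations (used directly as activities,
#' activity coefficients of 1) and pH. The defaults are the hypoxic
#' bottom-water medians of the study site: nitrite 848 nM, nitrate 2250 nM,
#' ammonium 320 nM, O2 63 µM, 28 degC, pH 8.1.
#'
#' @param temperature_K Temperature, K.
#' @param concentrations Named vector, species -> mol/L.
#' @param pH pH (sets the H+ activity).
#' @return A `thermo_conditions` object.
#' @export
thermo_conditions <- function(temperature_K = 301.15,
                              concentrations = c("NO2-" = 848e-9,
                                                 "NO3-" = 2250e-9,
                                                 "NH4+" = 320e-9,
                                                 "O2" = 63e-6),
                              pH = 8.1) {
  stopifnot(temperature_K > 0, all(concentrations > 0))
  structure(list(temperature_K = temperature_K,
                 concentrations = concentrations, pH = pH),
            class = "thermo_conditions")
}

#' Gibbs free energy of a reaction under in situ conditions
#'
#' `dG = sum(nu * dGf) + R T ln Q`, with the activity quotient `Q` built
#' from the supplied concentrations (products over reactants, each raised to
#' its stoichiometric coefficient). Water enters at unit activity and H+ at
#' `10^-pH`. Negative values are exergonic.
#'
#' @param rxn A [reaction()].
#' @param cond A [thermo_conditions()].
#' @return Free energy, kJ per mole of reaction as written.
#' @examples
#' gibbs_free_energy(nitrite_oxidation(), thermo_conditions())  # about -65
#' @export
gibbs_free_energy <- function(rxn, cond) {
  stopifnot(inherits(rxn, "reaction"), inherits(cond, "thermo_conditions"))
  nu <- rxn$stoichiometry
  dG0 <- sum(nu * rxn$dgf)
  act <- vapply(names(nu), function(sp) {
    if (sp == "H2O") return(1)
    if (sp == "H+") return(10^(-cond$pH))
    a <- cond$concentrations[sp]
    if (is.na(a)) stop("no concentration for species: ", sp)
    unname(a)
  }, numeric(1))
  lnQ <- sum(nu * log(act))
  dG0 + sip_constants$R_kJ * cond$temperature_K * lnQ
}

#' Catabolic energy flux from a bulk rate
#'
#' `flux = bulk_rate * |dG| * 1e-6`: a bulk rate in nmol/L/d times an energy
#' yield in kJ/mol gives J/L/d.
#'
#' @param bulk_rate Bulk rate, nmol L^-1 d^-1.
#' @param delta_g Free energy, kJ/mol (sign ignored; magnitude used).
#' @return Energy flux, J L^-1 d^-1.
#' @examples
#' energy_flux(2508, -262)  # 0.657 J/L/d
#' @export
energy_flux <- function(bulk_rate, delta_g) {
  if (any(bulk_rate < 0)) stop("bulk rate must be non-negative")
  bulk_rate * abs(delta_g) * 1e-6
}

#' Biomass yield per Joule
#'
#' Carbon assimilated per unit catabolic energy dissipated:
#' `yield = c_assim / flux`, nmol-C per Joule.
#'
#' @param c_assim Population C-assimilation, nmol-C L^-1 d^-1.
#' @param flux Energy flux, J L^-1 d^-1 (> 0).
#' @return Yield, nmol-C J^-1.
#' @examples
#' biomass_yield(404, 0.658)  # 614
#' @export
biomass_yield <- function(c_assim, flux) {
  if (any(flux <= 0)) stop("energy flux must be positive")
  if (any(c_assim < 0)) stop("C-assimilation must be non-negative")
  c_assim / flux
}
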