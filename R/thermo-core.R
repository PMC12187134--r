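# Gas constant in kcal/(mol K); all energies in the package are kcal/mol.
.R_KCAL <- 1.987204e-3

#' Gas constant used throughout the package
#'
#' @return The molar gas constant in kcal/(mol K).
#' @export
gas_constant_kcal <- function() .R_KCAL

#' One-set-of-sites thermodynamic parameters
#'
#' Container for the parameters of the single-class ("one set of sites", OSS)
#' ITC binding model: stoichiometry per macromolecule, dissociation constant,
#' enthalpy change and temperature.
#'
#' @param n_sites Stoichiometry N per macromolecule (dimensionless, > 0).
#' @param kd Dissociation constant in molar (> 0).
#' @param dh Enthalpy change in kcal/mol of ligand.
#' @param temperature Absolute temperature in kelvin (> 0); defaults to
#'   298.15 K (25 degrees C).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params(n_sites = 1.2, kd = 1.2e-6, dh = -10.6)
#' @export
thermo_params <- function(n_sites, kd, dh, temperature = 298.15) {
  stopifnot(is.numeric(n_sites), is.numeric(kd), is.numeric(dh),
            is.numeric(temperature))
  if (n_sites <= 0) stop("n_sites must be > 0")
  if (kd <= 0) stop("kd must be > 0 (molar)")
  if (temperature <= 0) stop("temperature must be > 0 (kelvin)")
  structure(list(n_sites = n_sites, kd = kd, ka = 1 / kd, dh = dh,
                 temperature = temperature),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "One-set-of-sites parameters: N = %.3g, Kd = %.3g uM, dH = %.3g kcal/mol, T = %.2f K\n",
    x$n_sites, x$kd * 1e6, x$dh, x$temperature))
  invisible(x)
}

#' Gibbs free energy of binding from a dissociation constant
#'
#' Computes `dG = R T ln(Kd)` in kcal/mol. With the standard-state convention
#' used here (Kd in molar), favourable binding (Kd < 1 M) gives a negative dG.
#'
#' @param kd Dissociation constant in molar (> 0).
#' @param temperature Absolute temperature in kelvin (> 0).
#' @return Gibbs free energy change in kcal/mol.
#' @examples
#' delta_g_from_kd(0.4e-6, 298.15)  # approx -8.73
#' @export
delta_g_from_kd <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be > 0 (molar)")
  if (any(temperature <= 0)) stop("temperature must be > 0 (kelvin)")
  .R_KCAL * temperature * log(kd)
}

#' Dissociation constant from a Gibbs free energy
#'
#' Inverse of [delta_g_from_kd()]: `Kd = exp(dG / (R T))`.
#'
#' @param dg Gibbs free energy change in kcal/mol.
#' @param temperature Absolute temperature in kelvin (> 0).
#' @return Dissociation constant in molar.
#' @export
kd_from_delta_g <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be > 0 (kelvin)")
  exp(dg / (.R_KCAL * temperature))
}

#' Entropic term -T dS from dG and dH
#'
#' The identity `dG = dH - T dS` rearranged: `-T dS = dG - dH`.  This is the
#' quantity tabulated alongside dG and dH in ITC reports.
#'
#' @param dg Gibbs free energy change, kcal/mol.
#' @param dh Enthalpy change, kcal/mol.
#' @return `-T dS` in kcal/mol.
#' @examples
#' neg_t_delta_s(-8.8, -9.7)  # 0.9
#' @export
neg_t_delta_s <- function(dg, dh) {
  stopifnot(is.finite(dg), is.finite(dh))
  dg - dh
}

#' Monomer mass table for 53BP1/LC8 complexes
#'
#' Expected monomer/dimer masses used for composition-to-mass bookkeeping.
#' Defaults are the construct masses used in the SEC-MALS analysis:
#' 53BP1 LBD-OD monomer 17.0 kDa, LC8 dimer 21.2 kDa, OD-only monomer
#' 13.2 kDa.
#'
#' @param lbd_od_monomer Mass of one LBD-OD chain, kDa.
#' @param lc8_dimer Mass of one LC8 homodimer, kDa.
#' @param od_monomer Mass of one OD-only chain, kDa.
#' @return An object of class `mass_table`.
#' @export
mass_table <- function(lbd_od_monomer = 17.0, lc8_dimer = 21.2,
                       od_monomer = 13.2) {
  m <- c(lbd_od_monomer = lbd_od_monomer, lc8_dimer = lc8_dimer,
         od_monomer = od_monomer)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all masses must be finite and strictly positive (kDa)")
  structure(as.list(m), class = "mass_table")
}

#' @export
print.mass_table <- function(x, ...) {
  cat("Mass table (kDa): LBD-OD monomer", x$lbd_od_monomer,
      "| LC8 dimer", x$lc8_dimer, "| OD monomer", x$od_monomer, "\n")
  invisible(x)
}

#' Write / read a mass table as plain key: value text
#'
#' Flat `key: value` serialization so mass overrides can live in a run
#' configuration file.
#'
#' @param x A `mass_table`.
#' @param path File path.
#' @return `write_mass_table` returns `path` invisibly; `read_mass_table`
#'   returns a `mass_table`.
#' @export
write_mass_table <- function(x, path) {
  stopifnot(inherits(x, "mass_table"))
  writeLines(sprintf("%s: %.10g", names(x), unlist(x)), path)
  invisible(path)
}

#' @rdname write_mass_table
#' @export
read_mass_table <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, ":", fixed = TRUE)
  vals <- vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  do.call(mass_table, as.list(vals))
}

#' Species composition of a 53BP1/LC8 complex
#'
#' A complex is described by how many 53BP1 trimers it contains (0, 1 or 2),
#' how many LC8 dimers are bound, and how many intact QT recognition sites
#' each chain carries (q = 1, 2 or 3).  A single trimer binds at most q LC8
#' dimers (one per QT register); the bridged dimer-of-trimers binds at most
#' 3q (two intratrimer plus one bridging LC8 per register).
#'
#' @param n_trimers Number of 53BP1 trimers (0, 1 or 2).
#' @param n_lc8_dimers Number of bound LC8 dimers (non-negative integer).
#' @param q Number of intact QT sites per chain (1, 2 or 3).
#' @return An object of class `species_composition`.
#' @examples
#' species_composition(2, 9, q = 3)  # fully occupied bridged complex
#' @export
species_composition <- function(n_trimers, n_lc8_dimers, q = 3) {
  if (!n_trimers %in% c(0, 1, 2)) stop("n_trimers must be 0, 1 or 2")
  if (!q %in% 1:3) stop("q must be 1, 2 or 3")
  if (n_lc8_dimers < 0 || n_lc8_dimers != round(n_lc8_dimers))
    stop("n_lc8_dimers must be a non-negative integer")
  if (n_trimers == 1 && n_lc8_dimers > q)
    stop(sprintf("a single trimer with q = %d binds at most %d LC8 dimers", q, q))
  if (n_trimers == 2 && n_lc8_dimers > 3 * q)
    stop(sprintf("a dimer-of-trimers with q = %d binds at most %d LC8 dimers",
                 q, 3 * q))
  if (n_trimers == 0 && n_lc8_dimers == 0)
    stop("empty composition")
  structure(list(n_trimers = n_trimers, n_lc8_dimers = n_lc8_dimers, q = q),
            class = "species_composition")
}

#' @export
print.species_composition <- function(x, ...) {
  cat(sprintf("Composition %d trimer(s) : %d LC8 dimer(s) [q = %d]\n",
              x$n_trimers, x$n_lc8_dimers, x$q))
  invisible(x)
}

#' Expected mass of a complex
#'
#' Mass is additive over components: `n_trimers * 3 * lbd_od_monomer +
#' n_lc8_dimers * lc8_dimer` (kDa).
#'
#' @param comp A [species_composition()].
#' @param masses A [mass_table()].
#' @return Expected mass in kDa.
#' @examples
#' complex_mass(species_composition(2, 9), mass_table())  # 292.8
#' @export
complex_mass <- function(comp, masses = mass_table()) {
  stopifnot(inherits(comp, "species_composition"), inherits(masses, "mass_table"))
  comp$n_trimers * 3 * masses$lbd_od_monomer + comp$n_lc8_dimers * masses$lc8_dimer
}

#' Maximum LC8 occupancy for a given number of intact QT sites
#'
#' A trimer complex binds at most q LC8 dimers; the fully occupied bridged
#' dimer-of-trimers binds 3q (per register: one intratrimer LC8 on each of
#' the two trimers plus one bridging LC8).
#'
#' @param q Number of intact QT sites per chain (1, 2 or 3).
#' @return Named integer vector `c(trimer_max, bridged_max) = c(q, 3q)`.
#' @examples
#' max_occupancy(3)  # c(trimer_max = 3, bridged_max = 9)
#' @export
max_occupancy <- function(q) {
  if (!q %in% 1:3) stop("q must be 1, 2 or 3")
  c(trimer_max = q, bridged_max = 3L * q)
}
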