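# Relative dimerization and calcium-binding energy algebra.
#
# Component energies are total molecular-mechanics energies of the hydrated
# species (dimer, monomers, dimer with two bound calcium ions, solvated
# Ca2+), in kcal/mol, consumed from files; the force-field minimizations
# that produce them are out of scope. The quantities derived here are
# differences of differences: they vanish when variant equals native and
# are invariant to any constant offset applied to all totals.

#' Bundle molecular-mechanics component energies
#'
#' @param e_tot_dimer Total energy of the hydrated subunit dimer AB,
#'   kcal/mol.
#' @param e_tot_monomer_a,e_tot_monomer_b Total energies of the hydrated
#'   monomers, kcal/mol.
#' @param e_tot_dimer_2ca Total energy of the dimer with two bound Ca2+
#'   ions, kcal/mol; optional, but required together with \code{e_sol_ca}
#'   for calcium-binding energies.
#' @param e_sol_ca Solvation energy of one Ca2+ ion, kcal/mol.
#' @param label \code{"native"} or a variant identifier.
#' @return An object of class \code{energy_components}.
#' @export
energy_components <- function(e_tot_dimer, e_tot_monomer_a, e_tot_monomer_b,
                              e_tot_dimer_2ca = NA_real_,
                              e_sol_ca = NA_real_,
                              label = "native") {
  core <- c(e_tot_dimer, e_tot_monomer_a, e_tot_monomer_b)
  if (any(is.na(core)) || any(!is.finite(core)))
    stop("dimer and monomer total energies must be finite", call. = FALSE)
  if (!is.na(e_tot_dimer_2ca) && is.na(e_sol_ca))
    stop("e_sol_ca must be present whenever e_tot_dimer_2ca is",
         call. = FALSE)
  structure(
    list(e_tot_dimer = e_tot_dimer,
         e_tot_monomer_a = e_tot_monomer_a,
         e_tot_monomer_b = e_tot_monomer_b,
         e_tot_dimer_2ca = e_tot_dimer_2ca,
         e_sol_ca = e_sol_ca,
         label = label),
    class = "energy_components")
}

#' Subunit dimerization energy
#'
#' \code{E_tot(dimer) - E_tot(monomer A) - E_tot(monomer B)}: the binding
#' energy between two neighbouring subunits in the hydrated dimer.
#'
#' @param c An \code{\link{energy_components}} object.
#' @return Dimerization energy in kcal/mol.
#' @export
dimerization_energy <- function(c) {
  stopifnot(inherits(c, "energy_components"))
  c$e_tot_dimer - c$e_tot_monomer_a - c$e_tot_monomer_b
}

#' Relative dimerization energy of a variant
#'
#' Variant-minus-native change in subunit dimerization energy; estimates
#' the damage a residue replacement does to channel assembly.
#' Antisymmetric under swapping the two arguments.
#'
#' @param variant,native \code{\link{energy_components}} for the variant
#'   and the native protein.
#' @return Relative dimerization energy in kcal/mol.
#' @export
relative_dimerization_energy <- function(variant, native) {
  dimerization_energy(variant) - dimerization_energy(native)
}

#' Per-calcium binding energy of the subunit dimer
#'
#' \code{0.5 * (E_tot(dimer+2Ca) - E_tot(dimer) - 2 * E_sol(Ca2+))}: the
#' energy of binding one Ca2+ ion from solution to the dimer.
#'
#' @param c An \code{\link{energy_components}} object with the calcium
#'   components present.
#' @return Calcium-binding energy in kcal/mol per ion.
#' @export
ca_binding_energy <- function(c) {
  stopifnot(inherits(c, "energy_components"))
  if (is.na(c$e_tot_dimer_2ca) || is.na(c$e_sol_ca))
    stop("calcium components missing for '", c$label, "'", call. = FALSE)
  (c$e_tot_dimer_2ca - c$e_tot_dimer - 2 * c$e_sol_ca) / 2
}

#' Relative calcium-binding energy of a variant
#'
#' Variant-minus-native change in the per-calcium binding energy of the
#' dimer; estimates altered calcium-dependent channel regulation.
#'
#' @inheritParams relative_dimerization_energy
#' @return Relative calcium-binding energy in kcal/mol.
#' @export
relative_ca_binding_energy <- function(variant, native) {
  ca_binding_energy(variant) - ca_binding_energy(native)
}

#' Read a component-energy table
#'
#' Reads a delimited table with columns \code{label}, \code{e_tot_dimer},
#' \code{e_tot_monomer_a}, \code{e_tot_monomer_b} and optionally
#' \code{e_tot_dimer_2ca}, \code{e_sol_ca}. One row must be labelled
#' \code{"native"} for relative energies to be computable.
#'
#' @inheritParams read_cohort
#' @return A named list of \code{\link{energy_components}} keyed by label.
#' @export
read_energy_components <- function(path, dec = ".", sep = ",") {
  dec <- match.arg(dec, c(".", ","))
  raw <- .read_delim_chr(path, sep = sep)
  mandatory <- c("label", "e_tot_dimer", "e_tot_monomer_a", "e_tot_monomer_b")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(col) if (col %in% names(raw))
    .parse_numeric(raw[[col]], dec, col) else rep(NA_real_, nrow(raw))
  e2ca <- num("e_tot_dimer_2ca"); esol <- num("e_sol_ca")
  out <- lapply(seq_len(nrow(raw)), function(i)
    energy_components(num("e_tot_dimer")[i], num("e_tot_monomer_a")[i],
                      num("e_tot_monomer_b")[i], e2ca[i], esol[i],
                      label = raw$label[i]))
  names(out) <- raw$label
  out
}

#' Derive a per-variant relative-energy table from raw components
#'
#' Evaluates the relative dimerization energy, and where calcium components
#' are present the relative calcium-binding energy, of every non-native
#' entry against the native one.
#'
#' @param components Named list from \code{\link{read_energy_components}}.
#' @param native_label Label of the native reference entry.
#' @return A data frame with columns \code{variant}, \code{dde_dim},
#'   \code{dde_cabin} (kcal/mol; \code{dde_cabin} missing where calcium
#'   components are absent).
#' @export
energy_table <- function(components, native_label = "native") {
  if (!native_label %in% names(components))
    stop("no component entry labelled '", native_label, "'", call. = FALSE)
  native <- components[[native_label]]
  variants <- components[setdiff(names(components), native_label)]
  rows <- lapply(variants, function(v) {
    cabin <- if (!is.na(v$e_tot_dimer_2ca) &&
                 !is.na(native$e_tot_dimer_2ca))
      relative_ca_binding_energy(v, native) else NA_real_
    data.frame(variant = v$label,
               dde_dim = relative_dimerization_energy(v, native),
               dde_cabin = cabin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
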