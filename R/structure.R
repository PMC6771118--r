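# Residue-location annotation on a multimeric channel structure.
#
# Reduced-scope reimplementation of the qualitative "location of variant
# residue" labels: a residue can sit at an inter-subunit interface, near a
# bound ion (Ca2+, K+, Cl-), on the pore wall (close to the channel's
# symmetry axis) or facing the membrane.  All cutoffs are explicit
# configuration; no published cutoffs exist, so the labels are qualitative
# guidance rather than a reproduction of any specific published table.

.ION_SPECIES <- c(CA = "Ca2+", K = "K+", CL = "Cl-")
.WATER_RESID <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SOL", "H2O")

# pairwise minimum distance between two coordinate matrices (rows = atoms)
.min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

.coords <- function(atoms, sel) {
  as.matrix(atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Load a multimeric channel structure
#'
#' Reads a PDB or mmCIF file via \pkg{bio3d}, drops waters and hydrogens,
#' collects bound ions (Ca2+, K+, Cl-; unknown single-atom het species are
#' ignored with a warning) and estimates the pore axis as the first
#' principal axis of the heavy-atom cloud, which approximates the
#' five-fold symmetry axis of the assembled channel without explicit
#' symmetry detection.
#'
#' @param path Path to a \code{.pdb} or \code{.cif} file.
#' @param membrane_band Optional length-2 numeric: the axial interval
#'   (Angstrom, along the pore axis relative to the centroid) spanned by
#'   the membrane; enables the membrane-facing label.
#' @return An object of class \code{channel_model}: \code{atoms} (heavy
#'   protein atoms with chain, residue number and coordinates),
#'   \code{ions} (species, coordinates, owning chain), \code{chains},
#'   \code{axis} (unit direction + anchor) and \code{membrane_band}.
#' @export
load_structure <- function(path, membrane_band = NULL) {
  if (!file.exists(path)) stop("cannot read structure: ", path,
                               call. = FALSE)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[!toupper(at$resid) %in% .WATER_RESID, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no atoms", call. = FALSE)
  hyd <- (!is.na(at$elesy) & toupper(at$elesy) == "H") |
    grepl("^[0-9]*H", at$elety)
  at <- at[!hyd, , drop = FALSE]
  at$chain[is.na(at$chain)] <- "A"

  is_ion <- toupper(at$resid) %in% names(.ION_SPECIES)
  unknown_het <- at$type == "HETATM" & !is_ion &
    !at$resid %in% bio3d::aa.table$aa3
  if (any(unknown_het)) {
    warning("ignoring unknown het species: ",
            paste(unique(at$resid[unknown_het]), collapse = ", "),
            call. = FALSE)
    at <- at[!unknown_het, , drop = FALSE]
    is_ion <- toupper(at$resid) %in% names(.ION_SPECIES)
  }
  ions <- data.frame(
    species = unname(.ION_SPECIES[toupper(at$resid[is_ion])]),
    x = at$x[is_ion], y = at$y[is_ion], z = at$z[is_ion],
    chain = at$chain[is_ion], stringsAsFactors = FALSE)
  prot <- at[!is_ion, c("chain", "resno", "resid", "elety", "x", "y", "z"),
             drop = FALSE]
  if (nrow(prot) == 0L) stop("structure contains no protein chains",
                             call. = FALSE)
  xyz <- as.matrix(prot[, c("x", "y", "z")])
  anchor <- colMeans(xyz)
  dir <- stats::prcomp(xyz, center = TRUE)$rotation[, 1]
  dir <- dir / sqrt(sum(dir^2))
  structure(
    list(atoms = prot, ions = ions,
         chains = sort(unique(prot$chain)),
         axis = list(direction = dir, anchor = anchor),
         membrane_band = membrane_band),
    class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("channel model: %d subunit(s) (%s), %d heavy atoms, %d ion(s)\n",
              length(x$chains), paste(x$chains, collapse = ","),
              nrow(x$atoms), nrow(x$ions)))
  invisible(x)
}

#' Residues of one chain at the interface to another
#'
#' A residue of \code{chain_a} is at the interface when any of its heavy
#' atoms lies within \code{cutoff} of any heavy atom of \code{chain_b}.
#' The relation is symmetric at equal cutoff: for every interface residue
#' of A there is a residue of B within the cutoff of it.
#'
#' @param model A \code{channel_model}.
#' @param chain_a,chain_b Chain identifiers present in the model.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5).
#' @return Data frame with columns \code{resno} and \code{min_dist}
#'   (possibly empty).
#' @export
interface_residues <- function(model, chain_a, chain_b, cutoff = 5) {
  stopifnot(inherits(model, "channel_model"))
  if (length(model$chains) < 2L)
    stop("interface queries need at least 2 subunits", call. = FALSE)
  for (ch in c(chain_a, chain_b))
    if (!ch %in% model$chains) stop("unknown chain id: ", ch, call. = FALSE)
  a <- model$atoms[model$atoms$chain == chain_a, , drop = FALSE]
  bxyz <- .coords(model$atoms, model$atoms$chain == chain_b)
  res <- sort(unique(a$resno))
  md <- vapply(res, function(r)
    .min_cross_dist(.coords(a, a$resno == r), bxyz), numeric(1))
  keep <- md <= cutoff & cutoff > 0
  data.frame(resno = res[keep], min_dist = md[keep])
}

#' Proximity of a residue to a bound ion species
#'
#' Minimum heavy-atom distance between a residue and the nearest ion of a
#' species, with the owning chain of that ion (the calcium clasps, for
#' instance, belong to the neighbouring subunit).
#'
#' @param model A \code{channel_model}.
#' @param chain,resno Chain id and residue number of the query residue.
#' @param species \code{"Ca2+"}, \code{"K+"} or \code{"Cl-"}.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return List with \code{applicable} (FALSE when the model holds no ion
#'   of the species), \code{within} (distance <= cutoff),
#'   \code{distance} and \code{ion_chain}.
#' @export
site_proximity <- function(model, chain, resno, species, cutoff = 8) {
  stopifnot(inherits(model, "channel_model"))
  species <- match.arg(species, unname(.ION_SPECIES))
  sel <- model$atoms$chain == chain & model$atoms$resno == resno
  if (!any(sel)) stop("residue ", chain, ":", resno, " not in model",
                      call. = FALSE)
  ion <- model$ions[model$ions$species == species, , drop = FALSE]
  if (nrow(ion) == 0L)
    return(list(applicable = FALSE, within = NA, distance = NA_real_,
                ion_chain = NA_character_))
  rxyz <- .coords(model$atoms, sel)
  d <- vapply(seq_len(nrow(ion)), function(i)
    .min_cross_dist(rxyz, as.matrix(ion[i, c("x", "y", "z")])), numeric(1))
  k <- which.min(d)
  list(applicable = TRUE, within = d[k] <= cutoff, distance = d[k],
       ion_chain = ion$chain[k])
}

#' Annotation cutoffs
#'
#' @param interface Heavy-atom interface cutoff, Angstrom.
#' @param ion Ion-proximity cutoff, Angstrom.
#' @param pore Maximum distance from the pore axis for the pore-lining
#'   label, Angstrom.
#' @return A named list of cutoffs.
#' @export
location_cutoffs <- function(interface = 5, ion = 8, pore = 12) {
  list(interface = interface, ion = ion, pore = pore)
}

#' Classify the structural location of a variant residue
#'
#' Unions the interface, ion-proximity, pore-axis and membrane-band tests
#' into a set of location labels for the residue a variant replaces.
#' Deterministic for a fixed configuration, and monotone in the cutoffs:
#' enlarging any cutoff never removes a label.
#'
#' @param model A \code{channel_model}.
#' @param variant A \code{protein_variant} (or a string parseable as one).
#' @param config Cutoffs from \code{\link{location_cutoffs}}.
#' @param chain Chain carrying the variant residue (default: first chain).
#' @return An object of class \code{residue_location}: \code{labels}
#'   (character vector drawn from \code{interface:<chain>},
#'   \code{near-Ca-site:<chain>}, \code{near-K-site:<chain>},
#'   \code{near-Cl-site}, \code{pore-lining}, \code{membrane-facing},
#'   \code{other}) and \code{distances} (named, Angstrom).
#' @export
classify_variant_location <- function(model, variant,
                                      config = location_cutoffs(),
                                      chain = NULL) {
  stopifnot(inherits(model, "channel_model"))
  if (is.character(variant)) variant <- parse_protein_variant(variant)
  if (is.null(chain)) chain <- model$chains[1]
  pos <- variant$position
  sel <- model$atoms$chain == chain & model$atoms$resno == pos
  if (!any(sel))
    stop(sprintf("residue %d is outside the modelled range of chain %s",
                 pos, chain), call. = FALSE)
  labels <- character(0)
  distances <- numeric(0)
  rxyz <- .coords(model$atoms, sel)

  for (other in setdiff(model$chains, chain)) {
    d <- .min_cross_dist(rxyz,
                         .coords(model$atoms, model$atoms$chain == other))
    distances[paste0("interface:", other)] <- d
    if (d <= config$interface)
      labels <- c(labels, paste0("interface:", other))
  }
  site_label <- c("Ca2+" = "near-Ca-site", "K+" = "near-K-site",
                  "Cl-" = "near-Cl-site")
  for (sp in unname(.ION_SPECIES)) {
    pr <- site_proximity(model, chain, pos, sp, config$ion)
    if (!pr$applicable) next
    lab <- if (sp == "Cl-") site_label[[sp]] else
      paste0(site_label[[sp]], ":", pr$ion_chain)
    distances[lab] <- pr$distance
    if (pr$within) labels <- c(labels, lab)
  }
  # distance from the pore axis: norm of the component orthogonal to it
  rel <- sweep(rxyz, 2, model$axis$anchor)
  axial <- rel %*% model$axis$direction
  radial <- sqrt(rowSums((rel - axial %*% t(model$axis$direction))^2))
  distances["pore-axis"] <- min(radial)
  if (min(radial) <= config$pore) labels <- c(labels, "pore-lining")
  if (!is.null(model$membrane_band)) {
    mid <- mean(axial)
    if (mid >= min(model$membrane_band) && mid <= max(model$membrane_band))
      labels <- c(labels, "membrane-facing")
  }
  if (!length(labels)) labels <- "other"
  structure(list(labels = labels, distances = distances,
                 chain = chain, resno = pos),
            class = "residue_location")
}

#' @export
print.residue_location <- function(x, ...) {
  cat(sprintf("residue %s:%d -> %s\n", x$chain, x$resno,
              paste(x$labels, collapse = "; ")))
  invisible(x)
}

#' Mechanistic reading of location labels
#'
#' Static lookup pairing each location label with the structural
#' consequence conventionally associated with it (interface residues with
#' channel formation and stability, calcium-site residues with channel
#' activation, and so on).
#'
#' @param labels Character vector of location labels.
#' @return Character vector of consequence phrases (deduplicated).
#' @export
location_consequences <- function(labels) {
  base <- sub(":.*$", "", labels)
  map <- c("interface" = "channel formation and stability",
           "near-Ca-site" = "channel activation",
           "near-K-site" = "channel pore shape",
           "near-Cl-site" = "chloride ion throughput or ion selectivity",
           "pore-lining" = "conformational changes, channel gating",
           "membrane-facing" = "channel embedding in cell membrane",
           "other" = "unassigned")
  unique(unname(map[base[base %in% names(map)]]))
}
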