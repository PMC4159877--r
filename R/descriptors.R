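## Conceptual-DFT reactivity descriptors from supplied molecular energies.
##
## All energies are heats of formation in kcal/mol, as produced by
## semi-empirical codes (PM6/PM7); no unit conversion is performed anywhere.

#' Default heat of formation of atomic hydrogen (kcal/mol)
#'
#' The standard semi-empirical heat of formation of the hydrogen atom, used
#' as the default E(H) term in [bde()].  Supply your own value when the
#' upstream calculation used a different reference.
#' @export
HYDROGEN_HOF <- 52.1

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("non-finite or non-numeric ", what, call. = FALSE)
  x
}

#' Ionization potential from total energies
#'
#' The (adiabatic) ionization potential is the energy of the
#' electron-abstracted species minus the energy of the parent molecule,
#' I = E(N-1) - E(N).
#'
#' @param e_cation Energy of the electron-abstracted radical, kcal/mol.
#' @param e_neutral Energy of the parent molecule, kcal/mol.
#' @return Ionization potential in kcal/mol (vectorised).
#' @export
#' @examples
#' ionization_potential(180.4, 12.3)  # 168.1
ionization_potential <- function(e_cation, e_neutral) {
  check_finite(e_cation, "e_cation")
  check_finite(e_neutral, "e_neutral")
  e_cation - e_neutral
}

#' Electron affinity from total energies
#'
#' A = E(N) - E(N+1): the energy released on adding an electron.
#'
#' @param e_neutral Energy of the parent molecule, kcal/mol.
#' @param e_anion Energy of the electron-added radical, kcal/mol.
#' @return Electron affinity in kcal/mol (vectorised).
#' @export
#' @examples
#' electron_affinity(12.3, -31.9)  # 44.2
electron_affinity <- function(e_neutral, e_anion) {
  check_finite(e_neutral, "e_neutral")
  check_finite(e_anion, "e_anion")
  e_neutral - e_anion
}

#' Full conceptual-DFT descriptor set for one or more energy records
#'
#' From the three total energies of a molecule (neutral, electron-abstracted,
#' electron-added) computes the seven reactivity descriptors:
#' ionization potential \eqn{I}, electron affinity \eqn{A}, chemical
#' hardness \eqn{\eta = (I-A)/2}, softness \eqn{S = 1/(2\eta)},
#' electronegativity \eqn{\chi = (I+A)/2}, chemical potential
#' \eqn{\mu = -\chi} and electrophilicity \eqn{\omega = \mu^2/(2\eta)}.
#'
#' When \eqn{\eta = 0} for a record, its softness and electrophilicity are
#' undefined; they are returned as \code{NA} with a warning rather than as
#' infinities, so that downstream correlation analysis cannot silently
#' ingest them.
#'
#' @param records A data frame with numeric columns \code{e_neutral},
#'   \code{e_cation} and \code{e_anion} (kcal/mol), one row per
#'   compound/form, e.g. as read by [read_energy_table()].  Identifier
#'   columns (\code{compound}, \code{form}, \code{method}) are carried
#'   through if present.
#' @return A data frame with the identifier columns (if any) and numeric
#'   columns \code{I}, \code{A}, \code{eta}, \code{S}, \code{chi},
#'   \code{mu}, \code{omega}.
#' @export
#' @examples
#' descriptor_set(data.frame(e_neutral = 0, e_cation = 100, e_anion = -60))
descriptor_set <- function(records) {
  records <- as.data.frame(records)
  need <- c("e_neutral", "e_cation", "e_anion")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  I <- ionization_potential(records$e_cation, records$e_neutral)
  A <- electron_affinity(records$e_neutral, records$e_anion)
  eta <- (I - A) / 2
  chi <- (I + A) / 2
  mu <- -chi
  S <- ifelse(eta != 0, 1 / (2 * eta), NA_real_)
  omega <- ifelse(eta != 0, mu^2 / (2 * eta), NA_real_)
  if (any(eta == 0))
    warning("hardness is zero for ", sum(eta == 0),
            " record(s); softness and electrophilicity set to NA")
  ids <- intersect(c("compound", "form", "method"), names(records))
  out <- cbind(records[ids],
               data.frame(I = I, A = A, eta = eta, S = S, chi = chi,
                          mu = mu, omega = omega))
  rownames(out) <- NULL
  out
}

#' Homolytic O-H bond dissociation energy
#'
#' BDE = E(A-O.) + E(H) - E(A-OH): the energy of the hydrogen-abstracted
#' phenoxyl radical plus that of the free hydrogen atom minus the parent.
#' A lower BDE marks a hydroxyl that donates its hydrogen more readily,
#' the elementary step of hydrogen-atom-transfer radical scavenging.
#'
#' @param e_parent Energy of the parent molecule E(A-OH), kcal/mol.
#' @param e_phenoxyl Energy of the phenoxyl radical E(A-O.), kcal/mol.
#' @param e_hydrogen Energy of the hydrogen atom E(H), kcal/mol; defaults
#'   to [HYDROGEN_HOF].
#' @return BDE in kcal/mol (vectorised).
#' @export
#' @examples
#' bde(11.12, 40.0)  # 80.98 with the default E(H)
bde <- function(e_parent, e_phenoxyl, e_hydrogen = HYDROGEN_HOF) {
  check_finite(e_parent, "e_parent")
  check_finite(e_phenoxyl, "e_phenoxyl")
  check_finite(e_hydrogen, "e_hydrogen")
  e_phenoxyl + e_hydrogen - e_parent
}

.OH_POSITIONS <- c("3", "5", "7", "3'", "4'", "5'")

#' Positions carrying a free hydroxyl
#'
#' Given a compound's substituent pattern, lists the ring positions with a
#' free OH, i.e. the positions for which a phenoxyl radical (and hence a
#' BDE) is defined.
#'
#' @inheritParams available_forms
#' @return Character vector, a subset of \code{c("3","5","7","3'","4'","5'")}.
#' @export
oh_positions <- function(compound) {
  compound <- as.list(compound)
  pos <- c("7", "4'")  # constitutive
  if (identical(compound$r3, "OH")) pos <- c(pos, "3")
  if (identical(compound$r4, "OH")) pos <- c(pos, "5")
  if (identical(compound$r1, "OH")) pos <- c(pos, "3'")
  if (identical(compound$r2, "OH")) pos <- c(pos, "5'")
  .OH_POSITIONS[.OH_POSITIONS %in% pos]
}

#' Lowest bond dissociation energy across hydroxyl positions
#'
#' Returns the position with the minimum BDE; this minimum is the standard
#' proxy for hydrogen-atom-transfer reactivity of a polyphenol.  Ties are
#' broken by ring-position order 3 < 5 < 7 < 3' < 4' < 5'.
#'
#' @param positions Character vector of OH position labels.
#' @param energies Numeric vector of BDEs (kcal/mol), parallel to
#'   \code{positions}.
#' @return A list with elements \code{position} and \code{bde}.
#' @export
#' @examples
#' bde_min(c("3", "5", "3'", "4'"), c(67.08, 75.5, 76.04, 72.44))
bde_min <- function(positions, energies) {
  if (length(positions) == 0L) stop("empty BDE list", call. = FALSE)
  if (length(positions) != length(energies))
    stop("positions and energies differ in length", call. = FALSE)
  check_finite(energies, "energies")
  ord <- order(energies, match(positions, .OH_POSITIONS))
  list(position = positions[ord[1L]], bde = energies[ord[1L]])
}

#' Read a molecular energy table
#'
#' Reads a delimited (tab or comma) file with header columns
#' \code{compound}, \code{form}, \code{method}, \code{e_neutral},
#' \code{e_cation}, \code{e_anion}; energies in kcal/mol.
#'
#' @param path File path.
#' @return Data frame of energy records.
#' @export
read_energy_table <- function(path) {
  tab <- read_table_auto(path)
  need <- c("compound", "form", "method", "e_neutral", "e_cation", "e_anion")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("energy table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("e_neutral", "e_cation", "e_anion"))
    check_finite(tab[[col]], col)
  tab
}

#' Extract the final heat of formation from a MOPAC-style output file
#'
#' Scans the text for the last \code{"FINAL HEAT OF FORMATION"} record and
#' returns its kcal/mol value.  This is a convenience adapter for feeding
#' semi-empirical program output into [read_energy_table()]-style records;
#' it never runs the external program.
#'
#' @param path Path to the output text file.
#' @return Heat of formation in kcal/mol.
#' @export
read_mopac_heat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  if (length(hits) == 0L)
    stop("no 'FINAL HEAT OF FORMATION' record in ", path, call. = FALSE)
  m <- regmatches(hits, regexpr("=\\s*(-?[0-9]+\\.?[0-9]*)\\s*KCAL/MOL",
                                hits))
  if (length(m) == 0L)
    stop("malformed heat-of-formation record in ", path, call. = FALSE)
  as.numeric(gsub("[=A-Z/ ]", "", m[length(m)]))
}

# Parses a feature id like "A_FC", "chi_FC", "I_QB7" into descriptor + form;
# "nOH" is the structural hydroxyl count.
parse_feature_id <- function(id) {
  if (id == "nOH") return(list(descriptor = "nOH", form = NA_character_))
  parts <- strsplit(id, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in%
        c("I", "A", "eta", "S", "chi", "mu", "omega") ||
      !parts[2L] %in% structural_forms())
    stop(sprintf(
      "malformed feature id '%s' (expected '<descriptor>_<form>' or 'nOH')",
      id), call. = FALSE)
  list(descriptor = parts[1L], form = parts[2L])
}

#' Assemble the per-compound feature table for QSAR modelling
#'
#' For each registry compound, pulls the requested descriptor/form pairs
#' from the energy records and appends the structural hydroxyl count.  The
#' default feature set is the electron affinity and electronegativity of
#' the flavylium cation, the ionization potential of the 7-quinoidal base,
#' and the hydroxyl count: \code{c("A_FC", "chi_FC", "I_QB7", "nOH")}.
#'
#' @param registry Compound registry data frame from [load_registry()].
#' @param energies Energy records with columns \code{compound}, \code{form},
#'   \code{method}, \code{e_neutral}, \code{e_cation}, \code{e_anion}.
#' @param method Which semi-empirical parameterisation to use, \code{"PM6"}
#'   or \code{"PM7"}.
#' @param features Character vector of feature ids,
#'   \code{"<descriptor>_<form>"} with descriptor in \code{I, A, eta, S,
#'   chi, mu, omega} and form in [structural_forms()], or \code{"nOH"}.
#' @return Data frame with rownames the compound names, one column per
#'   feature, rows in registry order.
#' @export
build_feature_table <- function(registry, energies, method = c("PM6", "PM7"),
                                features = c("A_FC", "chi_FC", "I_QB7",
                                             "nOH")) {
  method <- match.arg(method)
  parsed <- lapply(features, parse_feature_id)
  en <- energies[energies$method == method, , drop = FALSE]
  desc <- if (nrow(en)) descriptor_set(en) else en
  out <- matrix(NA_real_, nrow(registry), length(features),
                dimnames = list(registry$name, features))
  for (j in seq_along(features)) {
    p <- parsed[[j]]
    if (p$descriptor == "nOH") {
      out[, j] <- registry$n_oh
      next
    }
    for (i in seq_len(nrow(registry))) {
      if (!p$form %in% available_forms(registry[i, ]))
        stop(sprintf("form %s does not exist for compound '%s'",
                     p$form, registry$name[i]), call. = FALSE)
      k <- which(desc$compound == registry$name[i] & desc$form == p$form)
      if (length(k) == 0L)
        stop(sprintf("no %s energy record for compound '%s', form %s",
                     method, registry$name[i], p$form), call. = FALSE)
      out[i, j] <- desc[[p$descriptor]][k[1L]]
    }
  }
  as.data.frame(out)
}
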