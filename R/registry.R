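## Compound registry for the flavylium (anthocyanidin/anthocyanin) class.
##
## Substituent slots map to ring positions: r1 -> 3', r2 -> 5', r3 -> 3,
## r4 -> 5.  Positions 7 and 4' carry a hydroxyl in every compound of this
## class, so they are treated as constitutive.

.GLYCOSIDES <- c("glc", "gal", "ara", "rut", "sam", "coumaroyl-sam",
                 "glucoside", "galactoside", "arabinoside", "rutinoside",
                 "sambubioside", "coumaroyl-sambubioside")
.RING_CODES <- c("H", "OH", "OCH3")

#' The six structural forms of an anthocyanin
#'
#' Anthocyanins interconvert between six structures depending on pH: the
#' flavylium cation (\code{FC}, dominant below pH 2), three quinoidal bases
#' formed by deprotonation of the 4'-, 5- or 7-hydroxyl (\code{QB4p},
#' \code{QB5}, \code{QB7}), the hydrated carbinol pseudobase (\code{CP}) and
#' the ring-opened chalcone (\code{Ch}).
#'
#' @return Character vector of the six form codes.
#' @seealso [available_forms()] for which forms a given compound can adopt.
#' @export
#' @examples
#' structural_forms()
structural_forms <- function() {
  c("FC", "QB4p", "QB5", "QB7", "CP", "Ch")
}

is_glycoside <- function(code) code %in% .GLYCOSIDES

check_substituent <- function(code, slot, allow_glycoside = FALSE) {
  ok <- if (allow_glycoside) {
    code %in% c("OH", .GLYCOSIDES)
  } else {
    code %in% .RING_CODES
  }
  if (!all(ok)) {
    stop(sprintf("invalid substituent code %s in slot '%s'",
                 paste(sQuote(unique(code[!ok])), collapse = ", "), slot),
         call. = FALSE)
  }
  invisible(code)
}

#' Count hydroxyl groups on the flavonoid core
#'
#' Counts OH groups over the six positional slots 3, 5, 7, 3', 4', 5' given
#' the substituent pattern.  Positions 7 and 4' are hydroxylated in every
#' compound of this class and contribute a constant 2; positions 3 and 5
#' (slots \code{r3}, \code{r4}) contribute unless glycosylated; positions 3'
#' and 5' (slots \code{r1}, \code{r2}) contribute when they carry OH rather
#' than H or OCH3.
#'
#' @param r1,r2 Substituents at the 3'- and 5'-positions: \code{"H"},
#'   \code{"OH"} or \code{"OCH3"}.
#' @param r3,r4 Substituents at the 3- and 5-positions: \code{"OH"} or a
#'   glycoside label (\code{"glc"}, \code{"gal"}, \code{"ara"}, \code{"rut"},
#'   \code{"sam"}, \code{"coumaroyl-sam"}).
#' @return Integer vector of hydroxyl counts (vectorised over the inputs).
#' @export
#' @examples
#' count_hydroxyls("OH", "OH", "OH", "OH")   # delphinidin: 6
#' count_hydroxyls("H", "H", "glc", "OH")    # pelargonidin-3-glucoside: 3
count_hydroxyls <- function(r1, r2, r3, r4) {
  check_substituent(r1, "r1")
  check_substituent(r2, "r2")
  check_substituent(r3, "r3", allow_glycoside = TRUE)
  check_substituent(r4, "r4", allow_glycoside = TRUE)
  as.integer(2L + (r1 == "OH") + (r2 == "OH") + (r3 == "OH") + (r4 == "OH"))
}

#' Structural forms available to a compound
#'
#' A quinoidal base exists only when the corresponding position carries a
#' free (non-glycosylated) hydroxyl: a 5-glycosylated compound cannot form
#' the 5-quinoidal base \code{QB5}.  Positions 7 and 4' are constitutively
#' hydroxylated in this compound class, so \code{QB7} and \code{QB4p} are
#' always available, as are \code{FC}, \code{CP} and \code{Ch}.
#'
#' @param compound A single-row data frame or named list with at least the
#'   substituent fields \code{r3} and \code{r4} (as in the registry returned
#'   by [load_registry()]).
#' @return Character vector, a subset of [structural_forms()].
#' @export
#' @examples
#' reg <- load_registry()
#' available_forms(reg[reg$name == "cyanidin", ])
#' available_forms(reg[reg$name == "malvidin-3,5-diglucoside", ])  # no QB5
available_forms <- function(compound) {
  compound <- as.list(compound)
  if (is.null(compound$r3) || is.null(compound$r4))
    stop("'compound' must have substituent fields r3 and r4", call. = FALSE)
  forms <- structural_forms()
  # deprotonation-site rule, applied generically per quinoidal base
  site_free <- c(QB5 = compound$r4 == "OH",
                 QB7 = TRUE,    # 7-OH constitutive
                 QB4p = TRUE)   # 4'-OH constitutive
  drop <- names(site_free)[!unlist(site_free)]
  setdiff(forms, drop)
}

#' Load a compound registry
#'
#' Reads a tab- or comma-separated registry with header columns
#' \code{name}, \code{family}, \code{r1}, \code{r2}, \code{r3}, \code{r4}
#' and optionally \code{n_oh}.  Substituents use \code{"OH"}/\code{"H"}/
#' \code{"OCH3"}, and glycosides the abbreviated sugar names (\code{"glc"},
#' \code{"gal"}, \code{"ara"}, \code{"rut"}, \code{"sam"},
#' \code{"coumaroyl-sam"}).  The hydroxyl count is recomputed with
#' [count_hydroxyls()] and, when an \code{n_oh} column is present, checked
#' against it.  With no argument, the packaged registry of the 21 reference
#' anthocyanidins and anthocyanins is loaded.
#'
#' @param path Path to a registry file, or \code{NULL} for the packaged one.
#' @return A data frame with columns \code{name}, \code{family},
#'   \code{r1}--\code{r4} and the recomputed integer \code{n_oh}, one row
#'   per compound.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg)                                   # 21
#' table(reg$family)                           # 5 aglycones, 16 glycosides
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "anthocyanin_registry.tsv",
                        package = "anfisqsar", mustWork = TRUE)
  }
  reg <- read_table_auto(path)
  if (nrow(reg) == 0L) {
    return(data.frame(name = character(), family = character(),
                      r1 = character(), r2 = character(),
                      r3 = character(), r4 = character(),
                      n_oh = integer(), stringsAsFactors = FALSE))
  }
  need <- c("name", "family", "r1", "r2", "r3", "r4")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(reg$name)) {
    dup <- reg$name[duplicated(reg$name)][1L]
    stop(sprintf("duplicate compound name '%s' (row %d)",
                 dup, which(reg$name == dup)[2L]), call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    n <- tryCatch(
      count_hydroxyls(reg$r1[i], reg$r2[i], reg$r3[i], reg$r4[i]),
      error = function(e) stop(sprintf("registry row %d (%s): %s", i,
                                       reg$name[i], conditionMessage(e)),
                               call. = FALSE))
    if ("n_oh" %in% names(reg) && !is.na(reg$n_oh[i]) && reg$n_oh[i] != n)
      stop(sprintf(
        "registry row %d (%s): stated n_oh = %s but substituents imply %d",
        i, reg$name[i], reg$n_oh[i], n), call. = FALSE)
    reg$n_oh[i] <- n
    glyc <- is_glycoside(reg$r3[i]) || is_glycoside(reg$r4[i])
    fam_ok <- (reg$family[i] == "anthocyanin") == glyc
    if (!reg$family[i] %in% c("anthocyanidin", "anthocyanin") || !fam_ok)
      stop(sprintf(
        "registry row %d (%s): family '%s' inconsistent with glycosylation",
        i, reg$name[i], reg$family[i]), call. = FALSE)
  }
  reg$n_oh <- as.integer(reg$n_oh)
  reg
}

# Sniffs the delimiter (tab beats comma) from the header line.
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    return(data.frame())
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}
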