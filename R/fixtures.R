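## Packaged reference tables: the 21-compound registry, the experimental
## and model-predicted DPPH activities, and the per-position O-H bond
## dissociation energies, each shipped as plain delimited text with an
## MD5 manifest.

#' Packaged reference tables
#'
#' Returns the three reference tables shipped with the package:
#' \describe{
#'   \item{\code{registry}}{the 21 anthocyanidins/anthocyanins with their
#'     substituent pattern and hydroxyl count (see [load_registry()]);}
#'   \item{\code{activities}}{experimental DPPH radical scavenging
#'     activities (percent scavenged) and the PM6- and PM7-descriptor model
#'     predictions, one row per compound;}
#'   \item{\code{bde}}{phenolic O-H bond dissociation energies (kcal/mol)
#'     by compound, method, structural form and ring position, with the
#'     lowest-BDE flag per group.}
#' }
#' File integrity is checked against the packaged MD5 manifest on every
#' call.
#'
#' @return A list with data frames \code{registry}, \code{activities} and
#'   \code{bde}.
#' @export
#' @examples
#' fx <- qsar_fixtures()
#' fx$activities[fx$activities$name == "delphinidin", ]
qsar_fixtures <- function() {
  dir <- system.file("extdata", package = "anfisqsar", mustWork = TRUE)
  manifest <- read.delim(file.path(dir, "MANIFEST"), sep = "\t",
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    sum_i <- unname(tools::md5sum(file.path(dir, manifest$file[i])))
    if (!identical(sum_i, manifest$md5[i]))
      stop("packaged fixture ", manifest$file[i],
           " fails its checksum; reinstall the package", call. = FALSE)
  }
  list(registry = load_registry(),
       activities = read_table_auto(file.path(dir, "dpph_activities.tsv")),
       bde = read_table_auto(file.path(dir, "bde_table.tsv")))
}
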