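## Canonical Biolog EcoPlate substrate catalog and guild classification.
##
## The EcoPlate carries 31 carbon sources (x3 replicate blocks) plus water
## blanks. Guilds follow the conventional six-group classification used in
## community-level physiological profiling (carbohydrates, carboxylic acids,
## amino acids, polymers, amines, phenolic compounds).

.eco_substrates <- data.frame(
  substrate = c(
    "beta-Methyl-D-Glucoside", "D-Xylose", "i-Erythritol", "D-Mannitol",
    "N-Acetyl-D-Glucosamine", "D-Cellobiose", "Glucose-1-Phosphate",
    "alpha-D-Lactose", "D,L-alpha-Glycerol Phosphate",
    "Pyruvic Acid Methyl Ester", "D-Galactonic Acid gamma-Lactone",
    "D-Galacturonic Acid", "gamma-Hydroxybutyric Acid",
    "D-Glucosaminic Acid", "Itaconic Acid", "alpha-Ketobutyric Acid",
    "D-Malic Acid",
    "L-Arginine", "L-Asparagine", "L-Phenylalanine", "L-Serine",
    "L-Threonine", "Glycyl-L-Glutamic Acid",
    "Tween 40", "Tween 80", "alpha-Cyclodextrin", "Glycogen",
    "Phenylethyl-amine", "Putrescine",
    "2-Hydroxy Benzoic Acid", "4-Hydroxy Benzoic Acid"
  ),
  guild = c(
    rep("carbohydrates", 9L),
    rep("carboxylic_acids", 8L),
    rep("amino_acids", 6L),
    rep("polymers", 4L),
    rep("amines", 2L),
    rep("phenolic_compounds", 2L)
  ),
  stringsAsFactors = FALSE
)

#' Canonical EcoPlate substrate catalog
#'
#' The 31 named carbon sources of a Biolog EcoPlate together with their
#' conventional six-guild classification (carbohydrates, carboxylic acids,
#' amino acids, polymers, amines, phenolic compounds). The water blank is
#' not part of the catalog; blank wells are identified by the substrate
#' name \code{"Water"}.
#'
#' @return A data frame with columns \code{substrate} and \code{guild}
#'   (31 rows).
#' @examples
#' nrow(eco_substrates())  # 31
#' table(eco_substrates()$guild)
#' @export
eco_substrates <- function() .eco_substrates

#' Normalize a substrate name for matching
#'
#' Matching against the catalog is case-insensitive and
#' punctuation-normalized: Greek letters are transliterated
#' (\eqn{\alpha}/\eqn{\beta}/\eqn{\gamma} to alpha/beta/gamma), and all
#' non-alphanumeric characters are removed.
#'
#' @param x character vector of substrate names.
#' @return normalized character vector.
#' @examples
#' normalize_substrate("a-Ketobutyric Acid")  # not matched: spell out alpha
#' normalize_substrate("Alpha-Ketobutyric acid") == normalize_substrate(
#'   "alpha-Ketobutyric Acid")
#' @export
normalize_substrate <- function(x) {
  x <- gsub("α", "alpha", x)
  x <- gsub("β", "beta", x)
  x <- gsub("γ", "gamma", x)
  x <- tolower(x)
  gsub("[^a-z0-9]", "", x)
}

## Map arbitrary substrate spellings onto catalog names; NA where unmatched.
match_substrate <- function(x) {
  idx <- match(normalize_substrate(x), normalize_substrate(.eco_substrates$substrate))
  .eco_substrates$substrate[idx]
}

is_blank_substrate <- function(x) normalize_substrate(x) == "water"

#' C- and N-cycling marker gene identifiers
#'
#' The twelve functional genes tracked by the pipeline: carbon fixation
#' (\code{cbbL}, \code{porA}, \code{accA}, \code{oorA}), methane metabolism
#' (\code{mcrA}, \code{pmoA}), nitrogen fixation (\code{nifH}),
#' nitrification (\code{nxrA}), denitrification (\code{nirK}, \code{nirS},
#' \code{nosZ}) and assimilatory nitrate reduction (\code{nirA}).
#'
#' @return named list with components \code{carbon} and \code{nitrogen}.
#' @export
cn_cycle_genes <- function() {
  list(
    carbon   = c("mcrA", "pmoA", "cbbL", "porA", "accA", "oorA"),
    nitrogen = c("nirA", "nirK", "nosZ", "nxrA", "nirS", "nifH")
  )
}

#' CAZy family aggregate identifiers
#'
#' The six carbohydrate-active enzyme classes: glycoside hydrolases (GH),
#' glycosyl transferases (GT), polysaccharide lyases (PL), carbohydrate
#' esterases (CE), auxiliary activities (AA), carbohydrate-binding modules
#' (CBM).
#'
#' @return character vector of length 6.
#' @export
cazy_families <- function() c("GH", "GT", "PL", "CE", "AA", "CBM")
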