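#' Species covered by the cross-species phenotype framework
#'
#' Returns the reference table of the five species the framework harmonizes:
#' human, mouse, zebrafish, fruit fly and roundworm. `age_rank` orders the
#' four model organisms by the evolutionary distance of their last common
#' ancestor with mouse (1 = roundworm, most distant; 4 = mouse). Human carries
#' `NA` because conservation dating is defined over the model organisms only.
#'
#' @return A tibble with columns `species`, `taxon_id`, `prefix` (the
#'   diagnostic phenotype-ontology code prefix for the species) and
#'   `age_rank`.
#' @export
#' @examples
#' como_species()
como_species <- function() {
  tibble::tibble(
    species  = c("human", "mouse", "zebrafish", "fly", "worm"),
    taxon_id = c(9606L, 10090L, 7955L, 7227L, 6239L),
    prefix   = c("HP:", "MP:", "ZP:", "FBcv:", "WBPhenotype:"),
    age_rank = c(NA_integer_, 4L, 3L, 2L, 1L)
  )
}

species_codes <- function() como_species()$species

#' Unified phenotype categories
#'
#' The 19 unified phenotype categories: the 18 whole-body categories used by
#' aggregate model-organism databases plus the additive `Fertility` category
#' that collects all reproduction-related terms. `Fertility` is deliberately
#' distinct from `Genitourinary`: a fertility term counts into both (see
#' [categorize_term()]).
#'
#' @param base_only If `TRUE`, return only the 18 base categories.
#' @return Character vector of category names, in canonical order.
#' @export
#' @examples
#' mcat_categories()
mcat_categories <- function(base_only = FALSE) {
  base <- c(
    "Prenatal Development or Birth", "Growth Abnormality", "Nervous System",
    "Eye and Ear", "Integument", "Head and Neck", "Limb/appendage",
    "Skeletal and Connective Tissue", "Blood and Immune", "Cardiovascular",
    "Musculature", "Respiratory", "Digestive", "Genitourinary", "Endocrine",
    "Metabolism", "Neoplasm", "Other"
  )
  if (base_only) base else c(base, "Fertility")
}

#' Reproductive phenotype groups
#'
#' The fertility side of the two-part ontology is subdivided into 13 broad
#' reproductive groups (meiosis, gametogenesis, fertilization, ...). The group
#' vocabulary is configuration rather than a fixed enum: curated term tables
#' may carry their own labels, as long as there are exactly 13 of them and
#' every fertility term maps to exactly one. This function returns the
#' package's default vocabulary.
#'
#' @return Character vector of 13 group labels.
#' @export
default_repro_groups <- function() {
  c(
    "DNA/cell division defects", "meiosis", "gametogenesis",
    "gonad/urogenital development", "quantitative sperm defect",
    "sperm morphology", "sperm motility", "testis function", "fertilization",
    "mating/reproductive behavior", "oogenesis",
    "general male infertility", "general female infertility"
  )
}

#' Default species-by-category applicability mask
#'
#' Not every category is phenotyped in every species: zebrafish fertility
#' codes are not exposed by the aggregate source, and the eye-and-ear category
#' is not phenotyped in roundworm. The default mask marks those two pairs
#' untestable and everything else (in particular the whole mouse row)
#' testable.
#'
#' @return A tibble with columns `species`, `category`, `testable` (logical),
#'   one row per species-category pair.
#' @seealso [load_mask()] to read a mask from a TSV file.
#' @export
#' @examples
#' dplyr::filter(default_mask(), !testable)
default_mask <- function() {
  m <- tidyr::expand_grid(species = species_codes(), category = mcat_categories())
  m$testable <- !((m$species == "zebrafish" & m$category == "Fertility") |
                    (m$species == "worm" & m$category == "Eye and Ear"))
  validate_mask(m)
}

validate_mask <- function(mask) {
  need <- tidyr::expand_grid(species = species_codes(), category = mcat_categories())
  key <- paste(mask$species, mask$category, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate species/category pair in mask", call. = FALSE)
  missing <- setdiff(paste(need$species, need$category, sep = "\r"), key)
  if (length(missing) > 0) {
    stop("mask is missing species/category pairs, e.g. ",
         gsub("\r", " / ", missing[1]), call. = FALSE)
  }
  extra <- setdiff(key, paste(need$species, need$category, sep = "\r"))
  if (length(extra) > 0) {
    stop("mask has unknown species/category pairs, e.g. ",
         gsub("\r", " / ", extra[1]), call. = FALSE)
  }
  if (!is.logical(mask$testable) || anyNA(mask$testable)) {
    stop("mask 'testable' must be logical and complete", call. = FALSE)
  }
  tibble::as_tibble(mask[c("species", "category", "testable")])
}

mask_lookup <- function(mask, species, category) {
  mask$testable[mask$species == species & mask$category == category]
}
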