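#' Load a cross-species phenotype term map
#'
#' Reads the curated two-part ontology table: each species-specific phenotype
#' ontology term is mapped to one of the 18 base categories, flagged as a
#' fertility term or not, and — when it is a fertility term — assigned to one
#' of the 13 reproductive groups. The table is a flat TSV, not an OBO file;
#' no ontology-graph reasoning (subsumption closure) is performed.
#'
#' @param path Path to a tab-delimited file with header columns `term_id`,
#'   `species`, `label`, `base_category`, `is_fertility` (0/1),
#'   `repro_group` (empty for non-fertility terms).
#' @param repro_groups Allowed reproductive-group vocabulary; defaults to
#'   [default_repro_groups()]. Must have exactly 13 labels.
#' @return A validated term-map tibble with columns `term_id`, `species`,
#'   `label`, `base_category`, `is_fertility` (logical), `repro_group`.
#' @export
load_term_map <- function(path, repro_groups = default_repro_groups()) {
  tm <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("term_id", "species", "label", "base_category", "is_fertility", "repro_group")
  if (!all(need %in% names(tm))) {
    stop("term map is missing columns: ", paste(setdiff(need, names(tm)), collapse = ", "),
         call. = FALSE)
  }
  tm <- tm[need]
  tm$is_fertility <- as.logical(as.integer(tm$is_fertility))
  tm$repro_group[!is.na(tm$repro_group) & tm$repro_group %in% c("", "-", "–")] <- NA_character_
  validate_term_map(tm, repro_groups)
}

validate_term_map <- function(tm, repro_groups = default_repro_groups()) {
  if (length(repro_groups) != 13L) {
    stop("reproductive-group vocabulary must have exactly 13 labels", call. = FALSE)
  }
  tm <- tibble::as_tibble(tm)
  if (nrow(tm) == 0) return(tm)

  dup <- unique(tm$term_id[duplicated(tm$term_id)])
  if (length(dup) > 0) {
    # identical duplicate rows collapse; conflicting mappings are an error
    conflict <- dup[vapply(dup, function(id) {
      nrow(unique(tm[tm$term_id == id, setdiff(names(tm), "label")])) > 1L
    }, logical(1))]
    if (length(conflict) > 0) {
      stop("conflicting mappings for term(s): ", paste(conflict, collapse = ", "),
           call. = FALSE)
    }
    tm <- tm[!duplicated(tm$term_id), ]
  }

  bad_sp <- setdiff(unique(tm$species), species_codes())
  if (length(bad_sp) > 0) stop("unknown species: ", paste(bad_sp, collapse = ", "), call. = FALSE)

  sp <- como_species()
  pref <- stats::setNames(sp$prefix, sp$species)
  ok <- startsWith(tm$term_id, pref[tm$species])
  if (!all(ok)) {
    stop("term id prefix inconsistent with species for: ",
         paste(utils::head(tm$term_id[!ok], 3), collapse = ", "), call. = FALSE)
  }

  bad_cat <- setdiff(unique(tm$base_category), mcat_categories(base_only = TRUE))
  if (length(bad_cat) > 0) {
    stop("unknown base category label: ", paste(bad_cat, collapse = "; "), call. = FALSE)
  }
  if (anyNA(tm$is_fertility)) stop("is_fertility must be 0/1", call. = FALSE)
  miss_grp <- tm$is_fertility & is.na(tm$repro_group)
  if (any(miss_grp)) {
    stop("fertility term(s) without a reproductive group: ",
         paste(utils::head(tm$term_id[miss_grp], 3), collapse = ", "), call. = FALSE)
  }
  bad_grp <- setdiff(unique(tm$repro_group[tm$is_fertility]), repro_groups)
  if (length(bad_grp) > 0) {
    stop("unknown reproductive group: ", paste(bad_grp, collapse = "; "), call. = FALSE)
  }
  tm
}

#' Write a term map back to TSV
#'
#' Inverse of [load_term_map()]; `load_term_map(write_term_map(tm, f))`
#' reproduces `tm` up to row order.
#'
#' @param term_map A term-map tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(term_map, path) {
  out <- term_map
  out$is_fertility <- as.integer(out$is_fertility)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Map a phenotype term to its unified categories
#'
#' A non-fertility term maps to its single base category. A fertility term is
#' counted additively: it maps to both its base category and `Fertility`, so
#' neither the whole-body signal nor the reproductive signal is lost. Terms
#' absent from the map yield an empty vector with a warning.
#'
#' @param term_id Ontology term code (e.g. `"HP:0000119"`).
#' @param term_map A term map from [load_term_map()].
#' @return Character vector of 0, 1 or 2 category names.
#' @export
#' @examples
#' tm <- tibble::tibble(
#'   term_id = "FBcv:0000431", species = "fly",
#'   label = "meiotic cell cycle defective", base_category = "Genitourinary",
#'   is_fertility = TRUE, repro_group = "gametogenesis"
#' )
#' categorize_term("FBcv:0000431", tm)
categorize_term <- function(term_id, term_map) {
  i <- match(term_id, term_map$term_id)
  if (is.na(i)) {
    warning("unmapped term: ", term_id, call. = FALSE)
    return(character(0))
  }
  base <- term_map$base_category[i]
  if (isTRUE(term_map$is_fertility[i])) c(base, "Fertility") else base
}

#' Count fertility terms by species and reproductive group
#'
#' Tabulates how many distinct fertility terms each species' ontology
#' contributes to each of the 13 reproductive groups (the vocabulary-size
#' comparison across species). Each term counts once; summing a species' row
#' over groups gives that species' total number of fertility terms.
#'
#' @param terms A data frame with columns `term_id` and `species` (extra
#'   columns ignored); typically the term map itself, or a set of observed
#'   annotation terms.
#' @param term_map A term map from [load_term_map()].
#' @return A tibble `species` x `repro_group` with a `n` count column, one
#'   row per species-group pair (all pairs present, zero-filled).
#' @export
count_terms_by_group <- function(terms, term_map) {
  stopifnot(all(c("term_id", "species") %in% names(terms)))
  bad <- setdiff(unique(terms$species), species_codes())
  if (length(bad) > 0) stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  groups <- sort(unique(term_map$repro_group[term_map$is_fertility]))
  grid <- tidyr::expand_grid(species = species_codes(), repro_group = groups)
  if (nrow(terms) == 0 || length(groups) == 0) {
    grid$n <- 0L
    return(grid)
  }
  obs <- tibble::tibble(term_id = unique(terms$term_id)) |>
    dplyr::inner_join(term_map, by = "term_id") |>
    dplyr::filter(.data$is_fertility) |>
    dplyr::count(.data$species, .data$repro_group)
  dplyr::left_join(grid, obs, by = c("species", "repro_group")) |>
    dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))
}

#' Load a species-by-category applicability mask from TSV
#'
#' The file has one row per species and one 0/1 column per category (plus the
#' leading `species` column); 1 means the category is phenotyped/testable in
#' that species.
#'
#' @param path Path to the mask TSV.
#' @return A long mask tibble (`species`, `category`, `testable`).
#' @seealso [default_mask()]
#' @export
load_mask <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(), .default = readr::col_integer()
  ))
  if (!"species" %in% names(wide)) stop("mask file needs a 'species' column", call. = FALSE)
  long <- tidyr::pivot_longer(wide, -"species",
                              names_to = "category", values_to = "testable")
  long$testable <- long$testable > 0L
  validate_mask(long)
}

#' @rdname load_mask
#' @param mask A long mask tibble.
#' @export
write_mask <- function(mask, path) {
  wide <- validate_mask(mask) |>
    dplyr::mutate(testable = as.integer(.data$testable)) |>
    tidyr::pivot_wider(names_from = "category", values_from = "testable")
  readr::write_tsv(wide, path)
  invisible(path)
}
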