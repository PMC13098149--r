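#' Build a gene's cross-species phenotype-count profile
#'
#' Counts, for one gene and each species, how many distinct mapped phenotype
#' terms fall in each of the 19 unified categories. Duplicate
#' (species, term) annotations are deduplicated before counting — the unit of
#' counting is the phenotype term, not the allele. Fertility terms count into
#' both their base category and `Fertility` (additive rule). Categories
#' masked untestable for a species are forced to zero. Unmapped terms are
#' dropped with one summary warning.
#'
#' @param gene Source (mouse) gene symbol.
#' @param records Annotation records for this gene (tibble with `species`,
#'   `term_id`), e.g. from [parse_payload()].
#' @param term_map Term map from [load_term_map()].
#' @param mask Applicability mask; defaults to [default_mask()].
#' @param presence Optional tibble `species`, `ortholog_present`; defaults to
#'   marking present exactly the species with >= 1 record.
#' @return A tibble with one row per species: `gene`, `species`,
#'   `ortholog_present`, `n_raw_annotations`, then the 19 category count
#'   columns. Species without an ortholog have all-zero counts and
#'   `ortholog_present = FALSE` (missing, not observed-zero).
#' @export
build_profile <- function(gene, records, term_map, mask = default_mask(),
                          presence = NULL) {
  cats <- mcat_categories()
  if (is.null(presence)) {
    presence <- tibble::tibble(species = species_codes(),
                               ortholog_present = species_codes() %in% records$species)
  }
  if (nrow(records) > 0 && "source_gene" %in% names(records) &&
      !all(records$source_gene == gene)) {
    stop("records for a different gene passed to build_profile", call. = FALSE)
  }
  rec <- dplyr::distinct(tibble::as_tibble(records)[c("species", "term_id")])
  hit <- dplyr::inner_join(rec, term_map[c("term_id", "base_category", "is_fertility")],
                           by = "term_id")
  n_unmapped <- nrow(rec) - nrow(hit)
  if (n_unmapped > 0) {
    warning(n_unmapped, " unmapped term(s) dropped for gene ", gene, call. = FALSE)
  }
  long <- dplyr::bind_rows(
    dplyr::count(hit, .data$species, category = .data$base_category),
    hit |> dplyr::filter(.data$is_fertility) |>
      dplyr::count(.data$species, category = "Fertility")
  )
  counts <- matrix(0L, nrow = length(species_codes()), ncol = length(cats),
                   dimnames = list(species_codes(), cats))
  if (nrow(long) > 0) {
    counts[cbind(long$species, long$category)] <- as.integer(long$n)
  }
  # apply mask and ortholog presence
  untestable <- mask[!mask$testable, ]
  counts[cbind(untestable$species, untestable$category)] <- 0L
  pres <- presence$ortholog_present[match(species_codes(), presence$species)]
  counts[!pres, ] <- 0L
  n_raw <- as.integer(table(factor(rec$species, levels = species_codes())))
  n_raw[!pres] <- 0L
  out <- tibble::tibble(gene = gene, species = species_codes(),
                        ortholog_present = pres, n_raw_annotations = n_raw)
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

#' Assemble per-gene profiles and genome backgrounds into a profile matrix
#'
#' The profile matrix is the pipeline's central object: a long gene x species
#' table of 19-category phenotype counts with ortholog-presence flags, plus a
#' per-species genome background (number of genes with a mouse ortholog, and
#' how many of those carry >= 1 phenotype in each category).
#'
#' @param profiles A list of per-gene profile tibbles from [build_profile()],
#'   or one row-bound tibble of them.
#' @param background A tibble with one row per species: `species`,
#'   `genome_size`, then the 19 category columns giving the number of genes
#'   (in the mouse-ortholog universe) with >= 1 phenotype in that category.
#' @param mask Applicability mask recorded alongside (default [default_mask()]).
#' @return An object of class `como_matrix`: a list with elements `profiles`,
#'   `background`, `mask`, `categories`.
#' @export
assemble_matrix <- function(profiles, background, mask = default_mask()) {
  if (is.data.frame(profiles)) prof <- tibble::as_tibble(profiles)
  else prof <- purrr::list_rbind(profiles)
  cats <- mcat_categories()
  need <- c("gene", "species", "ortholog_present", "n_raw_annotations", cats)
  if (!all(need %in% names(prof))) {
    stop("profiles are missing columns: ",
         paste(utils::head(setdiff(need, names(prof)), 3), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(prof[c("gene", "species")])) {
    dup <- prof$gene[duplicated(prof[c("gene", "species")])][1]
    stop("duplicate gene in profiles: ", dup, call. = FALSE)
  }
  prof <- dplyr::arrange(prof[need], .data$gene, match(.data$species, species_codes()))
  bg <- tibble::as_tibble(background)
  if (!all(c("species", "genome_size", cats) %in% names(bg))) {
    stop("background is missing species/genome_size/category columns", call. = FALSE)
  }
  bg <- bg[match(species_codes(), bg$species), c("species", "genome_size", cats)]
  if (anyNA(bg$species)) stop("background must cover all five species", call. = FALSE)
  over <- which(as.matrix(bg[cats]) > bg$genome_size, arr.ind = TRUE)
  if (length(over) > 0) stop("background category count exceeds genome size", call. = FALSE)
  structure(list(profiles = prof, background = bg, mask = validate_mask(mask),
                 categories = cats),
            class = "como_matrix")
}

#' @export
print.como_matrix <- function(x, ...) {
  ng <- length(unique(x$profiles$gene))
  cat("<como_matrix> ", ng, " genes x ", length(species_codes()), " species x ",
      length(x$categories), " categories\n", sep = "")
  pres <- x$profiles |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(orthologs = sum(.data$ortholog_present))
  for (i in seq_len(nrow(pres))) {
    cat(sprintf("  %-9s %d orthologs (genome background %d)\n", pres$species[i],
                pres$orthologs[i],
                x$background$genome_size[x$background$species == pres$species[i]]))
  }
  invisible(x)
}

#' Extract a gene x category count matrix for one species
#'
#' @param matrix A `como_matrix`.
#' @param species Species code.
#' @param present_only Keep only genes with an ortholog in that species.
#' @return A numeric matrix, genes in rows (lexicographic), 19 categories in
#'   columns.
#' @export
species_counts <- function(matrix, species, present_only = TRUE) {
  p <- matrix$profiles[matrix$profiles$species == species, ]
  if (present_only) p <- p[p$ortholog_present, ]
  m <- as.matrix(p[matrix$categories])
  rownames(m) <- p$gene
  storage.mode(m) <- "double"
  m
}

#' Fraction of seed-gene orthologs linked to a fertility phenotype
#'
#' For each species, the fraction of the seed genes *with an ortholog
#' present there* that carry at least one `Fertility`-category phenotype
#' (in mouse every seed gene is present, so the denominator is the full
#' seed list). For species where `Fertility` is masked untestable
#' (zebrafish under the default mask), the `Genitourinary` category
#' substitutes and the row is flagged via `proxy_category`.
#'
#' @param matrix A `como_matrix`.
#' @return A tibble: `species`, `n_linked`, `n_orthologs`, `n_seed`,
#'   `fraction` (= `n_linked / n_orthologs`), `proxy_category` (`NA` when
#'   `Fertility` itself was used).
#' @export
summarize_fertility_linkage <- function(matrix) {
  prof <- matrix$profiles
  n_seed <- length(unique(prof$gene))
  if (n_seed == 0) stop("empty profile matrix", call. = FALSE)
  purrr::map(species_codes(), function(s) {
    cat_use <- if (isTRUE(mask_lookup(matrix$mask, s, "Fertility"))) "Fertility"
    else "Genitourinary"
    rows <- prof[prof$species == s & prof$ortholog_present, ]
    n_linked <- sum(rows[[cat_use]] >= 1)
    tibble::tibble(species = s, n_linked = n_linked, n_orthologs = nrow(rows),
                   n_seed = n_seed,
                   fraction = if (nrow(rows) > 0) n_linked / nrow(rows) else NA_real_,
                   proxy_category = if (cat_use == "Fertility") NA_character_ else cat_use)
  }) |> purrr::list_rbind()
}

#' Write / read a profile matrix in long TSV form
#'
#' @param matrix A `como_matrix`.
#' @param path Output TSV path (profiles); the background is written next to
#'   it with suffix `"_background.tsv"` unless `background_path` is given.
#' @param background_path Optional explicit background output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path, background_path = NULL) {
  readr::write_tsv(matrix$profiles, path)
  bp <- background_path %||% sub("(\\.tsv)?$", "_background.tsv", path)
  readr::write_tsv(matrix$background, bp)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#'
#' @param path Profiles TSV (long format: gene, species, ortholog_present,
#'   n_raw_annotations, 19 count columns).
#' @param background_path Background TSV; defaults to the
#'   `"_background.tsv"` sibling of `path`.
#' @param mask Applicability mask (default [default_mask()]).
#' @return A `como_matrix`.
#' @export
read_profile_matrix <- function(path, background_path = NULL,
                                mask = default_mask()) {
  prof <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), species = readr::col_character(),
    ortholog_present = readr::col_logical(), .default = readr::col_integer()
  ))
  bp <- background_path %||% sub("(\\.tsv)?$", "_background.tsv", path)
  bg <- readr::read_tsv(bp, col_types = readr::cols(
    species = readr::col_character(), .default = readr::col_integer()
  ))
  assemble_matrix(prof, bg, mask)
}

#' Load per-species genome background tables
#'
#' Each file lists the species' genes with a `has_mouse_ortholog` 0/1 flag
#' and one 0/1 indicator column per category (>= 1 phenotype in that
#' category). Genes without a mouse ortholog are excluded from the universe
#' and from the per-category counts.
#'
#' @param paths Named character vector, species code -> background TSV path.
#' @return A background tibble suitable for [assemble_matrix()].
#' @export
load_background <- function(paths) {
  stopifnot(!is.null(names(paths)), all(names(paths) %in% species_codes()))
  purrr::imap(paths, function(p, s) {
    d <- readr::read_tsv(p, col_types = readr::cols(
      gene_id = readr::col_character(), .default = readr::col_integer()
    ))
    if (!all(c("gene_id", "has_mouse_ortholog") %in% names(d))) {
      stop("background for ", s, " needs gene_id and has_mouse_ortholog", call. = FALSE)
    }
    d <- d[d$has_mouse_ortholog > 0, ]
    cats <- intersect(mcat_categories(), names(d))
    if (length(cats) != length(mcat_categories())) {
      stop("background for ", s, " is missing category indicator columns", call. = FALSE)
    }
    out <- tibble::tibble(species = s, genome_size = nrow(d))
    dplyr::bind_cols(out, tibble::as_tibble(as.list(colSums(d[cats]))))
  }) |> purrr::list_rbind()
}
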