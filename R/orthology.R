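#' Load an ortholog prediction table
#'
#' Reads integrative ortholog predictions (DIOPT-style scores collapsed into
#' high/moderate/low confidence tiers) from TSV. Confidence tiers are taken
#' from the table, not recomputed from raw scores.
#'
#' @param path TSV with columns `source_gene`, `target_species`,
#'   `target_symbol`, `target_id`, `diopt_score`, `confidence`, `is_best`.
#' @return A validated ortholog tibble.
#' @export
load_orthologs <- function(path) {
  ort <- readr::read_tsv(path, col_types = readr::cols(
    source_gene = readr::col_character(),
    target_species = readr::col_character(),
    target_symbol = readr::col_character(),
    target_id = readr::col_integer(),
    diopt_score = readr::col_integer(),
    confidence = readr::col_character(),
    is_best = readr::col_logical()
  ))
  validate_orthologs(ort)
}

validate_orthologs <- function(ort) {
  need <- c("source_gene", "target_species", "target_symbol", "target_id",
            "diopt_score", "confidence", "is_best")
  if (!all(need %in% names(ort))) {
    stop("ortholog table is missing columns: ",
         paste(setdiff(need, names(ort)), collapse = ", "), call. = FALSE)
  }
  if (any(ort$target_species == "mouse")) {
    stop("ortholog records must target a species other than mouse", call. = FALSE)
  }
  bad <- setdiff(unique(ort$target_species), species_codes())
  if (length(bad) > 0) stop("unknown target species: ", paste(bad, collapse = ", "), call. = FALSE)
  bad_conf <- setdiff(unique(ort$confidence), c("high", "moderate", "low"))
  if (length(bad_conf) > 0) {
    stop("unknown confidence tier: ", paste(bad_conf, collapse = ", "), call. = FALSE)
  }
  if (any(ort$diopt_score < 0, na.rm = TRUE)) stop("diopt_score must be >= 0", call. = FALSE)
  tibble::as_tibble(ort)
}

confidence_rank <- function(x) match(x, c("low", "moderate", "high"))

#' Filter ortholog predictions by confidence
#'
#' Keeps records at or above the requested confidence tier, optionally also
#' requiring the "best"-scoring prediction flag. Input row order is
#' preserved; the operation is idempotent.
#'
#' @param orthologs Ortholog tibble (see [load_orthologs()]).
#' @param min_confidence `"moderate"` (default; the tier used for the main
#'   cross-species analyses) or `"high"`.
#' @param best_only If `TRUE`, additionally require `is_best`.
#' @return The filtered ortholog tibble.
#' @export
filter_orthologs <- function(orthologs, min_confidence = c("moderate", "high"),
                             best_only = FALSE) {
  min_confidence <- match.arg(min_confidence)
  keep <- confidence_rank(orthologs$confidence) >= confidence_rank(min_confidence)
  if (best_only) keep <- keep & orthologs$is_best
  orthologs[keep, , drop = FALSE]
}

#' Assign each gene its oldest conserved species
#'
#' Traces each source (mouse) gene to the most evolutionarily distant model
#' organism in which it retains an ortholog among the supplied
#' (already confidence-filtered) records, in the order roundworm, fruit fly,
#' zebrafish; genes with no non-mammalian ortholog are labelled mouse. Human
#' does not participate in conservation dating. Adding records can only move
#' a gene's label to an older species.
#'
#' @param genes Character vector of source gene symbols to classify.
#' @param orthologs Confidence-filtered ortholog tibble.
#' @return A tibble with columns `gene` and `oldest_species`.
#' @export
assign_oldest_species <- function(genes, orthologs) {
  sp <- como_species()
  ranked <- sp$species[order(sp$age_rank)]
  ranked <- ranked[!is.na(sp$age_rank[order(sp$age_rank)])]        # worm fly zebrafish mouse
  ranked <- setdiff(ranked, "mouse")
  if (is.null(orthologs$target_species) || nrow(orthologs) == 0) {
    return(tibble::tibble(gene = genes,
                          oldest_species = rep("mouse", length(genes))))
  }
  ort <- orthologs[orthologs$target_species %in% ranked, ]
  rk <- match(ort$target_species, ranked)
  oldest <- tapply(rk, ort$source_gene, min)
  lab <- ranked[oldest[genes]]
  lab[is.na(lab)] <- "mouse"
  tibble::tibble(gene = genes, oldest_species = lab)
}

#' Conservation distribution of a gene set
#'
#' Counts genes by oldest conserved species over the four model organisms.
#'
#' @param genes Character vector of source gene symbols.
#' @param orthologs Confidence-filtered ortholog tibble.
#' @return A tibble with `oldest_species`, `n` and `prop` rows for worm, fly,
#'   zebrafish and mouse (zero-filled; `n` sums to `length(genes)`).
#' @export
conservation_distribution <- function(genes, orthologs) {
  lev <- c("worm", "fly", "zebrafish", "mouse")
  ass <- assign_oldest_species(genes, orthologs)
  n <- as.integer(table(factor(ass$oldest_species, levels = lev)))
  tibble::tibble(oldest_species = lev, n = n,
                 prop = if (length(genes) > 0) n / length(genes) else rep(NA_real_, 4))
}

#' Compare two conservation distributions
#'
#' Pearson chi-square test on the 2 x 4 table of oldest-species counts for
#' two gene sets (no continuity correction; df = 3 when all four categories
#' are populated). Categories empty in both sets are dropped with a warning
#' and the degrees of freedom reduced accordingly. The test is symmetric in
#' its two arguments.
#'
#' @param d1,d2 Conservation distributions from [conservation_distribution()]
#'   (or any tibble with `oldest_species` and `n` over the same categories).
#' @return A tibble with `chi2`, `df`, `p`.
#' @export
compare_distributions <- function(d1, d2) {
  m <- merge(d1[c("oldest_species", "n")], d2[c("oldest_species", "n")],
             by = "oldest_species", sort = TRUE)
  tab <- rbind(m$n.x, m$n.y)
  tot <- colSums(tab)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " categor(ies) with zero total in both sets",
            call. = FALSE)
    tab <- tab[, tot > 0, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("fewer than 2 populated categories; test undefined", call. = FALSE)
  if (identical(tab[1, ] * sum(tab[2, ]), tab[2, ] * sum(tab[1, ]))) {
    # proportional rows: chi2 exactly 0, avoid chisq.test()'s expected-count warnings
    return(tibble::tibble(chi2 = 0, df = ncol(tab) - 1L, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), df = as.integer(ct$parameter),
                 p = unname(ct$p.value))
}
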