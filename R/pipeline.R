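#' Run the full cross-species comorbidity pipeline
#'
#' Orchestrates every stage against a set of input files: load the term map,
#' mask, orthologs, payloads and genome backgrounds; build the gene x
#' species x category profile matrix; run class-association enrichment with
#' pooled FDR, per-gene ICC with its permutation null, mouse-human
#' correlation, conservation dating, k-means comorbidity clustering with
#' gap-statistic model selection, cluster binarization, and the driver
#' regressions for whichever expression/GO blocks are supplied. Identical
#' config and seeds give byte-identical outputs.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `inputs`: `term_map`, `mask`, `payload_dir`, `orthologs`,
#'     `background` (named list species -> path), and optionally
#'     `celltype`, `tissue`, `go`, `annotations`;
#'   * `params` (all optional): `min_confidence` (default `"moderate"`),
#'     `fdr` (0.05), `n_perm` (999), `icc_seed` (1), `k` (fixed cluster
#'     count; when absent the gap statistic chooses), `k_max` (20), `B`
#'     (100), `n_start` (25), `cluster_seed` (1);
#'   * `output_dir` (optional): where to write the result tables.
#' @return A list of class `como_results` with elements `matrix`,
#'   `enrichment`, `icc`, `icc_by_function`, `correlation`, `conservation`,
#'   `linkage`, `gap`, `clusters`, `binary`, `drivers`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  params <- config$params %||% list()
  for (f in c("term_map", "mask", "payload_dir", "orthologs", "background")) {
    if (is.null(inputs[[f]])) stop("config is missing input: ", f, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  term_map <- stage("term_map", load_term_map(inputs$term_map))
  mask <- stage("mask", load_mask(inputs$mask))
  orthologs <- stage("orthologs", load_orthologs(inputs$orthologs))
  filtered <- filter_orthologs(orthologs,
                               params$min_confidence %||% "moderate",
                               best_only = isTRUE(params$best_only))
  payloads <- stage("payloads", read_payload_dir(inputs$payload_dir))
  background <- stage("background", load_background(unlist(inputs$background)))

  profiles <- stage("profiles", purrr::map(payloads, function(p) {
    build_profile(p$gene, p$records, term_map, mask, presence = p$presence)
  }))
  matrix <- stage("assemble", assemble_matrix(profiles, background, mask))

  enrichment <- stage("enrichment",
                      run_class_association(matrix, fdr = params$fdr %||% 0.05))
  icc <- stage("icc", run_icc(matrix, n_perm = params$n_perm %||% 999,
                              seed = params$icc_seed %||% 1L))
  icc_fn <- NULL
  if (!is.null(inputs$annotations)) {
    ann <- readr::read_tsv(inputs$annotations, col_types = "cc")
    icc_fn <- stage("icc_by_function", icc_by_function(icc, ann))
  }
  correlation <- stage("correlation", mouse_human_correlation(matrix))
  genes <- sort(unique(matrix$profiles$gene))
  conservation <- stage("conservation", conservation_distribution(genes, filtered))
  linkage <- stage("linkage", summarize_fertility_linkage(matrix))

  counts <- species_counts(matrix, "mouse")
  gap <- NULL
  k <- params$k
  if (is.null(k)) {
    gap <- stage("gap", select_k_gap(counts, k_max = params$k_max %||% 20,
                                     B = params$B %||% 100,
                                     n_start = params$n_start %||% 25,
                                     seed = params$cluster_seed %||% 1L))
    k <- gap$chosen_k
  }
  clusters <- NULL; binary <- NULL; drivers <- list()
  if (k >= 2) {
    clusters <- stage("clusters", cluster_genes(counts, k,
                                                n_start = params$n_start %||% 25,
                                                seed = params$cluster_seed %||% 1L))
    if (k %% 2 == 0) binary <- stage("binarize", binarize_clusters(clusters))
    blocks <- list(celltype = "celltype_z", tissue = "tissue_logtpm",
                   go = "go_indicator")
    for (bl in names(blocks)) {
      if (is.null(inputs[[bl]])) next
      block <- readr::read_tsv(inputs[[bl]], col_types = readr::cols(
        gene = readr::col_character(), .default = readr::col_double()
      ))
      x <- block[block$gene %in% clusters$labels$gene, ]
      if (blocks[[bl]] == "celltype_z") {
        z <- zscore_by_celltype(tibble::column_to_rownames(as.data.frame(x), "gene"))
        drivers[[bl]] <- stage(paste0("drivers_", bl),
                               fit_multinomial(clusters$labels, z$values,
                                               kind = "celltype_z"))
      } else {
        drivers[[bl]] <- stage(paste0("drivers_", bl),
                               fit_multinomial(clusters$labels, x, kind = blocks[[bl]]))
      }
      if (bl == "tissue" && !is.null(binary)) {
        drivers$tissue_binary <- stage("drivers_tissue_binary",
                                       fit_binary_logistic(binary, x))
      }
    }
  }

  res <- structure(list(matrix = matrix, enrichment = enrichment, icc = icc,
                        icc_by_function = icc_fn, correlation = correlation,
                        conservation = conservation, linkage = linkage,
                        gap = gap, clusters = clusters, binary = binary,
                        drivers = drivers),
                   class = "como_results")
  if (!is.null(config$output_dir)) write_results(res, config$output_dir)
  res
}

#' Write pipeline results to a directory of TSV/JSON tables
#'
#' @param results A `como_results` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_profile_matrix(results$matrix, file.path(dir, "profile_matrix.tsv"))
  readr::write_tsv(results$enrichment, file.path(dir, "enrichment.tsv"))
  readr::write_tsv(results$icc, file.path(dir, "icc.tsv"))
  if (!is.null(results$icc_by_function)) {
    readr::write_tsv(results$icc_by_function, file.path(dir, "icc_by_function.tsv"))
  }
  readr::write_tsv(results$correlation, file.path(dir, "correlations.tsv"))
  readr::write_tsv(results$conservation, file.path(dir, "conservation.tsv"))
  readr::write_tsv(results$linkage, file.path(dir, "linkage.tsv"))
  if (!is.null(results$gap)) readr::write_tsv(results$gap$gap_curve,
                                              file.path(dir, "gap.tsv"))
  if (!is.null(results$clusters)) {
    lab <- results$binary %||% results$clusters$labels
    readr::write_tsv(lab, file.path(dir, "clusters.tsv"))
  }
  if (length(results$drivers) > 0) {
    rep <- purrr::map(results$drivers, function(f) {
      list(kind = f$kind, model = f$model,
           coefficients = as.data.frame(f$coefficients),
           loglik_model = f$loglik_model, loglik_null = f$loglik_null,
           mcfadden_r2 = f$mcfadden_r2, lrt_stat = f$lrt_stat,
           lrt_df = f$lrt_df, lrt_p = f$lrt_p, converged = f$converged,
           separation_flag = f$separation_flag)
    })
    jsonlite::write_json(rep, file.path(dir, "drivers_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @export
print.como_results <- function(x, ...) {
  cat("<como_results>\n")
  print(x$matrix)
  sig <- sum(x$enrichment$significant, na.rm = TRUE)
  cat("  enrichment: ", sig, " significant species/category pairs (q < 0.05)\n",
      sep = "")
  cat("  ICC: median ", format(stats::median(x$icc$icc), digits = 3), ", ",
      sum(x$icc$p_perm <= 1e-3), " genes at p <= 1e-3\n", sep = "")
  if (!is.null(x$clusters)) {
    cat("  clusters: k = ", x$clusters$k, " sizes ",
        paste(x$clusters$sizes, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Recompute the study's headline quantities from its frozen data tables
#'
#' Given a directory holding the study's own frozen input tables in the
#' package's documented file formats (term map, mask, orthologs, payloads,
#' backgrounds, expression/GO blocks, annotations), reruns the pipeline and
#' returns the headline summary numbers: per-species fertility linkage, the
#' oldest-species conservation distribution, the median ICC and the number
#' of concordance-significant genes, the cluster sizes at k = 4, and the
#' GO-block McFadden pseudo-R-squared. This package ships no copy of those
#' frozen tables; the function is the reproduction recipe for users who
#' have them.
#'
#' @param sd1_dir Directory with the frozen study tables in bundle layout
#'   (see [write_bundle()] for file names).
#' @param n_perm Permutations for the ICC test (default 999).
#' @return A named list of headline quantities.
#' @export
reproduce_headline_numbers <- function(sd1_dir, n_perm = 999) {
  if (!dir.exists(sd1_dir)) {
    stop("frozen study tables not found at ", sd1_dir, call. = FALSE)
  }
  cfg <- list(
    inputs = list(
      term_map = file.path(sd1_dir, "term_map.tsv"),
      mask = file.path(sd1_dir, "mask.tsv"),
      payload_dir = file.path(sd1_dir, "payloads"),
      orthologs = file.path(sd1_dir, "orthologs.tsv"),
      background = as.list(stats::setNames(
        file.path(sd1_dir, paste0("background_", species_codes(), ".tsv")),
        species_codes())),
      celltype = maybe_file(sd1_dir, "expression_celltype.tsv"),
      tissue = maybe_file(sd1_dir, "expression_tissue.tsv"),
      go = maybe_file(sd1_dir, "go_indicator.tsv"),
      annotations = maybe_file(sd1_dir, "annotations.tsv")
    ),
    params = list(n_perm = n_perm, k = 4)
  )
  res <- run_pipeline(cfg)
  link <- res$linkage
  list(
    mouse_fertility_linkage = link$fraction[link$species == "mouse"],
    human_fertility_linkage = link$fraction[link$species == "human"],
    conservation_pct = stats::setNames(100 * res$conservation$prop,
                                       res$conservation$oldest_species),
    median_icc = stats::median(res$icc$icc),
    n_icc_significant = sum(res$icc$p_perm <= 1e-3),
    cluster_sizes = res$clusters$sizes,
    go_mcfadden_r2 = if (!is.null(res$drivers$go)) res$drivers$go$mcfadden_r2 else NA_real_
  )
}

maybe_file <- function(dir, name) {
  p <- file.path(dir, name)
  if (file.exists(p)) p else NULL
}
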