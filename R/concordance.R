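#' One-way intraclass correlation of a category x species count matrix
#'
#' Quantifies how similar a gene's phenotype profile is across species.
#' The one-way random-effects, single-rater form is used, with the 19
#' categories as objects and the species as interchangeable raters:
#' `ICC = (MSB - MSW) / (MSB + (S - 1) * MSW)`, where MSB/MSW are the
#' between-/within-category mean squares of the one-way ANOVA and S is the
#' number of species columns. An all-constant matrix (both mean squares
#' zero) returns 0 by convention; identical non-constant columns return 1.
#'
#' @param mat Numeric matrix, categories in rows, species in columns
#'   (>= 2 columns).
#' @return ICC value in `[-1/(S-1), 1]`.
#' @export
gene_icc <- function(mat) {
  mat <- as.matrix(mat)
  S <- ncol(mat)
  C <- nrow(mat)
  if (S < 2) stop("ICC needs >= 2 species columns", call. = FALSE)
  row_means <- rowMeans(mat)
  grand <- mean(mat)
  msb <- S * sum((row_means - grand)^2) / (C - 1)
  msw <- sum((mat - row_means)^2) / (C * (S - 1))
  denom <- msb + (S - 1) * msw
  if (denom == 0) return(0)
  (msb - msw) / denom
}

# gene's category x species matrix of counts, species without orthologs dropped
icc_matrix_for_gene <- function(matrix, gene) {
  rows <- matrix$profiles[matrix$profiles$gene == gene & matrix$profiles$ortholog_present, ]
  m <- t(as.matrix(rows[matrix$categories]))
  colnames(m) <- rows$species
  storage.mode(m) <- "double"
  m
}

#' Per-gene cross-species ICC with a permutation null
#'
#' For each gene with orthologs in at least two species, computes the
#' one-way ICC of its category x species count matrix (species without an
#' ortholog are excluded, not zero-filled) and a permutation p-value. The
#' null preserves each species' marginal count distribution: each species
#' column is replaced by the same species' column from a uniformly drawn
#' random gene (independently per species), and
#' `p = (1 + #\{null ICC >= observed\}) / (1 + n_perm)`.
#'
#' @param matrix A `como_matrix`.
#' @param n_perm Number of permutations (default 999, resolving p down to
#'   1e-3).
#' @param seed Integer seed making the null draws reproducible.
#' @return A tibble of class `como_icc`: `gene`, `icc`, `p_perm`,
#'   `n_species_used`. Genes with < 2 species present are excluded.
#' @export
run_icc <- function(matrix, n_perm = 999, seed = 1L) {
  prof <- matrix$profiles[matrix$profiles$ortholog_present, ]
  genes <- sort(unique(matrix$profiles$gene))
  if (length(genes) < 10) {
    warning("permutation null over < 10 genes is very coarse", call. = FALSE)
  }
  cats <- matrix$categories
  # per-species pool of count vectors (one row per gene present there)
  pools <- lapply(stats::setNames(species_codes(), species_codes()), function(s) {
    p <- prof[prof$species == s, ]
    m <- as.matrix(p[cats])
    rownames(m) <- p$gene
    storage.mode(m) <- "double"
    m
  })
  out <- with_seed(seed, purrr::map(genes, function(g) {
    sp <- prof$species[prof$gene == g]
    if (length(sp) < 2) return(NULL)
    obs_mat <- vapply(sp, function(s) pools[[s]][g, ], numeric(length(cats)))
    obs <- gene_icc(obs_mat)
    null_mat <- obs_mat
    hits <- 0L
    for (i in seq_len(n_perm)) {
      for (j in seq_along(sp)) {
        pool <- pools[[sp[j]]]
        null_mat[, j] <- pool[sample.int(nrow(pool), 1L), ]
      }
      if (gene_icc(null_mat) >= obs) hits <- hits + 1L
    }
    tibble::tibble(gene = g, icc = obs, p_perm = (1 + hits) / (1 + n_perm),
                   n_species_used = length(sp))
  })) |> purrr::list_rbind()
  class(out) <- c("como_icc", class(out))
  out
}

#' Proportion of concordance-significant genes per functional annotation
#'
#' @param icc_results Output of [run_icc()].
#' @param annotations Long tibble `gene`, `label` (a gene may carry several
#'   of the nine mechanism labels).
#' @param alpha Permutation-p significance threshold (default 1e-3; a gene
#'   counts as significant at `p_perm <= alpha`, since 1/(n_perm+1) is the
#'   exact floor of a 999-permutation test and is attained, never undercut).
#' @return A tibble `label`, `n_genes`, `n_significant`, `proportion`;
#'   labels with zero genes are absent rather than 0/0.
#' @export
icc_by_function <- function(icc_results, annotations, alpha = 1e-3) {
  miss <- setdiff(annotations$gene, icc_results$gene)
  ann <- annotations[!annotations$gene %in% miss, ]
  dplyr::inner_join(ann, icc_results, by = "gene") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_significant = sum(.data$p_perm <= alpha),
                     proportion = .data$n_significant / .data$n_genes,
                     .groups = "drop")
}

#' Mouse-human phenotype-profile correlation per gene
#'
#' Pearson correlation between a gene's mouse and human 19-category count
#' vectors, over genes with at least one phenotype in any category (in
#' either species). Following the substitution rule for incomplete
#' observations, `r` is set to 0 (and flagged `substituted`) when the human
#' ortholog is missing or either vector has zero standard deviation.
#'
#' @param matrix A `como_matrix`.
#' @return A tibble of class `como_correlation`: `gene`, `r`, `substituted`,
#'   `n_human_phenotypes`.
#' @export
mouse_human_correlation <- function(matrix) {
  cats <- matrix$categories
  prof <- matrix$profiles
  genes <- sort(unique(prof$gene))
  out <- purrr::map(genes, function(g) {
    mo <- prof[prof$gene == g & prof$species == "mouse", ]
    hu <- prof[prof$gene == g & prof$species == "human", ]
    mo_v <- as.numeric(mo[1, cats])
    hu_v <- if (nrow(hu) > 0 && hu$ortholog_present) as.numeric(hu[1, cats]) else NULL
    n_hu <- if (is.null(hu_v)) 0L else as.integer(sum(hu_v))
    if (sum(mo_v) + n_hu == 0) return(NULL)   # no phenotype in any category
    if (is.null(hu_v) || stats::sd(mo_v) == 0 || stats::sd(hu_v) == 0) {
      return(tibble::tibble(gene = g, r = 0, substituted = TRUE,
                            n_human_phenotypes = n_hu))
    }
    tibble::tibble(gene = g, r = stats::cor(mo_v, hu_v), substituted = FALSE,
                   n_human_phenotypes = n_hu)
  }) |> purrr::list_rbind()
  class(out) <- c("como_correlation", class(out))
  out
}

# evaluate code under a private seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
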