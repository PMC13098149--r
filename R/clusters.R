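#' K-means comorbidity clustering of gene count profiles
#'
#' Clusters genes by their (mouse) 19-category phenotype count vectors using
#' Hartigan-Wong k-means on the raw counts (no scaling by default, so that
#' heavily phenotyped genes separate from sparsely phenotyped ones), keeping
#' the best of `n_start` random restarts. Cluster ids are renumbered
#' deterministically by ascending mean total phenotype count, so "cluster 1"
#' is always the lightest-burden group.
#'
#' @param counts Numeric gene x category matrix (rownames = genes).
#' @param k Number of clusters.
#' @param n_start Random restarts (default 25).
#' @param seed Integer seed.
#' @param scale_counts Standardize columns before clustering (default
#'   `FALSE`).
#' @return An object of class `como_clusters`: `k`, `labels` (tibble `gene`,
#'   `cluster`), `centers` (k x 19, renumbered), `within_ss`, `sizes`.
#' @export
cluster_genes <- function(counts, k, n_start = 25, seed = 1L, scale_counts = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  n_distinct <- nrow(unique(counts))
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the ", n_distinct, " distinct profiles", call. = FALSE)
  }
  x <- if (scale_counts) scale(counts) else counts
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_start, iter.max = 100))
  # deterministic labels: ascending mean total count of member genes
  totals <- rowSums(counts)
  means <- tapply(totals, km$cluster, mean)
  ord <- order(means, as.integer(names(means)))     # tie-break by original id
  relabel <- integer(k)
  relabel[as.integer(names(means))[ord]] <- seq_len(k)
  labels <- relabel[km$cluster]
  centers <- km$centers[as.integer(names(means))[ord], , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(
    k = k,
    labels = tibble::tibble(gene = rownames(counts), cluster = labels),
    centers = centers,
    within_ss = km$tot.withinss,
    sizes = as.integer(table(factor(labels, levels = seq_len(k))))
  ), class = "como_clusters")
}

#' @export
print.como_clusters <- function(x, ...) {
  cat("<como_clusters> k =", x$k, " sizes:", paste(x$sizes, collapse = "/"),
      " within-SS:", format(x$within_ss, digits = 6), "\n")
  invisible(x)
}

#' Choose the number of clusters by the gap statistic
#'
#' Computes the gap statistic (log within-cluster dispersion of uniform
#' reference bootstraps minus that of the data) for k = 1..`k_max` with `B`
#' reference sets, and selects the smallest k whose gap is within one
#' standard error of the next k's gap (the "firstSEmax" rule).
#'
#' @param counts Numeric gene x category matrix.
#' @param k_max Largest k examined (default 20).
#' @param B Reference bootstrap sets (default 100).
#' @param n_start K-means restarts inside the search (default 25).
#' @param seed Integer seed.
#' @return A list with `chosen_k` and `gap_curve` (tibble `k`, `log_w`,
#'   `log_w_ref`, `gap`, `se`), plus `low_confidence = TRUE` when `B < 10`.
#' @export
select_k_gap <- function(counts, k_max = 20, B = 100, n_start = 25, seed = 1L) {
  counts <- as.matrix(counts)
  stopifnot(k_max >= 2, B >= 1, n_start >= 1)
  gs <- with_seed(seed, cluster::clusGap(
    counts,
    FUNcluster = function(x, k) stats::kmeans(x, k, nstart = n_start, iter.max = 100),
    K.max = k_max, B = B, verbose = FALSE
  ))
  tab <- gs$Tab
  se <- tab[, "SE.sim"]
  se[!is.finite(se)] <- 0          # degenerate B = 1 reference sets
  chosen <- cluster::maxSE(tab[, "gap"], se, method = "firstSEmax")
  list(
    chosen_k = as.integer(chosen),
    gap_curve = tibble::tibble(k = seq_len(k_max), log_w = tab[, "logW"],
                               log_w_ref = tab[, "E.logW"], gap = tab[, "gap"],
                               se = se),
    low_confidence = B < 10
  )
}

#' Row-wise z-scores of expression across cell types
#'
#' Standardizes each gene's expression vector across the cell-type columns
#' (sample standard deviation). Constant rows become all-zero and are
#' flagged, mirroring the zero-variance substitution used elsewhere.
#'
#' @param raw Numeric gene x cell-type matrix, non-negative.
#' @return A list: `values` (z-scored matrix), `constant` (logical per
#'   gene), `kind = "celltype_z"`.
#' @export
zscore_by_celltype <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("expression values must be non-negative", call. = FALSE)
  mu <- rowMeans(raw)
  sdv <- apply(raw, 1, stats::sd)
  constant <- sdv == 0
  z <- (raw - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  list(values = z, constant = constant, kind = "celltype_z")
}

# shared scaffolding for the driver-model fits
block_design <- function(block, kind = c("celltype_z", "tissue_logtpm", "go_indicator")) {
  kind <- match.arg(kind)
  m <- as.matrix(block)
  if (kind == "tissue_logtpm") {
    if (any(m < 0)) stop("TPM values must be non-negative", call. = FALSE)
    m <- log1p(m)
  }
  if (kind == "go_indicator" && !all(m %in% c(0, 1))) {
    stop("GO indicator block must be 0/1", call. = FALSE)
  }
  m
}

#' Multinomial logistic driver model of cluster membership
#'
#' Fits a maximum-likelihood multinomial logit of cluster membership on an
#' expression or annotation block (cluster 1 as reference; intercepts
#' included; TPM blocks are `ln(x + 1)`-transformed first). Goodness of fit
#' is summarized by McFadden's pseudo-R-squared,
#' `1 - lnL_model / lnL_null`, against the intercept-only null, and a
#' likelihood-ratio chi-square test with `(#features) * (k - 1)` degrees of
#' freedom. No penalty is applied; complete separation is detected by
#' coefficient divergence and flagged rather than regularized, so the
#' McFadden formula keeps its meaning.
#'
#' @param labels Tibble `gene`, `cluster` (e.g. from [cluster_genes()]).
#' @param block Numeric gene x feature matrix (rownames = genes) or data
#'   frame with a `gene` column.
#' @param kind Block kind: `"celltype_z"`, `"tissue_logtpm"` or
#'   `"go_indicator"`.
#' @param maxit Iteration cap (default 500); non-convergence is reported via
#'   `converged = FALSE`, never an error.
#' @return An object of class `como_fit`: coefficient matrix, `loglik_model`,
#'   `loglik_null`, `mcfadden_r2`, `lrt_stat`, `lrt_df`, `lrt_p`,
#'   `converged`, `separation_flag`, `n`, `k`, `kind`.
#' @export
fit_multinomial <- function(labels, block, kind = "celltype_z", maxit = 500) {
  m <- align_block(labels, block)
  x <- block_design(m$x, kind)
  k <- length(unique(m$cluster))
  if (k < 2) stop("need >= 2 clusters", call. = FALSE)
  y <- factor(m$cluster)
  dat <- data.frame(.y = y, x, check.names = TRUE)
  fit <- nnet::multinom(.y ~ ., data = dat, maxit = maxit, trace = FALSE,
                        reltol = 1e-14, MaxNWts = 10000)
  null <- nnet::multinom(.y ~ 1, data = dat, maxit = maxit, trace = FALSE,
                         reltol = 1e-14)
  ll_m <- as.numeric(stats::logLik(fit))
  ll_0 <- as.numeric(stats::logLik(null))
  coefs <- stats::coef(fit)
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1,
                                           dimnames = list(levels(y)[2], names(coefs)))
  colnames(coefs) <- c("(Intercept)", colnames(x))
  sep <- max(abs(coefs)) > 15
  structure(list(
    kind = kind, coefficients = coefs,
    loglik_model = ll_m, loglik_null = ll_0,
    mcfadden_r2 = 1 - ll_m / ll_0,
    lrt_stat = 2 * (ll_m - ll_0),
    lrt_df = ncol(x) * (k - 1),
    lrt_p = stats::pchisq(2 * (ll_m - ll_0), df = ncol(x) * (k - 1),
                          lower.tail = FALSE),
    converged = fit$convergence == 0,
    separation_flag = sep,
    n = nrow(dat), k = k, model = "multinomial"
  ), class = "como_fit")
}

#' Binarize comorbidity clusters into comorbid vs fertility-restricted
#'
#' Ranks clusters by the mass of their centers summed over the
#' non-reproductive categories (all except `Fertility`, `Genitourinary` and
#' `Other`); the top half of clusters is labelled `comorbid`, the rest
#' `fertility_restricted`. Ties are broken by cluster id, with a warning.
#'
#' @param model A `como_clusters` object.
#' @param n_comorbid Number of clusters labelled comorbid; defaults to
#'   `k / 2` (requires even k unless supplied).
#' @return A tibble `gene`, `cluster`, `binary_class`.
#' @export
binarize_clusters <- function(model, n_comorbid = NULL) {
  k <- model$k
  if (is.null(n_comorbid)) {
    if (k %% 2 != 0) stop("odd k: supply n_comorbid explicitly", call. = FALSE)
    n_comorbid <- k %/% 2
  }
  non_repro <- setdiff(mcat_categories(), c("Fertility", "Genitourinary", "Other"))
  non_repro <- intersect(non_repro, colnames(model$centers))
  burden <- rowSums(model$centers[, non_repro, drop = FALSE])
  if (anyDuplicated(burden)) warning("tie in cluster burden; breaking by cluster id",
                                     call. = FALSE)
  ord <- order(-burden, as.integer(rownames(model$centers)))
  comorbid_ids <- as.integer(rownames(model$centers))[ord][seq_len(n_comorbid)]
  dplyr::mutate(model$labels,
                binary_class = ifelse(.data$cluster %in% comorbid_ids,
                                      "comorbid", "fertility_restricted"))
}

#' Binary logistic driver model of comorbidity state
#'
#' One joint multivariable logistic regression of the binarized comorbidity
#' state (comorbid = 1) on all tissue expression features
#' (`ln(x + 1)`-transformed), with per-feature Wald tests.
#'
#' @param binary_labels Tibble `gene`, `binary_class` from
#'   [binarize_clusters()].
#' @param block Gene x tissue TPM matrix (rownames = genes) or data frame
#'   with a `gene` column.
#' @param kind Block kind for the transformation (default `"tissue_logtpm"`).
#' @return A `como_fit` with a per-feature `wald` tibble (`feature`,
#'   `estimate`, `std_error`, `p`) alongside the likelihood summaries.
#' @export
fit_binary_logistic <- function(binary_labels, block, kind = "tissue_logtpm") {
  lab <- tibble::tibble(gene = binary_labels$gene,
                        cluster = binary_labels$binary_class)
  m <- align_block(lab, block)
  if (length(unique(m$cluster)) < 2) {
    stop("both comorbidity classes must be non-empty", call. = FALSE)
  }
  x <- block_design(m$x, kind)
  y <- as.integer(m$cluster == "comorbid")
  dat <- data.frame(.y = y, x, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  null <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  ll_m <- as.numeric(stats::logLik(fit))
  ll_0 <- as.numeric(stats::logLik(null))
  sm <- summary(fit)$coefficients
  est <- stats::coef(fit)[-1]               # aliased features stay NA
  se <- pp <- rep(NA_real_, length(est))
  hit <- match(names(est), rownames(sm))
  se[!is.na(hit)] <- sm[hit[!is.na(hit)], "Std. Error"]
  pp[!is.na(hit)] <- sm[hit[!is.na(hit)], "Pr(>|z|)"]
  structure(list(
    kind = kind,
    coefficients = stats::coef(fit),
    wald = tibble::tibble(feature = colnames(x), estimate = unname(est),
                          std_error = se, p = pp),
    loglik_model = ll_m, loglik_null = ll_0,
    mcfadden_r2 = 1 - ll_m / ll_0,
    lrt_stat = 2 * (ll_m - ll_0),
    lrt_df = ncol(x),
    lrt_p = stats::pchisq(2 * (ll_m - ll_0), df = ncol(x), lower.tail = FALSE),
    converged = fit$converged,
    separation_flag = suppressWarnings(max(abs(stats::coef(fit)[-1]), na.rm = TRUE)) > 15,
    n = nrow(dat), k = 2, model = "binary_logistic"
  ), class = "como_fit")
}

# match a labels tibble against a block's genes; block may carry a gene column
align_block <- function(labels, block) {
  if (is.data.frame(block) && "gene" %in% names(block)) {
    x <- as.matrix(block[setdiff(names(block), "gene")])
    rownames(x) <- block$gene
  } else {
    x <- as.matrix(block)
  }
  miss <- setdiff(labels$gene, rownames(x))
  if (length(miss) > 0) {
    stop("labelled gene(s) absent from block: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  list(cluster = labels$cluster, x = x[labels$gene, , drop = FALSE])
}

#' @export
print.como_fit <- function(x, ...) {
  cat("<como_fit> ", x$model, " on ", x$kind, ": n = ", x$n, ", k = ", x$k,
      "\n  McFadden R2 = ", format(x$mcfadden_r2, digits = 4),
      ", LRT X2(", x$lrt_df, ") = ", format(x$lrt_stat, digits = 5),
      ", p = ", format(x$lrt_p, digits = 3),
      if (!x$converged) "  [not converged]" else "",
      if (x$separation_flag) "  [separation]" else "", "\n", sep = "")
  invisible(x)
}
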