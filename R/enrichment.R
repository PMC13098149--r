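#' Build a 2x2 seed-vs-genome contingency table for one species and category
#'
#' `a` counts seed genes with an ortholog in the species and >= 1 phenotype
#' in the category; `b` the remaining seed orthologs; `c`/`d` split the
#' non-seed part of the genome background (genes with a mouse ortholog) by
#' the same flag. Seed genes without an ortholog in the species are excluded
#' from the seed side, not counted as phenotype-free.
#'
#' @param matrix A `como_matrix`.
#' @param species,category The pair to tabulate (must be testable under the
#'   matrix's mask).
#' @return A tibble row `species`, `category`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(matrix, species, category) {
  if (!isTRUE(mask_lookup(matrix$mask, species, category))) {
    stop(species, " / ", category, " is not testable under the mask", call. = FALSE)
  }
  rows <- matrix$profiles[matrix$profiles$species == species &
                            matrix$profiles$ortholog_present, ]
  a <- sum(rows[[category]] >= 1)
  b <- nrow(rows) - a
  bg <- matrix$background[matrix$background$species == species, ]
  genome <- bg$genome_size
  flagged <- bg[[category]]
  if (nrow(rows) > genome || flagged > genome) {
    stop("seed genes missing from the background universe for ", species, call. = FALSE)
  }
  cc <- flagged - a
  dd <- (genome - flagged) - b
  if (cc < 0 || dd < 0) {
    stop("background counts inconsistent with seed counts for ", species, " / ",
         category, call. = FALSE)
  }
  tibble::tibble(species = species, category = category,
                 a = as.integer(a), b = as.integer(b),
                 c = as.integer(cc), d = as.integer(dd))
}

#' Two-sided Fisher exact test with conditional-MLE odds ratio
#'
#' Exact test of association in a 2x2 table, conditioning on both margins.
#' The two-sided p-value is the minimum-likelihood rule: the sum of
#' hypergeometric point probabilities not exceeding the observed table's
#' probability times `1 + 1e-7` (the slack guards against floating-point
#' ties). Two odds-ratio estimates are returned: the sample cross-product
#' `ad/bc` (`Inf` when `bc = 0` and `ad > 0`; `NaN` when a full row or
#' column margin is zero) and the conditional maximum-likelihood estimate,
#' obtained by solving the noncentral-hypergeometric score equation
#' `E_psi[A] = a` by bracketed root finding (tolerance 1e-8; 0 or `Inf` when
#' `a` sits on the boundary of its support).
#'
#' @param a,b,c,d Non-negative integer cell counts (seed-with, seed-without,
#'   background-with, background-without); vectors of equal length are
#'   accepted.
#' @return A tibble with one row per table: `p`, `or_sample`, `or_cmle`.
#' @export
#' @examples
#' fisher_exact(5, 0, 0, 5)   # p = 2 / choose(10, 5)
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  if (any(a + b + c + d == 0)) stop("empty table", call. = FALSE)
  n_tab <- length(a)
  p <- or_sample <- or_cmle <- numeric(n_tab)
  for (i in seq_len(n_tab)) {
    p[i] <- fisher_p_one(a[i], a[i] + b[i], c[i] + d[i], a[i] + c[i])
    or_sample[i] <- if ((a[i] + b[i]) == 0 || (c[i] + d[i]) == 0 ||
                          (a[i] + c[i]) == 0 || (b[i] + d[i]) == 0) {
      NaN
    } else if (b[i] * c[i] == 0) {
      if (a[i] * d[i] > 0) Inf else NaN
    } else (a[i] / b[i]) / (c[i] / d[i])
    or_cmle[i] <- cmle_or(a[i], a[i] + b[i], c[i] + d[i], a[i] + c[i])
  }
  tibble::tibble(p = p, or_sample = or_sample, or_cmle = or_cmle)
}

# two-sided minimum-likelihood exact p for one table, margins (m, n, k)
fisher_p_one <- function(a, m, n, k) {
  lo <- max(0L, k - n)
  hi <- min(m, k)
  logp <- stats::dhyper(lo:hi, m, n, k, log = TRUE)
  obs <- logp[a - lo + 1L]
  min(1, sum(exp(logp[logp <= obs + log1p(1e-7)])))
}

# conditional-MLE odds ratio: solve E_psi[A] = a on the log scale
cmle_or <- function(a, m, n, k) {
  lo <- max(0L, k - n)
  hi <- min(m, k)
  if (lo == hi) return(NaN)          # degenerate support: psi not identifiable
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  x <- lo:hi
  lw <- lchoose(m, x) + lchoose(n, k - x)
  score <- function(t) {             # t = log psi
    lz <- lw + x * t
    w <- exp(lz - max(lz))
    sum(x * w) / sum(w) - a
  }
  lim <- 1
  while (score(-lim) > 0 || score(lim) < 0) {
    lim <- lim * 2
    if (lim > 745) break             # exp() range exhausted; effectively boundary
  }
  if (score(-lim) > 0) return(0)
  if (score(lim) < 0) return(Inf)
  exp(stats::uniroot(score, c(-lim, lim), tol = 1e-8)$root)
}

#' Benjamini-Hochberg adjustment over the pooled test set
#'
#' Applies the BH step-up procedure jointly over all tested species-category
#' pairs (pooled across species, as a single family); untested rows are left
#' untouched.
#'
#' @param results An enrichment tibble with columns `p` and `tested`.
#' @return The same tibble with the `q` column filled for tested rows.
#' @export
adjust_fdr <- function(results) {
  results$q <- NA_real_
  idx <- which(results$tested)
  results$q[idx] <- stats::p.adjust(results$p[idx], method = "BH")
  results
}

#' Class-association enrichment across all species and categories
#'
#' Runs the seed-vs-genome Fisher exact test for every species x category
#' pair testable under the mask, and controls the FDR by Benjamini-Hochberg
#' over the pooled set of p-values from all species together. `log_or` is
#' the natural log of the conditional-MLE odds ratio.
#'
#' @param matrix A `como_matrix`.
#' @param fdr FDR threshold recorded in the `significant` column (default
#'   0.05).
#' @return A tibble of class `como_enrichment`, one row per species x
#'   category: the 2x2 cells, `or_sample`, `or_cmle`, `log_or`, `p`, `q`,
#'   `tested`, `significant`.
#' @export
run_class_association <- function(matrix, fdr = 0.05) {
  grid <- tidyr::expand_grid(species = species_codes(), category = matrix$categories)
  res <- purrr::pmap(grid, function(species, category) {
    if (!isTRUE(mask_lookup(matrix$mask, species, category))) {
      return(tibble::tibble(species = species, category = category,
                            a = NA_integer_, b = NA_integer_, c = NA_integer_,
                            d = NA_integer_, or_sample = NA_real_, or_cmle = NA_real_,
                            log_or = NA_real_, p = NA_real_, tested = FALSE))
    }
    tab <- build_contingency(matrix, species, category)
    ft <- fisher_exact(tab$a, tab$b, tab$c, tab$d)
    dplyr::bind_cols(tab, ft) |>
      dplyr::mutate(log_or = log(.data$or_cmle), tested = TRUE) |>
      dplyr::select("species", "category", "a", "b", "c", "d",
                    "or_sample", "or_cmle", "log_or", "p", "tested")
  }) |> purrr::list_rbind()
  res <- adjust_fdr(res)
  res$significant <- !is.na(res$q) & res$q < fdr
  class(res) <- c("como_enrichment", class(res))
  res
}
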