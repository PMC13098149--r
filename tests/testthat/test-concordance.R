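test_that("one-way ICC matches its definition on canonical matrices", {
  # identical non-constant species columns agree perfectly
  v <- c(0, 3, 1, 7, rep(0, 15))
  expect_equal(gene_icc(cbind(v, v, v)), 1)

  # an all-zero (or all-constant) matrix is 0 by convention
  expect_equal(gene_icc(matrix(0, 19, 4)), 0)
  expect_equal(gene_icc(matrix(2, 19, 4)), 0)

  expect_error(gene_icc(matrix(1, 19, 1)), ">= 2 species")

  # invariant to species column order and to adding a common constant
  set.seed(1)
  m <- matrix(rpois(19 * 4, 2), 19, 4)
  expect_equal(gene_icc(m), gene_icc(m[, c(3, 1, 4, 2)]))
  expect_equal(gene_icc(m), gene_icc(m + 5))

  # bounded by [-1/(S-1), 1]
  for (i in 1:50) {
    S <- sample(2:5, 1)
    mm <- matrix(rnorm(19 * S), 19, S)
    icc <- gene_icc(mm)
    expect_gte(icc, -1 / (S - 1) - 1e-12)
    expect_lte(icc, 1 + 1e-12)
  }
})

test_that("ICC equals the one-way ANOVA oracle on random matrices", {
  set.seed(7)
  for (i in 1:200) {
    C <- sample(c(5, 19), 1)
    S <- sample(2:5, 1)
    m <- matrix(rpois(C * S, lambda = runif(1, 0.5, 6)), C, S)
    if (stats::var(as.vector(m)) == 0) next
    expect_equal(gene_icc(m), oracle_icc_aov(m), tolerance = 1e-10)
  }
})

test_that("the permutation test is deterministic, floored and excludes <2-species genes", {
  b <- simulate_bundle(tiny_sim(), seed = 3, materialize_terms = FALSE)
  r1 <- run_icc(b$matrix, n_perm = 99, seed = 42)
  r2 <- run_icc(b$matrix, n_perm = 99, seed = 42)
  expect_equal(r1, r2)

  expect_true(all(r1$p_perm >= 1 / 100))
  expect_true(all(r1$p_perm <= 1))
  expect_true(all(r1$n_species_used >= 2))

  # genes with fewer than two species present are absent from the result
  few <- b$matrix$profiles$gene[!b$matrix$profiles$ortholog_present]
  pres <- dplyr::count(dplyr::filter(b$matrix$profiles, ortholog_present), gene)
  only1 <- pres$gene[pres$n < 2]
  expect_false(any(r1$gene %in% only1))
})

test_that("functional annotation summaries report per-label significance rates", {
  icc <- tibble::tibble(gene = paste0("g", 1:6),
                        icc = runif(6), p_perm = c(0.001, 0.001, 0.5, 0.001, 0.2, 1),
                        n_species_used = 3L)
  class(icc) <- c("como_icc", class(icc))
  ann <- tibble::tibble(gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g1"),
                        label = c("A", "A", "A", "B", "B", "B", "B"))
  out <- icc_by_function(icc, ann, alpha = 1e-3)
  expect_equal(out$proportion[out$label == "A"], 2 / 3)
  expect_equal(out$proportion[out$label == "B"], 2 / 4)   # g1 carries both labels
  # a label with no genes is absent rather than 0/0
  expect_false("C" %in% out$label)
})

test_that("mouse-human correlation applies the r = 0 substitution rules", {
  b <- simulate_bundle(tiny_sim(), seed = 4, materialize_terms = FALSE)
  m <- b$matrix
  res <- mouse_human_correlation(m)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_true(all(res$r[res$substituted] == 0))

  # genes without a human ortholog are substituted, not dropped
  no_hu <- m$profiles$gene[m$profiles$species == "human" & !m$profiles$ortholog_present]
  no_hu <- intersect(no_hu, res$gene)
  expect_true(all(res$substituted[res$gene %in% no_hu]))

  # exact linearity gives r = 1: craft a two-gene matrix
  cats <- mcat_categories()
  mk_row <- function(gene, species, counts, present = TRUE) {
    dplyr::bind_cols(tibble::tibble(gene = gene, species = species,
                                    ortholog_present = present,
                                    n_raw_annotations = sum(counts)),
                     tibble::as_tibble(as.list(stats::setNames(counts, cats))))
  }
  v <- c(1, 2, 3, rep(0, 16))
  prof <- dplyr::bind_rows(
    purrr::map(species_codes(), function(s) {
      mk_row("G1", s, if (s == "human") as.integer(2 * v) else as.integer(v))
    })
  )
  bg <- dplyr::bind_cols(tibble::tibble(species = species_codes(), genome_size = 50L),
                         tibble::as_tibble(matrix(5L, 5, 19,
                                                  dimnames = list(NULL, cats))))
  mm <- assemble_matrix(prof, bg)
  r <- mouse_human_correlation(mm)
  expect_equal(r$r, 1)
  expect_false(r$substituted)
})

test_that("reported correlations match the textbook formula on random profiles", {
  set.seed(5)
  cats <- mcat_categories()
  for (i in 1:10) {
    mo <- rpois(19, 3); hu <- rpois(19, 3)
    if (sd(mo) == 0 || sd(hu) == 0) next
    mk_row <- function(species, counts) {
      dplyr::bind_cols(tibble::tibble(gene = "G", species = species,
                                      ortholog_present = TRUE,
                                      n_raw_annotations = sum(counts)),
                       tibble::as_tibble(as.list(stats::setNames(as.integer(counts), cats))))
    }
    prof <- purrr::list_rbind(purrr::map(species_codes(), function(s) {
      mk_row(s, if (s == "human") hu else mo)
    }))
    bg <- dplyr::bind_cols(tibble::tibble(species = species_codes(), genome_size = 100L),
                           tibble::as_tibble(matrix(20L, 5, 19,
                                                    dimnames = list(NULL, cats))))
    r <- mouse_human_correlation(assemble_matrix(prof, bg))$r
    expect_equal(r, oracle_pearson(mo, hu), tolerance = 1e-12)
  }
})
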