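test_that("bundles are deterministic given a seed", {
  cfg <- tiny_sim()
  b1 <- simulate_bundle(cfg, seed = 1)
  b2 <- simulate_bundle(cfg, seed = 1)
  expect_equal(b1$matrix$profiles, b2$matrix$profiles)
  expect_equal(b1$matrix$background, b2$matrix$background)
  expect_equal(b1$orthologs, b2$orthologs)
  expect_equal(b1$truth, b2$truth)
  expect_equal(b1$payloads, b2$payloads)

  b3 <- simulate_bundle(cfg, seed = 2)
  expect_false(identical(b1$matrix$profiles, b3$matrix$profiles))
})

test_that("written bundles are byte-identical across repeated writes", {
  cfg <- tiny_sim()
  b <- simulate_bundle(cfg, seed = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b, d1, seed = 1)
  write_bundle(b, d2, seed = 1)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_gt(length(f1), 10)
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  sum1 <- tools::md5sum(file.path(d1, f1))
  sum2 <- tools::md5sum(file.path(d2, f1))
  expect_equal(unname(sum1), unname(sum2))
})

test_that("count model moments match the Poisson targets", {
  draw_channel_counts <- comodbm:::draw_channel_counts
  set.seed(21)
  # nearly degenerate gamma mixing: mean lambda, variance approximately lambda
  rates <- matrix(3, nrow = 10000, ncol = 1)
  shared <- matrix(rgamma(10000, 500, 500), ncol = 1)
  x <- draw_channel_counts(rates, shared, share = 0.5, shape = 500)
  expect_equal(mean(x), 3, tolerance = 0.06 / 3)
  expect_equal(var(as.numeric(x)), 3 + 9 / 250, tolerance = 0.15)

  # a zero rate yields all-zero counts
  expect_true(all(draw_channel_counts(rates * 0, shared, 0.5, 500) == 0))
})

test_that("flag probabilities match the closed form used for backgrounds", {
  flag_prob <- comodbm:::flag_prob
  draw_channel_counts <- comodbm:::draw_channel_counts
  set.seed(22)
  for (case in list(c(l = 0.4, s = 0.6, a = 0.35), c(l = 2.5, s = 1.0, a = 1),
                    c(l = 0.15, s = 0, a = 5))) {
    n <- 40000
    shared <- matrix(rgamma(n, case["a"], case["a"]), ncol = 1)
    x <- draw_channel_counts(matrix(case["l"], n, 1), shared, case["s"], case["a"])
    emp <- mean(x >= 1)
    thr <- unname(flag_prob(case["l"], case["s"], case["a"]))
    expect_lt(abs(emp - thr), 4 * sqrt(thr * (1 - thr) / n) + 1e-4)
  }

  # planted rate multiplier moves the flag-rate ratio by the zero-class formula
  set.seed(23)
  n <- 40000; l <- 0.3; rho <- 10
  x0 <- rpois(n, l); x1 <- rpois(n, l * rho)
  ratio <- mean(x1 >= 1) / mean(x0 >= 1)
  expect_equal(ratio, (1 - exp(-rho * l)) / (1 - exp(-l)), tolerance = 0.05)
})

test_that("every emitted file parses cleanly through its consuming module", {
  cfg <- tiny_sim()
  b <- simulate_bundle(cfg, seed = 6)
  dir <- withr::local_tempdir()
  write_bundle(b, dir, seed = 1)

  expect_no_warning({
    tm <- load_term_map(file.path(dir, "term_map.tsv"))
    mask <- load_mask(file.path(dir, "mask.tsv"))
    ort <- load_orthologs(file.path(dir, "orthologs.tsv"))
    payloads <- read_payload_dir(file.path(dir, "payloads"))
    bg <- load_background(stats::setNames(
      file.path(dir, paste0("background_", species_codes(), ".tsv")),
      species_codes()))
  })
  expect_equal(length(payloads), cfg$n_seed_genes)
  expect_equal(bg$genome_size, unname(cfg$genome_sizes[bg$species]))

  # rebuilding profiles from the payloads reproduces the bundle matrix exactly
  profiles <- purrr::map(payloads, function(p) {
    build_profile(p$gene, p$records, tm, mask, presence = p$presence)
  })
  m2 <- assemble_matrix(profiles, bg, mask)
  expect_equal(m2$profiles[c("gene", "species", "ortholog_present",
                             mcat_categories())],
               b$matrix$profiles[c("gene", "species", "ortholog_present",
                                   mcat_categories())])
  expect_equal(m2$background, b$matrix$background)
})

test_that("the oldest-species distribution tracks the planted retention rates", {
  cfg <- sim_config(n_seed_genes = 400L)
  b <- simulate_bundle(cfg, seed = 8, materialize_terms = FALSE)
  d <- conservation_distribution(b$truth$gene, filter_orthologs(b$orthologs, "moderate"))
  expect_equal(sum(d$n), 400L)
  ret <- cfg$ortholog_retention
  expected <- c(worm = unname(ret["worm"]),
                fly = unname((1 - ret["worm"]) * ret["fly"]),
                zebrafish = unname((1 - ret["worm"]) * (1 - ret["fly"]) * ret["zebrafish"]),
                mouse = unname((1 - ret["worm"]) * (1 - ret["fly"]) * (1 - ret["zebrafish"])))
  for (s in names(expected)) {
    phat <- d$prop[d$oldest_species == s]
    se <- sqrt(expected[[s]] * (1 - expected[[s]]) / 400)
    expect_lt(abs(phat - expected[[s]]), 4 * se + 0.01)
  }
  # and the truth table agrees with the orthology module
  expect_equal(b$truth$oldest_species,
               assign_oldest_species(b$truth$gene,
                                     filter_orthologs(b$orthologs, "moderate"))$oldest_species)
})

test_that("concordance share moves cross-species agreement in the right direction", {
  hi <- simulate_bundle(sim_config("null", concordance_share = 0.95,
                                   mouse_share = 0.95, n_seed_genes = 60L,
                                   activity_boost = 6, share_high_frac = 1,
                                   share_high = 0.95),
                        seed = 9, materialize_terms = FALSE)
  lo <- simulate_bundle(sim_config("null", concordance_share = 0, n_seed_genes = 60L),
                        seed = 9, materialize_terms = FALSE)
  icc_hi <- run_icc(hi$matrix, n_perm = 9, seed = 1)
  icc_lo <- run_icc(lo$matrix, n_perm = 9, seed = 1)
  expect_gt(mean(icc_hi$icc), mean(icc_lo$icc) + 0.05)
  expect_lt(abs(mean(icc_lo$icc)), 0.08)   # independent columns: ICC near 0
})

test_that("expression blocks carry the planted class structure", {
  cfg <- tiny_sim()
  b <- simulate_bundle(cfg, seed = 10, materialize_terms = FALSE)
  expect_equal(dim(b$expression$celltype), c(40, 14))
  expect_equal(dim(b$expression$tissue), c(40, 55))
  expect_true(all(as.matrix(b$expression$go[, -1]) %in% 0:1))
  expect_true(all(as.matrix(b$expression$tissue[, -1]) >= 0))

  # classes 1-2 were planted with higher testis expression than classes 3-4
  te <- log1p(b$expression$tissue$Testis)
  cls <- b$truth$class
  expect_gt(mean(te[cls <= 2]), mean(te[cls >= 3]))
})
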