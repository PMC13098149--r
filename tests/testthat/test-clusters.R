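test_that("k-means separates point masses and labels deterministically", {
  cats <- mcat_categories()
  centers <- rbind(rep(0, 19), c(rep(10, 5), rep(0, 14)),
                   c(rep(0, 14), rep(10, 5)), rep(20, 19))
  counts <- centers[rep(1:4, each = 10), ]
  colnames(counts) <- cats
  rownames(counts) <- sprintf("g%02d", 1:40)

  cm <- cluster_genes(counts, 4, seed = 1)
  expect_equal(cm$within_ss, 0)
  expect_equal(cm$sizes, rep(10L, 4))
  # deterministic relabeling: ascending mean total count
  totals <- tapply(rowSums(counts), cm$labels$cluster, mean)
  expect_true(all(diff(totals) >= 0))

  cm2 <- cluster_genes(counts, 4, seed = 1)
  expect_equal(cm$labels, cm2$labels)

  expect_error(cluster_genes(counts, 5, seed = 1), "distinct")
})

test_that("k-means objective improves with restarts and never beats the best start", {
  set.seed(3)
  x <- matrix(rpois(200 * 19, 2), 200, 19)
  multi <- cluster_genes(x, 5, n_start = 20, seed = 9)
  singles <- vapply(1:8, function(s) cluster_genes(x, 5, n_start = 1, seed = s)$within_ss,
                    numeric(1))
  expect_lte(multi$within_ss, min(singles) + 1e-8)
})

test_that("gap search flags a degenerate bootstrap configuration", {
  set.seed(2)
  x <- matrix(rnorm(60 * 4), 60, 4)
  g <- select_k_gap(x, k_max = 3, B = 1, n_start = 2, seed = 1)
  expect_true(g$low_confidence)
  expect_true(g$chosen_k >= 1 && g$chosen_k <= 3)
  expect_equal(nrow(g$gap_curve), 3)
})

test_that("cell-type z-scores use the sample standard deviation and flag constants", {
  m <- rbind(c(1, 1), c(0, 10))
  z <- zscore_by_celltype(m)
  expect_equal(z$values[1, ], c(0, 0))
  expect_true(z$constant[1])
  expect_equal(z$values[2, ], c(-0.707, 0.707), tolerance = 1e-3)  # sample sd: 7.071

  set.seed(4)
  raw <- matrix(rexp(10 * 13), 10, 13)
  zz <- zscore_by_celltype(raw)$values
  expect_equal(unname(rowMeans(zz)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(zz, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_error(zscore_by_celltype(-raw), "non-negative")
})

test_that("multinomial driver fits degrade gracefully at the boundaries", {
  set.seed(6)
  labels <- tibble::tibble(gene = sprintf("g%02d", 1:60),
                           cluster = rep(1:3, each = 20))
  # all-zero features: model is the null model
  zeros <- matrix(0, 60, 4, dimnames = list(labels$gene, paste0("f", 1:4)))
  f0 <- fit_multinomial(labels, zeros, kind = "celltype_z")
  expect_equal(f0$mcfadden_r2, 0, tolerance = 1e-6)
  expect_equal(f0$lrt_p, 1, tolerance = 1e-4)
  expect_equal(f0$lrt_stat, 2 * (f0$loglik_model - f0$loglik_null), tolerance = 1e-10)

  # two clusters perfectly split by one binary feature: separation flagged
  lab2 <- tibble::tibble(gene = labels$gene, cluster = rep(1:2, each = 30))
  sep <- matrix(rep(c(0, 1), each = 30), 60, 1,
                dimnames = list(labels$gene, "f1"))
  fs <- fit_multinomial(lab2, sep, kind = "go_indicator")
  expect_true(fs$separation_flag)
  expect_gt(fs$mcfadden_r2, 0.95)
})

test_that("McFadden R2 is invariant to affine feature rescaling", {
  set.seed(8)
  labels <- tibble::tibble(gene = sprintf("g%03d", 1:120),
                           cluster = sample(1:3, 120, replace = TRUE))
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(labels$gene, paste0("f", 1:3)))
  x[, 1] <- x[, 1] + (labels$cluster == 2) * 1.2
  f1 <- fit_multinomial(labels, x, kind = "celltype_z")
  x2 <- sweep(x, 2, c(10, 0.2, 3), `*`) + 5
  f2 <- fit_multinomial(labels, x2, kind = "celltype_z")
  expect_equal(f1$mcfadden_r2, f2$mcfadden_r2, tolerance = 1e-5)
})

test_that("multinomial coefficients recover a known generating model", {
  set.seed(12)
  n <- 500
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  b_true <- rbind(c(0.3, -0.2), c(1.0, 0.6), c(-0.8, 1.2))   # (intercept, f1, f2) x 2
  eta <- cbind(0, cbind(1, x) %*% b_true)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- vapply(seq_len(n), function(i) sample(3, 1, prob = pr[i, ]), integer(1))
  labels <- tibble::tibble(gene = sprintf("g%03d", 1:n), cluster = y)
  rownames(x) <- labels$gene
  fit <- fit_multinomial(labels, x, kind = "celltype_z")
  est <- t(fit$coefficients)          # (intercept, f1, f2) x (k-1)
  # standard errors from the observed information of the same model
  ref <- nnet::multinom(factor(y) ~ f1 + f2, data = data.frame(x, y),
                        trace = FALSE, Hess = TRUE, reltol = 1e-14)
  se <- t(summary(ref)$standard.errors)
  cover <- abs(est - b_true) <= 2 * se
  expect_gte(mean(cover), 0.9)
})

test_that("cluster binarization ranks by non-reproductive burden", {
  cats <- mcat_categories()
  centers <- matrix(0.1, 4, 19, dimnames = list(1:4, cats))
  centers[3, "Integument"] <- 8; centers[4, "Nervous System"] <- 6
  centers[1, "Fertility"] <- 9; centers[2, c("Fertility", "Other")] <- 7
  centers[2, "Growth Abnormality"] <- 0.3       # break the 1-vs-2 burden tie
  model <- structure(list(
    k = 4,
    labels = tibble::tibble(gene = sprintf("g%02d", 1:8),
                            cluster = rep(1:4, each = 2)),
    centers = centers, within_ss = 0, sizes = rep(2L, 4)
  ), class = "como_clusters")
  out <- binarize_clusters(model)
  expect_equal(out$binary_class[out$cluster %in% 3:4], rep("comorbid", 4))
  expect_equal(out$binary_class[out$cluster %in% 1:2], rep("fertility_restricted", 4))

  # k = 2: the heavier cluster is comorbid
  m2 <- model; m2$k <- 2; m2$centers <- centers[1:2, ]; m2$sizes <- c(4L, 4L)
  m2$centers[2, "Integument"] <- 3
  m2$labels$cluster <- rep(1:2, each = 4)
  out2 <- binarize_clusters(m2)
  expect_equal(unique(out2$binary_class[out2$cluster == 2]), "comorbid")

  # odd k needs an explicit split; ties warn and break by cluster id
  m3 <- model; m3$k <- 3; m3$centers <- centers[1:3, ]
  m3$labels$cluster <- rep(1:3, length.out = 8)
  expect_error(binarize_clusters(m3), "odd k")
  mt <- model; mt$centers[3, ] <- mt$centers[4, ] <- rep(1, 19)
  expect_warning(binarize_clusters(mt), "tie")
})

test_that("binary logistic driver model reports per-tissue Wald tests", {
  set.seed(10)
  n <- 120
  tpm <- matrix(rlnorm(n * 5, 1, 0.7), n, 5,
                dimnames = list(sprintf("g%03d", 1:n), paste0("t", 1:5)))
  eta <- -1 + 1.4 * log1p(tpm[, 1])
  y <- ifelse(runif(n) < plogis(eta), "comorbid", "fertility_restricted")
  labels <- tibble::tibble(gene = rownames(tpm), binary_class = y)
  fit <- fit_binary_logistic(labels, tpm)
  expect_equal(nrow(fit$wald), 5)
  expect_gt(fit$wald$estimate[1], 0)
  expect_lt(fit$wald$p[1], 0.05)
  expect_equal(fit$lrt_stat, 2 * (fit$loglik_model - fit$loglik_null), tolerance = 1e-10)

  # single-class labels are a hard error
  one <- dplyr::mutate(labels, binary_class = "comorbid")
  expect_error(fit_binary_logistic(one, tpm), "non-empty")
})

test_that("tidy and glance methods expose fits and clusterings as tibbles", {
  set.seed(13)
  labels <- tibble::tibble(gene = sprintf("g%02d", 1:60),
                           cluster = sample(1:3, 60, replace = TRUE))
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(labels$gene, c("a", "b")))
  fit <- fit_multinomial(labels, x, kind = "celltype_z")
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("(Intercept)", "a", "b"))
  expect_equal(nrow(td), 3 * 2)
  gl <- glance(fit)
  expect_equal(gl$mcfadden_r2, fit$mcfadden_r2)

  counts <- matrix(rpois(60 * 19, 2), 60, 19,
                   dimnames = list(labels$gene, mcat_categories()))
  cm <- cluster_genes(counts, 2, seed = 1)
  expect_equal(nrow(tidy(cm)), 60)
  expect_equal(glance(cm)$k, 2)
})
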