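# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities from log-binomial coefficients
# rather than dhyper(), the conditional MLE by grid search + golden-section
# refinement rather than root finding, and the ICC through stats::aov().

# two-sided minimum-likelihood exact p by explicit enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(m, k)
  logw <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  w <- exp(logw)
  obs <- w[x == a]
  min(1, sum(w[w <= obs * (1 + 1e-7)]))
}

# conditional-MLE odds ratio: noncentral-hypergeometric likelihood maximized
# on a log-psi grid, then refined by optimize() on the bracketing interval
oracle_cmle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(m, k)
  if (length(x) == 1) return(NaN)
  if (a == min(x)) return(0)
  if (a == max(x)) return(Inf)
  lw <- lchoose(m, x) + lchoose(n, k - x)
  loglik <- function(t) {
    lz <- lw + x * t
    mx <- max(lz)
    (lw[x == a] + a * t) - (mx + log(sum(exp(lz - mx))))
  }
  grid <- seq(-30, 30, length.out = 1201)
  ll <- vapply(grid, loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  exp(stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum)
}

# one-way ANOVA ICC with categories as groups, via stats::aov
oracle_icc_aov <- function(mat) {
  S <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  g = factor(rep(seq_len(nrow(mat)), times = S)))
  tab <- summary(stats::aov(y ~ g, data = d))[[1]]
  msb <- tab["g", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  if (!is.finite(msb) || (msb + (S - 1) * msw) == 0) return(0)
  (msb - msw) / (msb + (S - 1) * msw)
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# direct numerical maximization of the multinomial-logit log-likelihood
# (reference class 1, intercepts included), as an optimizer-independent check
oracle_multinom <- function(y, x) {
  y <- as.integer(factor(y))
  k <- max(y)
  X <- cbind(1, as.matrix(x))
  p <- ncol(X)
  negll <- function(beta) {
    B <- matrix(beta, nrow = p)            # p x (k-1)
    eta <- cbind(0, X %*% B)               # n x k
    -sum(eta[cbind(seq_along(y), y)] - log(rowSums(exp(eta))))
  }
  fit <- stats::optim(rep(0, p * (k - 1)), negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(loglik = -fit$value,
       coefficients = matrix(fit$par, nrow = p,
                             dimnames = list(colnames(X) <- c("(Intercept)", colnames(x)),
                                             NULL)))
}

# small, fast simulation settings shared by several tests
tiny_sim <- function(...) {
  sim_config(
    n_seed_genes = 40L,
    genome_sizes = c(human = 2000L, mouse = 2500L, zebrafish = 1800L,
                     fly = 1500L, worm = 1200L),
    ...
  )
}

# a minimal hand-built term map used by several unit tests
toy_term_map <- function() {
  tibble::tibble(
    term_id = c("HP:0000119", "HP:0000001", "MP:0000002", "MP:0000003",
                "MP:0000004", "FBcv:0000431", "ZP:0000010", "WBPhenotype:0000020"),
    species = c("human", "human", "mouse", "mouse", "mouse", "fly",
                "zebrafish", "worm"),
    label = c("Abnormality of the genitourinary system", "nervous A",
              "fert m1", "fert m2", "nervous m", "meiotic cell cycle defective",
              "fish fert", "worm integument"),
    base_category = c("Genitourinary", "Nervous System", "Genitourinary",
                      "Genitourinary", "Nervous System", "Genitourinary",
                      "Genitourinary", "Integument"),
    is_fertility = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    repro_group = c(NA, NA, "gametogenesis", "meiosis", NA, "gametogenesis",
                    "gametogenesis", NA)
  )
}

# internal helpers reused across test files
species_codes <- comodbm:::species_codes
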