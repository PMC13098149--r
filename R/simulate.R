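#' Simulation configuration for the synthetic fixture generator
#'
#' Builds the configuration driving [simulate_bundle()]. The defaults are the
#' package's reference study conditions: 204 seed genes across five species,
#' genome backgrounds of roughly 7,500-21,000 genes with mouse orthologs,
#' ortholog retention falling with evolutionary distance (so ~61% of genes
#' trace to roundworm), negative-binomial-like phenotype counts (Poisson
#' rates mixed with per-gene gamma propensities, partially shared across
#' species to create cross-species concordance), four planted comorbidity
#' classes shaping the mouse count vectors, and expression/GO blocks whose
#' means depend on the planted class.
#'
#' @param preset `"study"` (default: planted enrichment, four classes,
#'   two-tier concordance) or `"null"` (no enrichment anywhere, a single
#'   class equal to the background rates, uniform concordance share — seed
#'   genes statistically exchangeable with the background).
#' @param ... Named overrides for any config element (see Details).
#' @details Elements: `n_seed_genes`; `genome_sizes`, `ortholog_retention`
#'   (named per species); `confidence_mix` (high/moderate split of retained
#'   orthologs); `decoy_low_rate` (extra low-confidence records);
#'   `baseline_rates` (species x 19 channel matrix of background Poisson
#'   means; the `Fertility` column is the fertility-term channel, which also
#'   feeds `Genitourinary`); `enrichment` (tibble `species`, `category`,
#'   `rho` of seed-gene rate multipliers); `class_props`, `class_rates`
#'   (planted mouse class mixture); `concordance_share`, `share_high`,
#'   `share_high_frac` (shared-propensity fractions), `gamma_shape`;
#'   `driver_effects` (class-dependent expression mean shifts and GO
#'   probabilities); `n_terms_per_category`, `fert_allocation` (ontology
#'   pool sizes); `annotation_probs` (mechanism-label probabilities by
#'   concordance tier).
#' @return A list of class `como_sim_config`.
#' @export
sim_config <- function(preset = c("study", "null"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_seed_genes = 204L,
    genome_sizes = c(human = 17000L, mouse = 21000L, zebrafish = 12774L,
                     fly = 8000L, worm = 7500L),
    ortholog_retention = c(human = 0.95, mouse = 1, zebrafish = 0.78,
                           fly = 0.41, worm = 0.61),
    confidence_mix = c(high = 0.6, moderate = 0.4),
    decoy_low_rate = 0.08,
    baseline_rates = default_baseline_rates(),
    enrichment = default_enrichment(),
    class_props = c(42, 84, 22, 43) / 191,
    class_rates = default_class_rates(),
    concordance_share = 0.6,
    share_high = 1.0,
    share_high_frac = 0.3,
    activity_boost = 12,
    gamma_shape = 0.35,
    mouse_share = 0.15,
    mouse_gamma_shape = 20,
    driver_effects = default_driver_effects(),
    expression_base = list(celltype_meanlog = 1, celltype_sdlog = 0.6,
                           tissue_meanlog = 1.2, tissue_sdlog = 0.8),
    n_terms_per_category = 60L,
    fert_allocation = default_fert_allocation(),
    annotation_probs = c(high_tier = 0.6, low_tier = 0.1, other = 0.15),
    mask = default_mask()
  )
  if (preset == "null") {
    cfg$enrichment <- cfg$enrichment[0, ]
    cfg$class_props <- 1
    cfg$class_rates <- cfg$baseline_rates["mouse", , drop = FALSE]
    cfg$share_high_frac <- 0
    cfg$activity_boost <- 1
  }
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config element: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  cfg[names(override)] <- override
  validate_sim_config(structure(cfg, class = "como_sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_seed_genes >= 1,
    all(cfg$ortholog_retention >= 0 & cfg$ortholog_retention <= 1),
    all(cfg$baseline_rates >= 0), all(cfg$class_rates >= 0),
    all(cfg$enrichment$rho >= 0),
    cfg$concordance_share >= 0, cfg$concordance_share <= 1,
    cfg$share_high_frac >= 0, cfg$share_high_frac <= 1,
    cfg$gamma_shape > 0,
    abs(sum(cfg$class_props) - 1) < 1e-8,
    nrow(cfg$class_rates) == length(cfg$class_props)
  )
  cfg
}

# background channel rates (Poisson means); Fertility column = fertility-term
# channel (counts additionally into Genitourinary)
default_baseline_rates <- function() {
  cats <- mcat_categories()
  sp <- species_codes()
  base_scale <- c(human = 0.25, mouse = 0.15, zebrafish = 0.12, fly = 0.15, worm = 0.20)
  m <- outer(base_scale[sp], rep(1, length(cats)))
  dimnames(m) <- list(sp, cats)
  m[, "Fertility"] <- c(human = 0.02, mouse = 0.08, zebrafish = 0.05,
                        fly = 0.12, worm = 12.0)[sp]
  m["worm", "Genitourinary"] <- 0.10   # worm GU base low; fertility channel dominates
  m["zebrafish", "Genitourinary"] <- 0.08
  m
}

# seed-gene rate multipliers emulating the class-level associations seen in
# heavily curated databases; mouse enrichment is carried by class_rates instead
default_enrichment <- function() {
  tibble::tribble(
    ~species,    ~category,                        ~rho,
    "human",     "Fertility",                      28,
    "human",     "Genitourinary",                  3.5,
    "human",     "Neoplasm",                       3.0,
    "human",     "Integument",                     2.5,
    "human",     "Nervous System",                 2.0,
    "human",     "Growth Abnormality",             2.0,
    "human",     "Endocrine",                      2.0,
    "human",     "Metabolism",                     2.0,
    "human",     "Blood and Immune",               2.0,
    "human",     "Cardiovascular",                 1.8,
    "human",     "Digestive",                      1.8,
    "zebrafish", "Genitourinary",                  3.0,
    "zebrafish", "Integument",                     3.3,
    "fly",       "Fertility",                      2.2,
    "fly",       "Genitourinary",                  3.8,
    "fly",       "Neoplasm",                       3.4,
    "fly",       "Prenatal Development or Birth",  2.3,
    "worm",      "Fertility",                      1.3,
    "worm",      "Genitourinary",                  1.8
  )
}

# planted mouse class channel rates: 1 isolated infertility, 2 extensive
# reproductive + molecular/cellular "Other", 3 broad comorbidities,
# 4 nervous-system-led
default_class_rates <- function() {
  cats <- mcat_categories()
  m <- matrix(0.15, nrow = 4, ncol = length(cats), dimnames = list(1:4, cats))
  m[1, ] <- c(0.3, 0.5, 0.3, 0.1, 0.1, 0.1, 0.1, 0.2, 0.3, 0.2, 0.1, 0.1, 0.2,
              2.3, 0.3, 0.5, 0.1, 1.0, 3.0)
  m[2, ] <- c(0.4, 0.6, 0.4, 0.1, 0.2, 0.1, 0.1, 0.3, 0.4, 0.2, 0.1, 0.1, 0.2,
              4.3, 0.4, 0.6, 0.2, 2.2, 6.0)
  m[3, ] <- c(5.0, 8.0, 4.0, 2.0, 6.0, 2.0, 2.5, 4.0, 5.0, 3.5, 2.0, 2.0, 3.5,
              8.0, 3.0, 5.0, 5.0, 6.0, 4.5)
  m[4, ] <- c(2.0, 3.0, 12.0, 2.5, 1.0, 1.0, 1.0, 2.0, 2.5, 1.5, 1.0, 1.0, 1.5,
              4.0, 1.5, 3.0, 1.0, 3.0, 4.0)
  m
}

#' @rdname sim_config
#' @export
celltype_names <- function() {
  c("SSC", "diff_spermatogonia", "leptotene_spermatocyte", "pachytene_spermatocyte",
    "round_spermatid", "elongating_spermatid", "sperm", "Sertoli", "Leydig",
    "peritubular_myoid", "endothelial", "macrophage", "lymphocyte")
}

#' @rdname sim_config
#' @export
tissue_names <- function() {
  organs <- c("Testis", "Ovary", "Pancreas", "Hippocampus", "Aorta", "Liver",
              "Lung", "Heart", "Kidney", "Spleen", "Thyroid", "Adrenal",
              "Pituitary", "Prostate", "Uterus", "Vagina", "Breast", "Skin_sun",
              "Skin_nosun", "Muscle", "Nerve_tibial", "Artery_tibial",
              "Artery_coronary", "Whole_blood", "Esophagus_mucosa",
              "Esophagus_muscularis", "Stomach", "Colon_sigmoid",
              "Colon_transverse", "Small_intestine", "Adipose_subcut",
              "Adipose_visceral", "Cerebellum", "Cortex", "Frontal_cortex",
              "Caudate", "Putamen", "Nucleus_accumbens", "Amygdala",
              "Hypothalamus", "Substantia_nigra", "Spinal_cord", "Cervix_ecto",
              "Cervix_endo", "Fallopian_tube", "Bladder", "Minor_salivary",
              "Fibroblasts", "Lymphocytes_EBV", "Pons", "Anterior_cingulate",
              "Esophagus_junction", "Heart_atrial", "Liver_caudate")
  organs[1:54]
}

#' @rdname sim_config
#' @export
go_names <- function() {
  c("response to stimulus", "signaling", "system development",
    "programmed cell death", "DNA-templated transcription",
    "cell differentiation", "cellular component organization",
    "cell cycle", "DNA repair", "chromatin organization", "RNA processing",
    "translation", "protein modification", "transport", "metabolic process",
    "catalytic activity", "DNA binding", "RNA binding", "protein binding",
    "ATP binding", "kinase activity", "transcription factor activity",
    "receptor activity", "structural molecule", "enzyme regulator",
    "transporter activity")
}

#' The nine mechanistic gene annotation labels
#' @export
mechanism_labels <- function() {
  c("meiotic arrest/cell cycle", "DNA damage and repair", "sperm motility",
    "Sertoli cell", "RNA binding/post-transcriptional", "hormone signaling",
    "germ cell", "apoptosis", "chromatin/epigenetic")
}

# class-dependent expression mean shifts (meanlog scale) and GO probabilities
default_driver_effects <- function() {
  ct <- matrix(0, 4, 13, dimnames = list(1:4, celltype_names()))
  germ4 <- c("SSC", "diff_spermatogonia", "leptotene_spermatocyte",
             "pachytene_spermatocyte")
  ct[1, germ4] <- 0.8; ct[1, "Sertoli"] <- 0.2
  ct[2, germ4] <- 0.8
  ct[3, c("diff_spermatogonia", "Sertoli", "endothelial")] <- c(0.5, 0.4, 0.3)
  ct[4, c("Leydig", "Sertoli", "endothelial", "macrophage", "lymphocyte",
          "peritubular_myoid", "SSC", "round_spermatid", "sperm",
          "elongating_spermatid")] <- 0.35

  ti <- matrix(0, 4, 54, dimnames = list(1:4, tissue_names()))
  ti[1:2, "Testis"] <- c(1.5, 1.2)
  ti[1:2, "Pancreas"] <- 0.6
  ti[1:2, "Hippocampus"] <- 0.5
  ti[3:4, "Ovary"] <- 0.8
  ti[3:4, "Aorta"] <- 0.7
  broad <- c("Liver", "Lung", "Heart", "Kidney", "Spleen", "Cortex", "Muscle",
             "Whole_blood", "Thyroid", "Adrenal")
  ti[3, broad] <- 0.4
  ti[4, c("Cortex", "Cerebellum", "Hippocampus", "Frontal_cortex", "Nerve_tibial")] <- 0.5

  go <- matrix(0.15, 4, 26, dimnames = list(1:4, go_names()))
  go[1, c("cell differentiation", "cellular component organization")] <- c(0.50, 0.63)
  go[2, c("cell differentiation", "cellular component organization",
          "DNA repair", "cell cycle")] <- c(0.45, 0.55, 0.35, 0.35)
  go[3, ] <- 0.35
  go[3, c("response to stimulus", "signaling", "system development",
          "programmed cell death", "DNA-templated transcription")] <-
    c(0.99, 0.91, 0.77, 0.73, 0.63)
  go[4, c("response to stimulus", "system development", "signaling")] <-
    c(0.74, 0.67, 0.5)
  list(celltype = ct, tissue = ti, go = go)
}

# fertility-term ontology pool sizes per species x reproductive group; the
# vertebrate/invertebrate contrasts (zebrafish-heavy gametogenesis, a single
# fly gametogenesis term, coarse fly vocabulary) follow the reference counts
default_fert_allocation <- function() {
  g <- default_repro_groups()
  m <- matrix(0L, nrow = 5, ncol = 13, dimnames = list(species_codes(), g))
  m["human", ] <- c(6L, 8L, 22L, 12L, 10L, 8L, 6L, 8L, 6L, 2L, 10L, 12L, 10L)
  m["mouse", ] <- c(8L, 10L, 28L, 14L, 10L, 8L, 8L, 10L, 6L, 2L, 10L, 8L, 8L)
  m["zebrafish", ] <- c(10L, 14L, 112L, 16L, 8L, 6L, 4L, 8L, 6L, 2L, 8L, 4L, 4L)
  m["fly", ] <- c(0L, 0L, 1L, 2L, 0L, 0L, 0L, 0L, 0L, 2L, 0L, 4L, 4L)
  m["worm", ] <- c(8L, 10L, 16L, 8L, 2L, 2L, 2L, 4L, 6L, 2L, 6L, 4L, 4L)
  m
}

# closed-form flag probability P(count >= 1) for rate lambda under the
# shared/private gamma mixing: u = s*G1 + (1-s)*G2, G ~ Gamma(shape a, rate a)
flag_prob <- function(lambda, share, shape, private_shape = shape) {
  1 - (1 + lambda * share / shape)^(-shape) *
    (1 + lambda * (1 - share) / private_shape)^(-private_shape)
}

# draw an n_genes x 19 channel count matrix for one species
# rates: 19-vector of per-channel Poisson means for each gene (matrix allowed)
draw_channel_counts <- function(rates, shared_g, share, shape,
                                private_shape = shape) {
  # rates: n x 19; shared_g: n x 19 shared gamma; share: length-n vector
  n <- nrow(rates)
  private_g <- matrix(stats::rgamma(n * ncol(rates), shape = private_shape,
                                    rate = private_shape), nrow = n)
  u <- share * shared_g + (1 - share) * private_g
  matrix(stats::rpois(n * ncol(rates), lambda = rates * u), nrow = n,
         dimnames = dimnames(rates))
}

#' Draw one gene's 19-channel phenotype counts
#'
#' Single-draw convenience wrapper over the generator's count model:
#' Poisson counts with rate `lambda * rho * u`, where `u` mixes a shared and
#' a private gamma propensity (`share` and `1 - share` weights, shape
#' `gamma_shape`), giving negative-binomial-like marginals with tunable
#' cross-species concordance.
#'
#' @param config A `como_sim_config`.
#' @param species Species whose baseline rates to use.
#' @param class Planted class (row of `class_rates`) when `species` is
#'   `"mouse"`.
#' @param seed Integer seed.
#' @return Named integer 19-vector of channel counts (the `Fertility`
#'   channel holds fertility-term counts, which also feed `Genitourinary`
#'   in profile space).
#' @export
draw_counts <- function(config, species, class = 1L, seed = 1L) {
  rates <- sim_seed_rates(config, species, class)
  with_seed(seed, {
    shared <- matrix(stats::rgamma(ncol(rates), config$gamma_shape,
                                   config$gamma_shape), nrow = 1)
    drop(draw_channel_counts(rates, shared, config$concordance_share,
                             config$gamma_shape))
  })
}

# per-gene seed rates for a species: baseline * enrichment rho (non-mouse),
# or the planted class rates * rho (mouse)
sim_seed_rates <- function(config, species, classes = 1L) {
  cats <- mcat_categories()
  rho <- rep(1, length(cats)); names(rho) <- cats
  e <- config$enrichment[config$enrichment$species == species, ]
  rho[e$category] <- e$rho
  base <- if (species == "mouse") {
    config$class_rates[classes, , drop = FALSE]
  } else {
    matrix(config$baseline_rates[species, ], nrow = length(classes),
           ncol = length(cats), byrow = TRUE, dimnames = list(NULL, cats))
  }
  sweep(base, 2, rho, `*`)
}

#' Generate a complete synthetic input bundle
#'
#' Draws a full, internally consistent set of pipeline inputs — term map,
#' applicability mask, ortholog table, per-gene payloads, genome
#' backgrounds, expression and GO blocks, mechanism annotations — together
#' with the planted ground truth needed to score recovery. The same seed
#' yields a byte-identical bundle.
#'
#' The count model and the genome background are coherent: profile counts
#' are distinct sampled ontology terms, and the per-category background
#' totals are drawn from the exact closed-form flag probability of the same
#' count model, so under the `"null"` preset seed genes are statistically
#' exchangeable with the background.
#'
#' @param config A `como_sim_config` from [sim_config()].
#' @param seed Integer seed.
#' @param materialize_terms If `FALSE`, skip sampling individual ontology
#'   terms and payloads (fast path for simulation studies that only need
#'   the profile matrix).
#' @return A list of class `como_bundle`: `config`, `matrix` (a
#'   `como_matrix`), `truth` (per-gene tibble: planted class, concordance
#'   tier, retention flags, oldest species), `term_map`, `mask`,
#'   `orthologs`, `payloads`, `expression` (`celltype`, `tissue`, `go`
#'   tibbles), `annotations`.
#' @seealso [write_bundle()] to put the bundle on disk in the documented
#'   file formats.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1L,
                            materialize_terms = TRUE) {
  stopifnot(inherits(config, "como_sim_config"))
  with_seed(seed, {
    cats <- mcat_categories()
    n <- config$n_seed_genes
    genes <- sprintf("Gene%04d", seq_len(n))
    k <- length(config$class_props)
    classes <- sample.int(k, n, replace = TRUE, prob = config$class_props)

    # concordance tiers
    high_tier <- stats::runif(n) < config$share_high_frac
    share <- ifelse(high_tier, config$share_high, config$concordance_share)

    # ortholog retention (mouse always present)
    retained <- vapply(species_codes(), function(s) {
      if (s == "mouse") rep(TRUE, n)
      else stats::runif(n) < config$ortholog_retention[[s]]
    }, logical(n))

    # shared propensity per gene x channel
    shared_g <- matrix(stats::rgamma(n * length(cats), config$gamma_shape,
                                     config$gamma_shape), nrow = n)

    # per-species channel counts; high-tier genes carry an annotation-depth
    # boost in the non-mouse species (well-studied genes accumulate terms)
    channel <- lapply(stats::setNames(species_codes(), species_codes()), function(s) {
      rates <- sim_seed_rates(config, s,
                              classes = if (s == "mouse") classes else seq_len(n) * 0 + 1)
      if (s != "mouse") {
        rates <- rates[rep(1, n), , drop = FALSE]
        rates[high_tier, ] <- rates[high_tier, , drop = FALSE] * config$activity_boost
      }
      dimnames(rates) <- list(genes, cats)
      cnt <- if (s == "mouse") {
        # mouse: modest weight on the shared propensity plus a mild private
        # gamma, keeping the planted class structure recoverable
        draw_channel_counts(rates, shared_g, config$mouse_share,
                            config$gamma_shape, config$mouse_gamma_shape)
      } else {
        draw_channel_counts(rates, shared_g, share, config$gamma_shape)
      }
      # counts are distinct ontology terms, so the term pool caps them
      pool_size <- rep(config$n_terms_per_category, length(cats))
      names(pool_size) <- cats
      pool_size["Fertility"] <- sum(config$fert_allocation[s, ])
      cnt <- pmin(cnt, matrix(pool_size, nrow = n, ncol = length(cats),
                              byrow = TRUE))
      # masked channels are unobservable
      off <- config$mask[!config$mask$testable & config$mask$species == s, ]
      cnt[, off$category] <- 0L
      cnt[!retained[, s], ] <- 0L
      cnt
    })

    # profile counts: Genitourinary gains the fertility channel
    profiles <- purrr::imap(channel, function(cnt, s) {
      prof <- cnt
      prof[, "Genitourinary"] <- prof[, "Genitourinary"] + prof[, "Fertility"]
      tibble::tibble(gene = genes, species = s,
                     ortholog_present = retained[, s],
                     n_raw_annotations = as.integer(rowSums(cnt))) |>
        dplyr::bind_cols(tibble::as_tibble(prof))
    }) |> purrr::list_rbind()

    # genome background: closed-form flag probabilities under baseline rates
    background <- purrr::map(species_codes(), function(s) {
      lam <- config$baseline_rates[s, ]
      p_one <- if (s == "mouse") {
        function(l) flag_prob(l, config$mouse_share, config$gamma_shape,
                              config$mouse_gamma_shape)
      } else {
        function(l) {   # mixture over concordance/annotation tiers
          config$share_high_frac *
            flag_prob(l * config$activity_boost, config$share_high, config$gamma_shape) +
            (1 - config$share_high_frac) *
              flag_prob(l, config$concordance_share, config$gamma_shape)
        }
      }
      fert_ok <- isTRUE(mask_lookup(config$mask, s, "Fertility"))
      p <- vapply(cats, function(cc) {
        if (!isTRUE(mask_lookup(config$mask, s, cc))) return(0)
        if (cc == "Genitourinary" && fert_ok) {
          1 - (1 - p_one(lam[["Genitourinary"]])) * (1 - p_one(lam[["Fertility"]]))
        } else p_one(lam[[cc]])
      }, numeric(1))
      n_seed_here <- sum(retained[, species_codes() == s])
      n_bg <- config$genome_sizes[[s]] - n_seed_here
      bg_draw <- stats::rbinom(length(cats), n_bg, p)
      prof_s <- profiles[profiles$species == s, ]
      seed_flags <- colSums(as.matrix(prof_s[cats]) >= 1)
      tibble::tibble(species = s, genome_size = config$genome_sizes[[s]]) |>
        dplyr::bind_cols(tibble::as_tibble(as.list(bg_draw + seed_flags)) |>
                           stats::setNames(cats))
    }) |> purrr::list_rbind()

    mat <- assemble_matrix(profiles, background, config$mask)

    # orthologs: retained records (high/moderate) plus low-confidence decoys
    orthologs <- purrr::map(setdiff(species_codes(), "mouse"), function(s) {
      idx <- which(retained[, s])
      conf <- sample(c("high", "moderate"), length(idx), replace = TRUE,
                     prob = config$confidence_mix)
      rec <- tibble::tibble(
        source_gene = genes[idx], target_species = s,
        target_symbol = paste0(tolower(genes[idx]), "_", substr(s, 1, 2)),
        target_id = 100000L + idx,
        diopt_score = ifelse(conf == "high", 13L, 8L),
        confidence = conf, is_best = TRUE
      )
      decoy_idx <- which(stats::runif(n) < config$decoy_low_rate)
      if (length(decoy_idx) > 0) {
        rec <- dplyr::bind_rows(rec, tibble::tibble(
          source_gene = genes[decoy_idx], target_species = s,
          target_symbol = paste0(tolower(genes[decoy_idx]), "_", substr(s, 1, 2), "b"),
          target_id = 900000L + decoy_idx, diopt_score = 2L,
          confidence = "low", is_best = FALSE
        ))
      }
      rec
    }) |> purrr::list_rbind()

    truth <- tibble::tibble(gene = genes, class = classes, high_tier = high_tier,
                            share = share) |>
      dplyr::bind_cols(tibble::as_tibble(retained) |>
                         stats::setNames(paste0("retained_", species_codes())))
    truth <- dplyr::left_join(
      truth,
      assign_oldest_species(genes, filter_orthologs(orthologs, "moderate")),
      by = "gene"
    )

    term_map <- simulate_term_map(config)
    payloads <- NULL
    if (materialize_terms) {
      payloads <- simulate_payloads(genes, channel, retained, term_map, orthologs)
    }

    expr <- simulate_expression(config, classes, genes)
    annotations <- simulate_annotations(config, genes, high_tier)

    structure(list(config = config, matrix = mat, truth = truth,
                   term_map = term_map, mask = config$mask,
                   orthologs = orthologs, payloads = payloads,
                   expression = expr, annotations = annotations),
              class = "como_bundle")
  })
}

# deterministic synthetic ontology: base-category pools plus the configured
# fertility-group allocation
simulate_term_map <- function(config) {
  sp <- como_species()
  cats18 <- mcat_categories(base_only = TRUE)
  groups <- default_repro_groups()
  purrr::map(seq_len(nrow(sp)), function(i) {
    s <- sp$species[i]
    counter <- 0L
    mk_id <- function(m) {
      ids <- sprintf("%s%07d", sp$prefix[i], counter + seq_len(m))
      counter <<- counter + m
      ids
    }
    base <- purrr::map(cats18, function(cc) {
      m <- config$n_terms_per_category
      tibble::tibble(term_id = mk_id(m), species = s,
                     label = paste0("synthetic ", s, " ", tolower(cc), " term ",
                                    seq_len(m)),
                     base_category = cc, is_fertility = FALSE,
                     repro_group = NA_character_)
    }) |> purrr::list_rbind()
    fert <- purrr::map(groups, function(g) {
      m <- config$fert_allocation[s, g]
      if (m == 0) return(NULL)
      tibble::tibble(term_id = mk_id(m), species = s,
                     label = paste0("synthetic ", s, " fertility term (", g, ") ",
                                    seq_len(m)),
                     base_category = "Genitourinary", is_fertility = TRUE,
                     repro_group = g)
    }) |> purrr::compact() |> purrr::list_rbind()
    dplyr::bind_rows(base, fert)
  }) |> purrr::list_rbind()
}

# materialize channel counts as distinct sampled ontology terms + payloads
simulate_payloads <- function(genes, channel, retained, term_map, orthologs) {
  cats <- mcat_categories()
  pools <- split(term_map$term_id,
                 paste(term_map$species,
                       ifelse(term_map$is_fertility, "Fertility", term_map$base_category),
                       sep = "\r"))
  ort_by_gene <- split(orthologs[orthologs$confidence != "low", ],
                       orthologs$source_gene[orthologs$confidence != "low"])
  purrr::map(seq_along(genes), function(gi) {
    g <- genes[gi]
    ort_block <- list(mouse = list(symbol = g, id = gi, diopt_score = 15L,
                                   confidence = "high", is_best = TRUE))
    og <- ort_by_gene[[g]]
    if (!is.null(og)) {
      for (j in seq_len(nrow(og))) {
        ort_block[[og$target_species[j]]] <- list(
          symbol = og$target_symbol[j], id = og$target_id[j],
          diopt_score = og$diopt_score[j], confidence = og$confidence[j],
          is_best = og$is_best[j]
        )
      }
    }
    phen <- list()
    for (s in species_codes()) {
      if (!retained[gi, s]) next
      terms <- character(0)
      for (cc in cats) {
        cnt <- channel[[s]][gi, cc]
        if (cnt == 0) next
        pool <- pools[[paste(s, cc, sep = "\r")]]
        if (cnt > length(pool)) {
          warning("term pool exhausted for ", s, " / ", cc, "; truncating",
                  call. = FALSE)
          cnt <- length(pool)
        }
        terms <- c(terms, sample(pool, cnt))
      }
      phen[[s]] <- lapply(terms, function(t) list(term_id = t, label = paste("synthetic", t)))
    }
    # species retained but with zero phenotypes still get an (empty) entry
    for (s in species_codes()) {
      if (retained[gi, s] && is.null(phen[[s]])) phen[[s]] <- list()
    }
    list(query_gene = g, orthologs = ort_block, phenotypes = phen)
  })
}

#' Simulate expression and GO blocks with class-dependent structure
#'
#' Draws the three driver blocks: raw testicular cell-type expression
#' (log-normal, per-class meanlog shifts from `driver_effects$celltype`),
#' whole-body tissue TPM (log-normal, shifts from `driver_effects$tissue`)
#' and GO indicators (Bernoulli with per-class probabilities from
#' `driver_effects$go`).
#'
#' @param config A `como_sim_config`.
#' @param classes Integer vector of planted classes per gene.
#' @param genes Gene names.
#' @return A list of tibbles `celltype`, `tissue`, `go`, each with a `gene`
#'   column then the feature columns.
#' @export
simulate_expression <- function(config, classes, genes) {
  de <- config$driver_effects
  eb <- config$expression_base
  n <- length(genes)
  draw_block <- function(shifts, meanlog, sdlog) {
    mu <- meanlog + shifts[classes, , drop = FALSE]
    m <- matrix(stats::rlnorm(n * ncol(shifts), meanlog = mu, sdlog = sdlog),
                nrow = n, dimnames = list(NULL, colnames(shifts)))
    dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
  }
  ct <- draw_block(de$celltype, eb$celltype_meanlog, eb$celltype_sdlog)
  ti <- draw_block(de$tissue, eb$tissue_meanlog, eb$tissue_sdlog)
  p <- de$go[classes, , drop = FALSE]
  go <- matrix(as.integer(stats::runif(n * ncol(de$go)) < p), nrow = n,
               dimnames = list(NULL, colnames(de$go)))
  list(celltype = ct, tissue = ti,
       go = dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(go)))
}

# mechanism labels: one focal label tracks the planted concordance tier
simulate_annotations <- function(config, genes, high_tier) {
  labs <- mechanism_labels()
  focal <- "DNA damage and repair"
  p <- config$annotation_probs
  out <- purrr::map(seq_along(genes), function(i) {
    keep <- stats::runif(length(labs)) <
      ifelse(labs == focal, if (high_tier[i]) p[["high_tier"]] else p[["low_tier"]],
             p[["other"]])
    if (!any(keep)) keep[sample.int(length(labs), 1)] <- TRUE
    tibble::tibble(gene = genes[i], label = labs[keep])
  }) |> purrr::list_rbind()
  out
}

#' Write a simulated bundle to disk in the documented file formats
#'
#' Emits `term_map.tsv`, `mask.tsv`, `orthologs.tsv`, `payloads/*.json`,
#' per-species gene-level `background_<species>.tsv`,
#' `expression_celltype.tsv`, `expression_tissue.tsv`, `go_indicator.tsv`,
#' `annotations.tsv` and `sim_truth.tsv`. Gene-level background indicator
#' flags are materialized consistently with the bundle's background totals.
#'
#' @param bundle A `como_bundle` (with payloads materialized).
#' @param dir Output directory (created if needed).
#' @param seed Seed for the background flag materialization.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_term_map(bundle$term_map, file.path(dir, "term_map.tsv"))
  write_mask(bundle$mask, file.path(dir, "mask.tsv"))
  ort <- bundle$orthologs
  ort$is_best <- as.logical(ort$is_best)
  readr::write_tsv(ort, file.path(dir, "orthologs.tsv"))
  pdir <- file.path(dir, "payloads")
  if (!dir.exists(pdir)) dir.create(pdir)
  if (is.null(bundle$payloads)) stop("bundle has no materialized payloads", call. = FALSE)
  for (p in bundle$payloads) {
    write_payload(p, file.path(pdir, paste0(p$query_gene, ".json")))
  }
  with_seed(seed, {
    cats <- mcat_categories()
    for (s in species_codes()) {
      bg <- bundle$matrix$background[bundle$matrix$background$species == s, ]
      prof <- bundle$matrix$profiles[bundle$matrix$profiles$species == s, ]
      prof <- prof[prof$ortholog_present, ]
      n_bg <- bg$genome_size - nrow(prof)
      bg_ids <- sprintf("BG%s%05d", toupper(substr(s, 1, 2)), seq_len(n_bg))
      flags <- matrix(0L, nrow = n_bg, ncol = length(cats),
                      dimnames = list(NULL, cats))
      for (cc in cats) {
        need <- bg[[cc]] - sum(prof[[cc]] >= 1)
        if (need > 0) flags[sample.int(n_bg, need), cc] <- 1L
      }
      seed_part <- dplyr::bind_cols(
        tibble::tibble(gene_id = prof$gene, has_mouse_ortholog = 1L),
        tibble::as_tibble(1L * (as.matrix(prof[cats]) >= 1))
      )
      bg_part <- dplyr::bind_cols(
        tibble::tibble(gene_id = bg_ids, has_mouse_ortholog = 1L),
        tibble::as_tibble(flags)
      )
      readr::write_tsv(dplyr::bind_rows(seed_part, bg_part),
                       file.path(dir, paste0("background_", s, ".tsv")))
    }
  })
  readr::write_tsv(bundle$expression$celltype, file.path(dir, "expression_celltype.tsv"))
  readr::write_tsv(bundle$expression$tissue, file.path(dir, "expression_tissue.tsv"))
  readr::write_tsv(bundle$expression$go, file.path(dir, "go_indicator.tsv"))
  readr::write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "sim_truth.tsv"))
  invisible(dir)
}
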