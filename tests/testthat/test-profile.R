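toy_payload <- function() {
  list(
    query_gene = "Abc1",
    orthologs = list(
      mouse = list(symbol = "Abc1", id = 1L, diopt_score = 15L,
                   confidence = "high", is_best = TRUE),
      human = list(symbol = "ABC1", id = 2L, diopt_score = 12L,
                   confidence = "high", is_best = TRUE)
    ),
    phenotypes = list(
      mouse = list(
        list(term_id = "MP:0000002", label = "fert m1"),
        list(term_id = "MP:0000003", label = "fert m2"),
        list(term_id = "MP:0000004", label = "nervous m")
      ),
      human = list()
    )
  )
}

test_that("payload parsing separates missing orthologs from empty annotation", {
  p <- parse_payload(toy_payload())
  expect_equal(p$gene, "Abc1")
  expect_equal(nrow(p$records), 3)
  pres <- p$presence
  expect_true(all(pres$ortholog_present[pres$species %in% c("mouse", "human")]))
  expect_false(any(pres$ortholog_present[pres$species %in% c("worm", "fly", "zebrafish")]))

  # single mouse term: 1 record, 4 species absent
  single <- toy_payload()
  single$phenotypes <- list(mouse = list(list(term_id = "MP:0000004", label = "x")))
  single$orthologs$human <- NULL
  ps <- parse_payload(single)
  expect_equal(nrow(ps$records), 1)
  expect_equal(sum(ps$presence$ortholog_present), 1)

  expect_error(parse_payload(list(foo = 1)), "query_gene")
  bad <- toy_payload()
  names(bad$phenotypes)[1] <- "gorilla"
  expect_error(parse_payload(bad), "gorilla")
})

test_that("payloads round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  write_payload(toy_payload(), f)
  back <- parse_payload(read_payload(f))
  direct <- parse_payload(toy_payload())
  expect_equal(back$records, direct$records)
  expect_equal(back$presence, direct$presence)
})

test_that("profiles count fertility terms additively and respect the mask", {
  tm <- toy_term_map()
  p <- parse_payload(toy_payload())
  prof <- build_profile("Abc1", p$records, tm, presence = p$presence)

  mo <- prof[prof$species == "mouse", ]
  expect_equal(mo[["Fertility"]], 2L)        # two fertility terms
  expect_equal(mo[["Genitourinary"]], 2L)    # same terms, base category
  expect_equal(mo[["Nervous System"]], 1L)
  expect_equal(mo$n_raw_annotations, 3L)
  # sum over base categories equals mapped annotations; Fertility on top
  base_sum <- sum(as.numeric(mo[mcat_categories(base_only = TRUE)]))
  expect_equal(base_sum, 3)

  # human present with zero annotations: observed zero, not missing
  hu <- prof[prof$species == "human", ]
  expect_true(hu$ortholog_present)
  expect_equal(sum(as.numeric(hu[mcat_categories()])), 0)
  # worm: no ortholog
  expect_false(prof$ortholog_present[prof$species == "worm"])

  # zebrafish fertility terms never reach the Fertility column (default mask)
  rec <- tibble::tibble(species = "zebrafish", term_id = "ZP:0000010")
  zprof <- build_profile("g", rec, tm,
                         presence = tibble::tibble(species = species_codes(),
                                                   ortholog_present = species_codes() == "zebrafish"))
  zrow <- zprof[zprof$species == "zebrafish", ]
  expect_equal(zrow[["Fertility"]], 0L)
  expect_equal(zrow[["Genitourinary"]], 1L)  # base category still counted

  # record order does not matter
  rec3 <- p$records[c(3, 1, 2), ]
  expect_equal(build_profile("Abc1", rec3, tm, presence = p$presence), prof)

  # duplicated (species, term) annotations count once
  dup <- dplyr::bind_rows(p$records, p$records[1, ])
  expect_equal(build_profile("Abc1", dup, tm, presence = p$presence), prof)

  # unmapped terms warn and are dropped
  rec_bad <- dplyr::bind_rows(p$records,
                              tibble::tibble(source_gene = "Abc1", species = "mouse",
                                             target_symbol = "Abc1",
                                             term_id = "MP:0999999", label = "?"))
  expect_warning(prof2 <- build_profile("Abc1", rec_bad, tm, presence = p$presence),
                 "unmapped")
  expect_equal(prof2[prof2$species == "mouse", ][["Genitourinary"]], 2L)
})

test_that("matrix assembly validates backgrounds and orders genes", {
  tm <- toy_term_map()
  p <- parse_payload(toy_payload())
  prof_b <- build_profile("Abc1", p$records, tm, presence = p$presence)
  prof_a <- dplyr::mutate(prof_b, gene = "Aaa1")
  bg <- tibble::tibble(species = species_codes(), genome_size = 100L)
  bg <- dplyr::bind_cols(bg, tibble::as_tibble(
    matrix(5L, 5, 19, dimnames = list(NULL, mcat_categories()))))

  m <- assemble_matrix(list(prof_b, prof_a), bg)
  expect_s3_class(m, "como_matrix")
  expect_equal(unique(m$profiles$gene), c("Aaa1", "Abc1"))   # lexicographic

  expect_error(assemble_matrix(list(prof_b, prof_b), bg), "duplicate")

  bad_bg <- dplyr::mutate(bg, genome_size = 2L)
  expect_error(assemble_matrix(list(prof_b), bad_bg), "exceeds genome size")

  # empty profile set is a valid (empty) matrix
  empty <- assemble_matrix(prof_b[0, ], bg)
  expect_equal(nrow(empty$profiles), 0)
})

test_that("fertility linkage uses orthologs as denominator and the zebrafish proxy", {
  b <- simulate_bundle(tiny_sim(), seed = 5, materialize_terms = FALSE)
  link <- summarize_fertility_linkage(b$matrix)
  expect_equal(link$n_seed, rep(40L, 5))
  pres <- dplyr::count(dplyr::filter(b$matrix$profiles, ortholog_present), species)
  expect_equal(link$n_orthologs, pres$n[match(link$species, pres$species)])
  expect_equal(link$proxy_category[link$species == "zebrafish"], "Genitourinary")
  expect_true(all(is.na(link$proxy_category[link$species != "zebrafish"])))
  expect_true(all(link$fraction >= 0 & link$fraction <= 1))

  # all-zero matrix gives zero linkage everywhere
  zero <- b$matrix
  zero$profiles[mcat_categories()] <- 0L
  expect_true(all(summarize_fertility_linkage(zero)$fraction == 0))
})
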