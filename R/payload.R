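#' Parse a per-gene genotype-phenotype payload
#'
#' Payloads are JSON documents, one per seed gene, in the schema emitted by
#' aggregate model-organism databases: a `query_gene`, an `orthologs` block
#' keyed by species, and a `phenotypes` block keyed by species holding
#' `term_id`/`label` pairs. A species absent from the `orthologs` block is
#' recorded as having no ortholog; a species present with an empty phenotype
#' list is an ortholog with no annotations — the two are distinct.
#'
#' @param doc A payload as an R list (from [read_payload()]), or a file path.
#' @return A list with `gene`, `records` (tibble `source_gene`, `species`,
#'   `target_symbol`, `term_id`, `label`; one row per annotation) and
#'   `presence` (tibble `species`, `ortholog_present`, `target_symbol`).
#' @export
parse_payload <- function(doc) {
  if (is.character(doc) && length(doc) == 1) return(parse_payload(read_payload(doc)))
  if (!is.list(doc) || is.null(doc$query_gene)) {
    stop("malformed payload: missing 'query_gene'", call. = FALSE)
  }
  gene <- doc$query_gene
  ort <- doc$orthologs
  phe <- doc$phenotypes
  if (!is.null(ort) && is.null(names(ort)) && length(ort) > 0) {
    stop("malformed payload for ", gene, ": 'orthologs' must be keyed by species",
         call. = FALSE)
  }
  bad <- setdiff(c(names(ort), names(phe)), species_codes())
  if (length(bad) > 0) {
    stop("unknown species key in payload for ", gene, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  presence <- tibble::tibble(
    species = species_codes(),
    ortholog_present = species_codes() %in% names(ort),
    target_symbol = purrr::map_chr(species_codes(), function(s) {
      if (s %in% names(ort)) ort[[s]]$symbol %||% NA_character_ else NA_character_
    })
  )
  records <- purrr::imap(phe %||% list(), function(terms, s) {
    if (length(terms) == 0) return(NULL)
    ok <- vapply(terms, function(t) is.list(t) && !is.null(t$term_id), logical(1))
    if (!all(ok)) stop("malformed phenotype entry under '", s, "' for ", gene, call. = FALSE)
    tibble::tibble(
      source_gene = gene, species = s,
      target_symbol = presence$target_symbol[presence$species == s],
      term_id = vapply(terms, function(t) t$term_id, character(1)),
      label = vapply(terms, function(t) t$label %||% NA_character_, character(1))
    )
  }) |> purrr::compact() |> purrr::list_rbind()
  if (nrow(records) == 0) {
    records <- tibble::tibble(source_gene = character(), species = character(),
                              target_symbol = character(), term_id = character(),
                              label = character())
  }
  list(gene = gene, records = records, presence = presence)
}

#' Read / write payload JSON files
#'
#' @param path File path of a payload JSON document.
#' @return `read_payload()` returns the payload as a list; `write_payload()`
#'   writes one and returns `path` invisibly.
#' @export
read_payload <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed payload at ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  doc
}

#' @rdname read_payload
#' @param doc A payload list (same schema as [parse_payload()] consumes).
#' @export
write_payload <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = FALSE, digits = NA)
  invisible(path)
}

#' Read every payload in a directory
#'
#' @param dir Directory containing `*.json` payload documents.
#' @return A list of parsed payloads (see [parse_payload()]), sorted by file
#'   name.
#' @export
read_payload_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(files, parse_payload)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
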