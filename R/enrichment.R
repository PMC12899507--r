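#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one tab-separated line per set with term id,
#' description, then member gene ids. Sets with no members are dropped with
#' a warning; a duplicated term id keeps the last occurrence (with a
#' warning).
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of
#'   character vectors), `names` (term id -> description), `universe`
#'   (union of all members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warn("empty GMT file: returning empty collection")
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line(s): %s", paste(bad, collapse = ", ")),
          class = "droughtrank_parse_error")
  }
  ids <- purrr::map_chr(fields, 1)
  descs <- purrr::map_chr(fields, 2)
  members <- purrr::map(fields, ~ unique(.x[-(1:2)]))
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s)", sum(empty)))
    ids <- ids[!empty]; descs <- descs[!empty]; members <- members[!empty]
  }
  if (anyDuplicated(ids)) {
    warn("duplicated term id(s): keeping the last occurrence")
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; descs <- descs[keep]; members <- members[keep]
  }
  gene_set_collection(setNames(members, ids), setNames(descs, ids))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional gene universe; defaults to the union of all
#'   members.
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  descriptions <- descriptions %||% setNames(names(sets), names(sets))
  universe <- universe %||% sort(unique(unlist(sets)))
  structure(
    list(sets = sets, names = descriptions, universe = universe),
    class = "gene_set_collection"
  )
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::imap_chr(collection$sets, function(members, id) {
    paste(c(id, collection$names[[id]] %||% id, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' For each annotated set, tests over-representation of a query gene list
#' with the upper-tail hypergeometric probability
#' `P(X >= k)` where `k` is the query/set overlap, `K` the set size, `n` the
#' query size and `M` the universe size, then adjusts across sets with
#' Benjamini-Hochberg. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of gene ids.
#' @param collection a `gene_set_collection` (e.g. from [read_gmt()]).
#' @param universe optional universe override (e.g. the expressed-gene set);
#'   set members outside it are ignored.
#' @return a tibble sorted by ascending p with columns `term`, `name`, `k`,
#'   `K`, `n`, `M`, `pvalue`, `qvalue`, `genes` (list column of overlapping
#'   ids).
#' @examples
#' coll <- gene_set_collection(list(S1 = letters[1:5]),
#'                             universe = letters[1:20])
#' hypergeometric_enrichment(letters[1:10], coll)
#' @export
hypergeometric_enrichment <- function(query, collection, universe = NULL) {
  universe <- universe %||% collection$universe
  if (length(universe) == 0) {
    abort("empty gene universe", class = "droughtrank_input_error")
  }
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("dropping %d query gene(s) outside the universe",
                 length(outside)))
    query <- intersect(query, universe)
  }
  M <- length(universe)
  n <- length(query)
  res <- purrr::imap(collection$sets, function(members, id) {
    members <- intersect(members, universe)
    hits <- intersect(query, members)
    K <- length(members)
    k <- length(hits)
    # upper tail P(X >= k); vacuous overlap gives p = 1
    p <- if (k == 0) 1 else phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    tibble::tibble(term = id, name = collection$names[[id]] %||% id,
                   k = k, K = K, n = n, M = M, pvalue = p,
                   genes = list(sort(hits)))
  }) |>
    purrr::list_rbind()
  res |>
    dplyr::mutate(qvalue = p.adjust(.data$pvalue, "BH")) |>
    dplyr::arrange(.data$pvalue, .data$term) |>
    dplyr::relocate("qvalue", .after = "pvalue")
}
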