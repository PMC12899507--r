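#' Table schemas used by the pipeline
#'
#' Named column specifications for every tabular input the pipeline reads.
#' Each schema maps column name to expected type (`"character"`,
#' `"numeric"`, `"integer"`) plus optional range checks applied row-wise.
#'
#' @return a named list of schemas.
#' @keywords internal
table_schemas <- function() {
  list(
    germination_counts = list(
      cols = c(variety = "character", treatment = "character",
               day = "numeric", newly_germinated = "numeric",
               total_sown = "numeric"),
      checks = list(
        day = function(x) x >= 1,
        newly_germinated = function(x) x >= 0,
        total_sown = function(x) x > 0
      )
    ),
    seedlings = list(
      cols = c(variety = "character", treatment = "character",
               replicate = "numeric", root_mm = "numeric",
               shoot_mm = "numeric"),
      checks = list(root_mm = function(x) x >= 0,
                    shoot_mm = function(x) x >= 0)
    ),
    traits = list(
      cols = c(variety = "character", treatment = "character",
               timepoint_d = "numeric", trait = "character",
               replicate = "numeric", value = "numeric"),
      checks = list()
    ),
    de_table = list(
      cols = c(gene = "character", log2fc = "numeric", pvalue = "numeric"),
      checks = list(pvalue = function(x) x >= 0 & x <= 1)
    ),
    expression = NULL,  # validated structurally (gene column + numeric rest)
    ct_table = list(
      cols = c(gene = "character", sample = "character",
               treatment = "character", ct = "numeric"),
      checks = list(ct = function(x) x > 0)
    ),
    memberships = list(
      cols = c(variety = "character", trait = "character",
               membership = "numeric"),
      checks = list(membership = function(x) x >= 0 & x <= 1)
    )
  )
}

#' Read and validate a pipeline table
#'
#' Reads a TSV (comma-separated accepted) and validates it against one of
#' the named pipeline schemas, reporting offending columns and 1-based data
#' line numbers on failure.
#'
#' @param path file path.
#' @param schema schema name, one of `names(table_schemas())`, or a schema
#'   list of the same shape.
#' @return a validated tibble.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "droughtrank_io_error")
  }
  if (is.character(schema)) {
    schema <- table_schemas()[[match.arg(schema, names(table_schemas()))]]
  }
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_table(df, schema, what = basename(path))
}

#' Validate a data frame against a schema
#'
#' @param df data frame.
#' @param schema schema list with `cols` (name -> type) and `checks`
#'   (name -> predicate), or `NULL` to skip.
#' @param what label used in error messages.
#' @return the validated tibble (with columns coerced to schema types).
#' @export
validate_table <- function(df, schema, what = "table") {
  df <- tibble::as_tibble(df)
  if (is.null(schema)) return(df)
  check_columns(df, names(schema$cols), what)
  for (col in names(schema$cols)) {
    type <- schema$cols[[col]]
    x <- df[[col]]
    coerced <- switch(type,
      character = as.character(x),
      numeric = suppressWarnings(as.numeric(x)),
      integer = suppressWarnings(as.integer(x))
    )
    bad <- which(is.na(coerced) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("%s: column `%s` has unparseable value(s) at data line(s) %s",
                    what, col, paste(head(bad, 5), collapse = ", ")),
            class = "droughtrank_schema_error")
    }
    df[[col]] <- coerced
  }
  for (col in names(schema$checks)) {
    ok <- schema$checks[[col]](df[[col]])
    bad <- which(!ok | is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: column `%s` out of range at data line(s) %s",
                    what, col, paste(head(bad, 5), collapse = ", ")),
            class = "droughtrank_schema_error")
    }
  }
  df
}

#' Read an expression matrix
#'
#' TSV with a `gene` id column followed by one numeric column per sample.
#'
#' @param path file path.
#' @return a tibble (validated: unique gene ids, finite numeric values).
#' @export
read_expression_matrix <- function(path) {
  df <- read_table(path, schema = NULL)
  expr_as_matrix(df)  # structural validation; result discarded
  df
}

#' Write a tibble as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
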