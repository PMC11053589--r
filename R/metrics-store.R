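#' In-process metrics store
#'
#' Mirrors a cloud measurement API: one named endpoint per measurement
#' type, each backed by a typed table; clients ingest JSON arrays of flat
#' records and retrieve them with per-column filters.  Column types are
#' `text`, `integer`, `real` and `timestamp`; every schema must contain at
#' least one `timestamp` column because all measurements carry absolute
#' timestamps.
#'
#' @return A `metrics_store` object (environment-backed).
#' @export
metrics_store <- function() {
  env <- new.env(parent = emptyenv())
  env$endpoints <- list()
  structure(env, class = "metrics_store")
}

#' @export
print.metrics_store <- function(x, ...) {
  eps <- names(x$endpoints)
  cat(sprintf("<metrics_store> %d endpoint(s)%s\n", length(eps),
              if (length(eps)) paste0(": ", paste(eps, collapse = ", ")) else ""))
  invisible(x)
}

.store_types <- c("text", "integer", "real", "timestamp")

.empty_table <- function(columns) {
  cols <- lapply(unname(columns), function(ty)
    switch(ty, text = character(0), integer = integer(0), numeric(0)))
  names(cols) <- names(columns)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Define (or re-open) a measurement endpoint
#'
#' Creates the backing table for a measurement type.  Re-defining an
#' existing endpoint with an identical schema is a no-op; a different
#' schema under the same name is an error.
#'
#' @param store A [metrics_store()].
#' @param name Endpoint name (one per measurement type).
#' @param columns Named character vector mapping column names to types in
#'   `c("text", "integer", "real", "timestamp")`; at least one `timestamp`
#'   column is required.
#' @return The endpoint name, invisibly.
#' @export
define_endpoint <- function(store, name, columns) {
  stopifnot(inherits(store, "metrics_store"),
            is.character(name), length(name) == 1L, nzchar(name),
            is.character(columns), length(columns) > 0L)
  if (is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("`columns` must be a named character vector")
  if (anyDuplicated(names(columns)))
    stop("column names must be unique within a schema")
  bad <- setdiff(unique(columns), .store_types)
  if (length(bad))
    stop("unknown column type(s): ", paste(bad, collapse = ", "))
  if (!any(columns == "timestamp"))
    stop("schema must contain at least one timestamp column")
  existing <- store$endpoints[[name]]
  if (!is.null(existing)) {
    if (!identical(existing$columns, columns))
      stop(sprintf("endpoint '%s' already exists with a different schema", name))
    return(invisible(name))
  }
  store$endpoints[[name]] <- list(columns = columns,
                                  data = .empty_table(columns))
  invisible(name)
}

.get_endpoint <- function(store, name) {
  ep <- store$endpoints[[name]]
  if (is.null(ep)) stop(sprintf("unknown endpoint '%s'", name))
  ep
}

.check_record <- function(rec, columns) {
  if (!all(names(columns) %in% names(rec))) return("missing column(s)")
  for (col in names(columns)) {
    v <- rec[[col]]
    if (length(v) != 1L) return(sprintf("column '%s' is not scalar", col))
    ok <- switch(columns[[col]],
      text = is.character(v),
      integer = is.numeric(v) && is.finite(v) && v == floor(v),
      real = is.numeric(v) && is.finite(v),
      timestamp = is.numeric(v) && is.finite(v))
    if (!ok) return(sprintf("column '%s' violates type '%s'", col, columns[[col]]))
  }
  NULL
}

#' Ingest a batch of measurement records
#'
#' All-or-nothing: if any record violates the schema, nothing is stored and
#' the error names the index of the first offender.
#'
#' @param store A [metrics_store()].
#' @param name Endpoint name.
#' @param records A data.frame, or a list of named lists (as produced by
#'   parsing a JSON array of objects).
#' @return The number of records inserted.
#' @export
insert_records <- function(store, name, records) {
  ep <- .get_endpoint(store, name)
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i)
      as.list(records[i, , drop = FALSE]))
  if (length(records) == 0L) return(0L)
  for (i in seq_along(records)) {
    why <- .check_record(records[[i]], ep$columns)
    if (!is.null(why))
      stop(sprintf("record %d rejected (%s); batch not stored", i, why))
  }
  rows <- do.call(rbind, lapply(records, function(r) {
    out <- r[names(ep$columns)]
    as.data.frame(out, stringsAsFactors = FALSE)
  }))
  for (col in names(ep$columns))  # normalize storage classes
    rows[[col]] <- switch(ep$columns[[col]],
                          text = as.character(rows[[col]]),
                          integer = as.integer(rows[[col]]),
                          as.numeric(rows[[col]]))
  store$endpoints[[name]]$data <- rbind(ep$data, rows)
  length(records)
}

#' Parse HTTP-style query-string filters
#'
#' Grammar: `col=v` is an equality filter, `col.gt=v` strictly greater
#' than, `col.lt=v` strictly less than.  A numeric column may carry one
#' `gt` and one `lt` simultaneously (a range); a text column only supports
#' equality.  Values are coerced to the column type.
#'
#' @param query Query string, e.g. `"angle.gt=0.1&angle.lt=0.5"`.  An empty
#'   string yields an empty filter set (match everything).
#' @param columns The endpoint schema (named character vector of types).
#' @return A `filter_set`: list of `list(column, op, value)` with
#'   `op` in `c("eq", "gt", "lt")`.
#' @export
parse_filters <- function(query, columns) {
  stopifnot(is.character(query), length(query) == 1L)
  filters <- list()
  if (!nzchar(query)) return(structure(filters, class = "filter_set"))
  parts <- strsplit(query, "&", fixed = TRUE)[[1]]
  seen <- list(eq = character(0), gt = character(0), lt = character(0))
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed filter '%s'", p))
    key <- URLdecode(kv[1]); val <- URLdecode(kv[2])
    op <- "eq"; col <- key
    if (grepl("\\.(gt|lt)$", key)) {
      op <- sub("^.*\\.", "", key)
      col <- sub("\\.(gt|lt)$", "", key)
    }
    if (!col %in% names(columns))
      stop(sprintf("unknown column '%s' in filter", col))
    ty <- columns[[col]]
    if (ty == "text" && op != "eq")
      stop_unsupported_operator(sprintf(
        "text column '%s' can only be compared for equality", col))
    if (col %in% seen[[op]])
      stop(sprintf("duplicate '%s' filter on column '%s'", op, col))
    seen[[op]] <- c(seen[[op]], col)
    value <- if (ty == "text") val else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop(sprintf("value '%s' is not numeric for column '%s'",
                                   val, col))
      num
    }
    filters[[length(filters) + 1L]] <- list(column = col, op = op, value = value)
  }
  structure(filters, class = "filter_set")
}

#' Query an endpoint
#'
#' Returns the records satisfying the conjunction of all filters, in
#' insertion order.  `gt`/`lt` are strict inequalities.
#'
#' @param store A [metrics_store()].
#' @param name Endpoint name.
#' @param filters A `filter_set` from [parse_filters()], or a query string
#'   (parsed against the endpoint schema), or `NULL` for all records.
#' @return A data.frame of matching records.
#' @export
query_records <- function(store, name, filters = NULL) {
  ep <- .get_endpoint(store, name)
  df <- ep$data
  if (is.character(filters)) filters <- parse_filters(filters, ep$columns)
  if (is.null(filters) || length(filters) == 0L) return(df)
  keep <- rep(TRUE, nrow(df))
  for (f in filters) {
    v <- df[[f$column]]
    keep <- keep & switch(f$op,
                          eq = v == f$value,
                          gt = v > f$value,
                          lt = v < f$value)
  }
  df[keep, , drop = FALSE]
}

#' JSON wire format for record batches
#'
#' Records travel as a JSON array of flat objects, both on ingestion and in
#' query responses.
#'
#' @param records A data.frame of records.
#' @param json A JSON string (array of objects).
#' @return `records_to_json` returns a JSON string; `records_from_json`
#'   returns a list of named lists suitable for [insert_records()].
#' @export
records_to_json <- function(records) {
  as.character(jsonlite::toJSON(records, dataframe = "rows", digits = NA,
                                auto_unbox = TRUE))
}

#' @rdname records_to_json
#' @export
records_from_json <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = FALSE)
}

#' Persist and restore a metrics store as JSON
#'
#' @param store A [metrics_store()].
#' @param path JSON file path.
#' @return `save_store` returns `path` invisibly; `load_store` returns a
#'   rebuilt [metrics_store()].
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "metrics_store"))
  payload <- lapply(store$endpoints, function(ep)
    list(columns = as.list(ep$columns),
         data = jsonlite::fromJSON(records_to_json(ep$data),
                                   simplifyVector = FALSE)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  payload <- jsonlite::read_json(path)
  store <- metrics_store()
  for (name in names(payload)) {
    cols <- unlist(payload[[name]]$columns)
    define_endpoint(store, name, cols)
    recs <- payload[[name]]$data
    if (length(recs)) insert_records(store, name, recs)
  }
  store
}
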