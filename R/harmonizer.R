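# Symbol harmonization: map every symbol seen in any snapshot to one
# current HGNC identity so evidence from six sources lands on one record.

#' Load an HGNC-style symbol table
#'
#' Reads a tab-separated symbol table with columns `hgnc_id`, `symbol`,
#' `status`, `prev_symbols`, `alias_symbols` (the latter two pipe-separated,
#' possibly empty). Withdrawn entries are retained in the table but never
#' match a query.
#'
#' @param path Path to the TSV file.
#' @return An object of class `symbol_table`: a list with `entries` (a
#'   tibble, one row per HGNC record) and pre-built lookup tables for the
#'   three match tiers.
#' @export
load_symbol_table <- function(path) {
  req <- c("hgnc_id", "symbol", "status", "prev_symbols", "alias_symbols")
  df <- mg_read_tsv(path, required_cols = req)
  if (anyDuplicated(df$hgnc_id)) {
    dup <- unique(df$hgnc_id[duplicated(df$hgnc_id)])
    abort(
      paste0("duplicate hgnc_id in symbol table: ", paste(dup, collapse = ", ")),
      class = "mg_integrity_error"
    )
  }
  bad_status <- setdiff(unique(df$status), c("approved", "withdrawn"))
  if (length(bad_status) > 0) {
    abort(
      paste0("unknown status value(s): ", paste(bad_status, collapse = ", ")),
      class = "mg_format_error"
    )
  }
  split_pipe <- function(x) {
    lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
  }
  entries <- tibble::tibble(
    hgnc_id = df$hgnc_id,
    approved_symbol = df$symbol,
    previous_symbols = split_pipe(df$prev_symbols),
    alias_symbols = split_pipe(df$alias_symbols),
    status = df$status
  )
  approved <- entries[entries$status == "approved", ]
  if (anyDuplicated(approved$approved_symbol)) {
    abort("duplicate approved symbol among approved entries",
      class = "mg_integrity_error"
    )
  }
  self_alias <- mapply(
    function(sym, al) sym %in% al,
    approved$approved_symbol, approved$alias_symbols
  )
  if (any(self_alias)) {
    abort("entry lists its own approved symbol among its aliases",
      class = "mg_integrity_error"
    )
  }
  long <- function(col) {
    n <- lengths(approved[[col]])
    tibble::tibble(
      symbol = unlist(approved[[col]], use.names = FALSE),
      hgnc_id = rep(approved$hgnc_id, n)
    )
  }
  structure(
    list(
      entries = entries,
      approved_lut = setNames(approved$hgnc_id, approved$approved_symbol),
      symbol_lut = setNames(approved$approved_symbol, approved$hgnc_id),
      previous_lut = long("previous_symbols"),
      alias_lut = long("alias_symbols")
    ),
    class = "symbol_table"
  )
}

#' @export
print.symbol_table <- function(x, ...) {
  n_app <- sum(x$entries$status == "approved")
  cat(
    "<symbol_table> ", nrow(x$entries), " entries (", n_app, " approved, ",
    nrow(x$entries) - n_app, " withdrawn)\n",
    sep = ""
  )
  invisible(x)
}

#' Resolve a gene symbol against the symbol table
#'
#' Matching is case-sensitive after trimming surrounding whitespace, with
#' tier precedence approved > previous > alias. A query matching the
#' previous or alias symbols of two or more distinct genes at its best tier
#' is returned as unmapped with `ambiguous = TRUE` rather than attributed
#' arbitrarily.
#'
#' @param query A single non-empty symbol string.
#' @param table A `symbol_table` from [load_symbol_table()].
#' @return A one-row tibble with columns `query`, `hgnc_id`,
#'   `current_symbol`, `match_tier` (one of `"approved"`, `"previous"`,
#'   `"alias"`, `"unmapped"`) and `ambiguous`.
#' @export
resolve_symbol <- function(query, table) {
  stopifnot(inherits(table, "symbol_table"))
  if (!is.character(query) || length(query) != 1 || is.na(query) ||
    !nzchar(trimws(query))) {
    abort("query must be a single non-empty string", class = "mg_argument_error")
  }
  q <- trimws(query)
  res <- function(id, tier, ambiguous = FALSE) {
    tibble::tibble(
      query = query,
      hgnc_id = id %||% NA_character_,
      current_symbol = if (is.null(id)) NA_character_ else unname(table$symbol_lut[[id]]),
      match_tier = tier,
      ambiguous = ambiguous
    )
  }
  hit <- table$approved_lut[q]
  if (!is.na(hit)) {
    return(res(unname(hit), "approved"))
  }
  for (tier in c("previous", "alias")) {
    lut <- table[[paste0(tier, "_lut")]]
    ids <- unique(lut$hgnc_id[lut$symbol == q])
    if (length(ids) == 1) {
      return(res(ids, tier))
    }
    if (length(ids) > 1) {
      return(res(NULL, "unmapped", ambiguous = TRUE))
    }
  }
  res(NULL, "unmapped")
}

#' Resolve many symbols at once
#'
#' Vectorised wrapper around [resolve_symbol()]; duplicate queries are
#' resolved once. Unmapped queries are reported via a message when
#' `quiet = FALSE`.
#'
#' @param queries Character vector of symbols.
#' @inheritParams resolve_symbol
#' @param quiet Suppress the unmapped-symbol message.
#' @return Tibble with one row per unique query, same columns as
#'   [resolve_symbol()].
#' @export
resolve_symbols <- function(queries, table, quiet = TRUE) {
  uq <- unique(queries)
  out <- dplyr::bind_rows(lapply(uq, resolve_symbol, table = table))
  if (!quiet && any(out$match_tier == "unmapped")) {
    inform(paste0(
      "unmapped symbols: ",
      paste(out$query[out$match_tier == "unmapped"], collapse = ", ")
    ))
  }
  out
}
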