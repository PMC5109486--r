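#' Canonical bioactivity record fields
#'
#' A bioactivity record is one raw assay measurement before curation. Records
#' are held as a data frame with one row per measurement and the columns
#' below; optional fields are NA when absent.
#'
#' \describe{
#'   \item{compound_id}{opaque compound identifier (non-empty)}
#'   \item{target_id}{opaque target identifier (non-empty)}
#'   \item{target_type}{target class, e.g. "SINGLE PROTEIN", "PROTEIN COMPLEX"}
#'   \item{assay_id}{assay identifier}
#'   \item{activity_comment}{free-text activity annotation, possibly empty}
#'   \item{potency_value}{numeric potency, finite and >= 0, or NA}
#'   \item{potency_units}{units of the potency value (nM expected), or NA}
#'   \item{potency_relation}{one of "=", ">", "<", ">=", "<=", or NA}
#'   \item{assay_type}{assay type code}
#'   \item{organism}{assay organism}
#' }
#'
#' @name bioactivity-record
#' @keywords internal
NULL

.record_fields <- c(
  "compound_id", "target_id", "target_type", "assay_id", "activity_comment",
  "potency_value", "potency_units", "potency_relation", "assay_type", "organism"
)

.potency_relations <- c("=", ">", "<", ">=", "<=")

#' Read a tab-separated bioactivity table
#'
#' Parses a ChEMBL-style bioactivity export (tab-separated, UTF-8, header
#' row) into a record data frame. No filtering is performed: every data row
#' becomes a record; empty cells become NA optional fields. A potency cell
#' that does not parse as a number (e.g. "ND") is treated as absent and a
#' warning is emitted naming the offending row.
#'
#' @param source path to a tab-separated file, or a connection.
#' @param column_map named character vector mapping logical field names
#'   (see \link{bioactivity-record}) to physical column names in the file.
#'   Fields absent from the map fall back to their logical name; mapped
#'   columns missing from the file are an error.
#' @return a data frame of bioactivity records, one row per data row.
#' @export
read_bioactivity_table <- function(source, column_map = NULL) {
  raw <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  map <- stats::setNames(.record_fields, .record_fields)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == ""))
      stop("column_map must be a named character vector (logical -> physical)")
    unknown <- setdiff(names(column_map), .record_fields)
    if (length(unknown))
      stop("column_map names unknown logical fields: ",
           paste(unknown, collapse = ", "))
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) not found in input: ",
         paste(missing_cols, collapse = ", "))

  rec <- stats::setNames(raw[unname(map)], names(map))
  for (f in .record_fields) {
    v <- trimws(rec[[f]])
    v[v == ""] <- NA_character_
    rec[[f]] <- v
  }
  pv <- suppressWarnings(as.numeric(rec$potency_value))
  bad <- !is.na(rec$potency_value) & is.na(pv)
  if (any(bad)) {
    warning(sprintf("%d unparsable potency value(s) treated as absent (rows %s)",
                    sum(bad), paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  rec$potency_value <- pv
  rel <- rec$potency_relation
  if (any(!is.na(rel) & !rel %in% .potency_relations))
    stop("invalid potency_relation value(s): ",
         paste(unique(rel[!is.na(rel) & !rel %in% .potency_relations]),
               collapse = ", "))
  validate_records(rec)
  rec
}

#' @keywords internal
validate_records <- function(records) {
  stopifnot(is.data.frame(records), all(.record_fields %in% names(records)))
  if (any(is.na(records$compound_id) | records$compound_id == ""))
    stop("compound_id must be non-empty for every record")
  if (any(is.na(records$target_id) | records$target_id == ""))
    stop("target_id must be non-empty for every record")
  pv <- records$potency_value
  if (any(!is.na(pv) & (!is.finite(pv) | pv < 0)))
    stop("potency_value must be finite and >= 0 when present")
  invisible(records)
}

#' Collapse assays measuring the same compound-target pair
#'
#' Different bioassays that probe the same protein are clustered into one
#' case per compound-target pair and activity class: all active evidence for
#' a pair collapses to a single record, and explicit-inactive evidence (an
#' activity comment in the config's inactive vocabulary) collapses to a
#' separate record, so downstream arbitration sees both. Auxiliary metadata
#' (assay ids, assay types, organisms) is concatenated into
#' semicolon-separated provenance fields. Among active records of a pair the
#' retained potency is the most favourable one: the smallest nM value, then
#' the smallest value in any unit, then no value.
#'
#' @param records a bioactivity record data frame.
#' @param config a \code{\link{curation_config}}; only its inactive-comment
#'   vocabulary is consulted, to separate activity classes.
#' @return a collapsed record data frame (one row per pair and class).
#' @export
cluster_assays_by_protein <- function(records, config = curation_config()) {
  validate_records(records)
  if (nrow(records) == 0L) return(records)
  comment_lc <- tolower(ifelse(is.na(records$activity_comment), "",
                               records$activity_comment))
  inactive <- .matches_any(comment_lc, config$inactive_comments)
  cls <- ifelse(inactive, "inactive", "active")
  key <- paste(records$compound_id, records$target_id, cls, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)

  cat_uniq <- function(x) paste(sort(unique(x[!is.na(x)])), collapse = ";")
  rows <- lapply(groups, function(ix) {
    g <- records[ix, , drop = FALSE]
    keep <- .best_potency_row(g)
    out <- g[keep, , drop = FALSE]
    out$assay_id <- cat_uniq(g$assay_id)
    out$assay_type <- cat_uniq(g$assay_type)
    out$organism <- cat_uniq(g$organism)
    # a pair with several distinct comments keeps the first flagged one so
    # curation still sees the exclusion vocabulary
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# index of the record with the most favourable potency evidence in a group:
# smallest nM value first, then smallest value in any unit, then no value
.best_potency_row <- function(g) {
  has_val <- !is.na(g$potency_value)
  is_nm <- has_val & !is.na(g$potency_units) &
    tolower(g$potency_units) == "nm"
  if (any(is_nm)) {
    ix <- which(is_nm)
    return(ix[which.min(g$potency_value[ix])])
  }
  if (any(has_val)) {
    ix <- which(has_val)
    return(ix[which.min(g$potency_value[ix])])
  }
  1L
}

.matches_any <- function(text_lc, substrings) {
  if (length(substrings) == 0L) return(rep(FALSE, length(text_lc)))
  hit <- rep(FALSE, length(text_lc))
  for (s in substrings) hit <- hit | grepl(s, text_lc, fixed = TRUE)
  hit
}
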