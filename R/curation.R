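#' Curation configuration
#'
#' Parameters governing how raw bioactivity records are reduced to the
#' reference standard of positive compound-target interactions.
#'
#' @param potency_ceiling_nM positive real; records whose potency is
#'   established as greater than this value (relation ">" or ">=" at or
#'   above the ceiling) are excluded. Default 50000 nM.
#' @param min_targets_per_compound positive integer; compounds with fewer
#'   distinct positive targets after curation are dropped. Default 15.
#' @param allowed_target_types target classes kept; everything else (protein
#'   complexes, unspecified targets, ...) is rejected. Default
#'   \code{"SINGLE PROTEIN"}.
#' @param excluded_comments lower-cased substrings of activity comments that
#'   disqualify a record from the positives ("not determined", "not
#'   soluble", "potential missing data", and the inactive vocabulary).
#' @param inactive_comments lower-cased substrings marking explicit
#'   inactivity; pairs whose only evidence matches enter the known-inactive
#'   set rather than being discarded.
#' @param reject_measured_above_ceiling logical; if TRUE (default) a
#'   measured potency value above the ceiling is also rejected, regardless
#'   of its relation symbol. Set FALSE to reject only ">"/" >=" records.
#' @return an object of class \code{curation_config}.
#' @export
curation_config <- function(potency_ceiling_nM = 50000,
                            min_targets_per_compound = 15L,
                            allowed_target_types = "SINGLE PROTEIN",
                            excluded_comments = c("not active", "not determined",
                                                  "not soluble",
                                                  "potential missing data"),
                            inactive_comments = "not active",
                            reject_measured_above_ceiling = TRUE) {
  stopifnot(is.numeric(potency_ceiling_nM), length(potency_ceiling_nM) == 1L,
            potency_ceiling_nM > 0,
            is.numeric(min_targets_per_compound),
            length(min_targets_per_compound) == 1L,
            min_targets_per_compound >= 1)
  structure(list(
    potency_ceiling_nM = as.numeric(potency_ceiling_nM),
    min_targets_per_compound = as.integer(min_targets_per_compound),
    allowed_target_types = as.character(allowed_target_types),
    excluded_comments = tolower(as.character(excluded_comments)),
    inactive_comments = tolower(as.character(inactive_comments)),
    reject_measured_above_ceiling = isTRUE(reject_measured_above_ceiling)
  ), class = "curation_config")
}

#' Rejection reason codes
#'
#' Machine-readable reasons attached to curated-out records: each rejected
#' record carries exactly one.
#' \describe{
#'   \item{TARGET_TYPE}{target class not in the allowed set}
#'   \item{COMMENT_EXCLUDED}{activity comment in the exclusion vocabulary
#'     (other than explicit inactivity)}
#'   \item{UNIT_UNSUPPORTED}{potency present in units other than nM; no
#'     silent unit conversion is attempted}
#'   \item{POTENCY_CEILING}{potency established as greater than the ceiling,
#'     or measured above it}
#' }
#' @name rejection-reasons
#' @keywords internal
NULL

#' Apply curation rules to collapsed records
#'
#' Classifies every collapsed record as a positive pair, an explicit
#' known-inactive pair, or a rejection with exactly one reason code. A pair
#' enters the positives iff its target type is allowed, its comment matches
#' no excluded substring, and its potency (when present, in nM) does not
#' violate the ceiling. Pairs whose only evidence is an explicit "not
#' active" comment enter the known-inactive set. A pair with both active
#' and inactive evidence is arbitrated in favour of the positive: the pair
#' is removed from the known inactives and the conflict is recorded.
#'
#' @param records collapsed records from
#'   \code{\link{cluster_assays_by_protein}}.
#' @param config a \code{\link{curation_config}}.
#' @return a list with elements \code{positives} and \code{known_inactives}
#'   (data frames with columns compound_id, target_id, sorted), a
#'   \code{rejection_log} data frame (record fields plus \code{reason}), and
#'   \code{conflicts}, the pairs with both active and inactive evidence.
#' @export
curate_records <- function(records, config = curation_config()) {
  validate_records(records)
  n <- nrow(records)
  comment_lc <- tolower(ifelse(is.na(records$activity_comment), "",
                               records$activity_comment))
  is_inactive <- .matches_any(comment_lc, config$inactive_comments)
  is_excluded <- .matches_any(comment_lc, config$excluded_comments) & !is_inactive

  reason <- rep(NA_character_, n)
  bad_type <- !(records$target_type %in% config$allowed_target_types) |
    is.na(records$target_type)
  reason[bad_type] <- "TARGET_TYPE"

  todo <- is.na(reason) & !is_inactive
  reason[todo & is_excluded] <- "COMMENT_EXCLUDED"

  todo <- is.na(reason) & !is_inactive
  has_val <- !is.na(records$potency_value)
  non_nm <- has_val & (is.na(records$potency_units) |
                         tolower(records$potency_units) != "nm")
  reason[todo & non_nm] <- "UNIT_UNSUPPORTED"

  todo <- is.na(reason) & !is_inactive
  rel <- records$potency_relation
  gt_ceiling <- has_val & !is.na(rel) & rel %in% c(">", ">=") &
    records$potency_value >= config$potency_ceiling_nM
  measured_above <- has_val & records$potency_value > config$potency_ceiling_nM
  ceiling_hit <- gt_ceiling |
    (config$reject_measured_above_ceiling & measured_above)
  reason[todo & ceiling_hit] <- "POTENCY_CEILING"

  ok_positive <- is.na(reason) & !is_inactive
  ok_inactive <- is.na(reason) & is_inactive

  pair_df <- function(keep) {
    d <- unique(data.frame(compound_id = records$compound_id[keep],
                           target_id = records$target_id[keep],
                           stringsAsFactors = FALSE))
    d[order(d$compound_id, d$target_id), , drop = FALSE]
  }
  positives <- pair_df(ok_positive)
  inactives <- pair_df(ok_inactive)

  # arbitration: positive evidence wins over explicit inactivity
  conflict <- .pair_key(inactives) %in% .pair_key(positives)
  conflicts <- inactives[conflict, , drop = FALSE]
  inactives <- inactives[!conflict, , drop = FALSE]

  rejection_log <- records[!is.na(reason), , drop = FALSE]
  rejection_log$reason <- reason[!is.na(reason)]
  rownames(positives) <- rownames(inactives) <- rownames(conflicts) <-
    rownames(rejection_log) <- NULL
  list(positives = positives, known_inactives = inactives,
       rejection_log = rejection_log, conflicts = conflicts)
}

.pair_key <- function(pairs) paste(pairs$compound_id, pairs$target_id, sep = "\r")

#' Build the curated interaction matrix (reference standard)
#'
#' Applies the minimum-target filter and fixes the compound and target
#' universes. Compounds with fewer than \code{min_targets_per_compound}
#' distinct positive targets are dropped and their pairs removed from both
#' sets; the target universe is the union of targets in the surviving
#' positives; both universes are sorted lexicographically so re-runs are
#' byte-identical.
#'
#' @param positives,known_inactives disjoint pair data frames (columns
#'   compound_id, target_id), e.g. from \code{\link{curate_records}}.
#' @param config a \code{\link{curation_config}}.
#' @return an object of class \code{interaction_matrix}: a list with
#'   \code{compounds}, \code{targets}, \code{positives},
#'   \code{known_inactives} and \code{min_targets}.
#' @export
build_interaction_matrix <- function(positives, known_inactives = NULL,
                                     config = curation_config()) {
  if (is.null(known_inactives))
    known_inactives <- data.frame(compound_id = character(),
                                  target_id = character(),
                                  stringsAsFactors = FALSE)
  stopifnot(is.data.frame(positives),
            all(c("compound_id", "target_id") %in% names(positives)))
  positives <- unique(positives[c("compound_id", "target_id")])
  known_inactives <- unique(known_inactives[c("compound_id", "target_id")])
  if (any(.pair_key(known_inactives) %in% .pair_key(positives)))
    stop("positives and known_inactives overlap; arbitrate before building")

  tally <- table(positives$compound_id)
  keep_compounds <- names(tally)[tally >= config$min_targets_per_compound]
  if (length(keep_compounds) == 0L)
    stop("empty reference standard: no compound has at least ",
         config$min_targets_per_compound, " targets")

  positives <- positives[positives$compound_id %in% keep_compounds, ,
                         drop = FALSE]
  compounds <- sort(unique(positives$compound_id))
  targets <- sort(unique(positives$target_id))
  known_inactives <- known_inactives[
    known_inactives$compound_id %in% compounds &
      known_inactives$target_id %in% targets, , drop = FALSE]

  positives <- positives[order(positives$compound_id, positives$target_id), ,
                         drop = FALSE]
  known_inactives <- known_inactives[
    order(known_inactives$compound_id, known_inactives$target_id), ,
    drop = FALSE]
  rownames(positives) <- rownames(known_inactives) <- NULL
  structure(list(compounds = compounds, targets = targets,
                 positives = positives, known_inactives = known_inactives,
                 min_targets = config$min_targets_per_compound),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix (reference standard)\n")
  cat(sprintf("  compounds: %d  targets: %d\n",
              length(x$compounds), length(x$targets)))
  cat(sprintf("  positive pairs: %d  known-inactive pairs: %d\n",
              nrow(x$positives), nrow(x$known_inactives)))
  cat(sprintf("  possible combinations: %.0f  min targets/compound: %d\n",
              as.numeric(length(x$compounds)) * length(x$targets),
              x$min_targets))
  invisible(x)
}

#' Run the full curation pipeline on raw records
#'
#' Convenience wrapper: cluster assays, curate, build the matrix.
#'
#' @inheritParams cluster_assays_by_protein
#' @return a list with the \code{matrix} (class \code{interaction_matrix}),
#'   the \code{rejection_log} and the arbitration \code{conflicts}.
#' @export
curate_bioactivity <- function(records, config = curation_config()) {
  collapsed <- cluster_assays_by_protein(records, config)
  cur <- curate_records(collapsed, config)
  m <- build_interaction_matrix(cur$positives, cur$known_inactives, config)
  list(matrix = m, rejection_log = cur$rejection_log,
       conflicts = cur$conflicts)
}

#' Write and read the reference standard
#'
#' The reference standard is serialized as a sorted, LF-terminated
#' tab-separated file with columns compound_id, target_id and status
#' (\code{positive} or \code{inactive}).
#'
#' @param matrix an \code{interaction_matrix}.
#' @param path output (input) file path.
#' @param min_targets for \code{read_reference_standard}, the min-target
#'   filter the matrix was built with (re-validated on read).
#' @return \code{write_reference_standard} returns \code{path} invisibly;
#'   \code{read_reference_standard} returns an \code{interaction_matrix}.
#' @export
write_reference_standard <- function(matrix, path) {
  pos <- cbind(matrix$positives, status = "positive")
  ina <- cbind(matrix$known_inactives, status = "inactive")
  out <- rbind(pos, ina)
  out <- out[order(out$compound_id, out$target_id, out$status), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_reference_standard
#' @export
read_reference_standard <- function(path, min_targets = 15L) {
  d <- utils::read.delim(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("compound_id", "target_id", "status") %in% names(d)))
  build_interaction_matrix(
    d[d$status == "positive", c("compound_id", "target_id")],
    d[d$status == "inactive", c("compound_id", "target_id")],
    curation_config(min_targets_per_compound = min_targets))
}
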