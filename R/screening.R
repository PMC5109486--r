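#' Score compound-target candidates by maximum profile similarity
#'
#' Every compound-target combination is scored against the known binders of
#' the target: the score of (c, t) is the maximum Tanimoto coefficient
#' between c's fingerprint and that of any compound b != c with (b, t) in
#' the positives, and the reference compound is the argmax (ties broken by
#' the lexicographically smallest compound id). Known positive pairs are
#' scored by the same rule — the maximisation already excludes the compound
#' itself, so a known pair gains nothing from self-similarity. Combinations
#' whose target has no other binder receive no score, and candidates below
#' \code{min_tc} are not materialised; the evaluator accounts for both as
#' predicted-negative.
#'
#' @param tipfs a \code{tipf_set} built from \code{matrix}.
#' @param matrix the \code{interaction_matrix} the fingerprints derive from.
#' @param min_tc materialisation floor in [0, 1]; default 0.5.
#' @return a data frame of class \code{candidate_scores} with columns
#'   \code{compound_id}, \code{target_id}, \code{tc_max},
#'   \code{reference_compound_id}, sorted by (target_id, -tc_max,
#'   compound_id). Attributes record the universes and the floor.
#' @export
score_candidates <- function(tipfs, matrix, min_tc = 0.5) {
  stopifnot(inherits(tipfs, "tipf_set"), inherits(matrix, "interaction_matrix"))
  if (!identical(sort(names(tipfs$on_bits)), matrix$compounds))
    stop("fingerprints were not built from this matrix")
  if (min_tc < 0 || min_tc > 1) stop("min_tc must be in [0, 1]")

  compounds <- matrix$compounds
  TC <- .tanimoto_matrix(tipfs)[compounds, compounds, drop = FALSE]
  binders <- split(matrix$positives$compound_id, matrix$positives$target_id)

  res <- vector("list", length(binders))
  for (k in seq_along(binders)) {
    t_id <- names(binders)[k]
    b <- sort(binders[[k]])
    sub <- TC[, b, drop = FALSE]
    self <- match(b, compounds)
    sub[cbind(self, seq_along(b))] <- -Inf   # b != c: mask self-columns
    tc_max <- do.call(pmax, c(as.data.frame(sub), list(na.rm = FALSE)))
    ref <- b[max.col(sub, ties.method = "first")]
    keep <- is.finite(tc_max) & tc_max >= min_tc
    if (!any(keep)) next
    res[[k]] <- data.frame(compound_id = compounds[keep], target_id = t_id,
                           tc_max = tc_max[keep],
                           reference_compound_id = ref[keep],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(compound_id = character(), target_id = character(),
                      tc_max = numeric(),
                      reference_compound_id = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$target_id, -out$tc_max, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_scores", "data.frame"),
            compounds = compounds, targets = matrix$targets, min_tc = min_tc)
}

#' Classify scored candidates against the reference standard
#'
#' Annotates each candidate as \code{known_positive} (the pair is in the
#' positives), \code{known_inactive} (explicit inactive evidence) or
#' \code{novel}, and tallies the partition. The partition satisfies
#' n_total = n_known_positive + n_known_inactive + n_novel by construction.
#'
#' @param candidates a \code{candidate_scores} data frame.
#' @param matrix the \code{interaction_matrix} the candidates were scored
#'   against.
#' @return the candidates with a \code{status} column added; the partition
#'   counts are attached as attribute \code{partition} (class
#'   \code{candidate_partition}).
#' @export
classify_candidates <- function(candidates, matrix) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  if (!all(candidates$compound_id %in% matrix$compounds) ||
      !all(candidates$target_id %in% matrix$targets))
    stop("candidate references a compound or target outside the matrix universes")
  key <- paste(candidates$compound_id, candidates$target_id, sep = "\r")
  status <- rep("novel", nrow(candidates))
  status[key %in% .pair_key(matrix$positives)] <- "known_positive"
  status[key %in% .pair_key(matrix$known_inactives)] <- "known_inactive"
  candidates$status <- status
  partition <- structure(list(
    n_total = nrow(candidates),
    n_known_positive = sum(status == "known_positive"),
    n_known_inactive = sum(status == "known_inactive"),
    n_novel = sum(status == "novel")), class = "candidate_partition")
  attr(candidates, "partition") <- partition
  candidates
}

#' @export
print.candidate_partition <- function(x, ...) {
  cat(sprintf(paste0("Candidate partition: %d total = %d known positive + ",
                     "%d known inactive + %d novel\n"),
              x$n_total, x$n_known_positive, x$n_known_inactive, x$n_novel))
  invisible(x)
}

#' Select and rank candidates for a target
#'
#' Restricts classified candidates to one target, an optional compound
#' whitelist (e.g. approved or experimental drugs and natural products,
#' supplied as a plain id vector) and a status filter, then ranks by
#' descending score with lexicographic compound-id tie-break.
#'
#' @param candidates classified candidates (from
#'   \code{\link{classify_candidates}}).
#' @param target_id the target to screen; must exist in the scoring
#'   universe.
#' @param whitelist optional character vector of admissible compound ids.
#' @param status statuses to keep; default \code{"novel"}.
#' @param top_k optional truncation of the ranked list.
#' @return the ranked candidate data frame.
#' @export
select_candidates <- function(candidates, target_id, whitelist = NULL,
                              status = "novel", top_k = NULL) {
  targets <- attr(candidates, "targets")
  if (!is.null(targets) && !target_id %in% targets)
    stop("unknown target_id: ", target_id)
  sel <- candidates[candidates$target_id == target_id, , drop = FALSE]
  if (!is.null(status) && "status" %in% names(sel))
    sel <- sel[sel$status %in% status, , drop = FALSE]
  if (!is.null(whitelist))
    sel <- sel[sel$compound_id %in% whitelist, , drop = FALSE]
  sel <- sel[order(-sel$tc_max, sel$compound_id), , drop = FALSE]
  if (!is.null(top_k)) sel <- utils::head(sel, top_k)
  rownames(sel) <- NULL
  sel
}

#' Write candidates and partition
#'
#' \code{write_candidates} writes the sorted candidate table as TSV;
#' \code{write_partition} writes the four partition counts as JSON.
#'
#' @param candidates classified candidates.
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("compound_id", "target_id", "tc_max", "reference_compound_id")
  if ("status" %in% names(candidates)) cols <- c(cols, "status")
  out <- as.data.frame(candidates)[cols]
  out$tc_max <- sprintf("%.6f", out$tc_max)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_candidates
#' @export
write_partition <- function(candidates, path) {
  p <- attr(candidates, "partition")
  if (is.null(p)) stop("candidates carry no partition; classify them first")
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
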