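#' Build target interaction profile fingerprints
#'
#' Each compound in the reference standard is encoded as a binary vector
#' over the target universe, with bit i on iff the compound is a known
#' binder of target i. The vector is stored sparsely as the strictly
#' increasing set of on positions.
#'
#' @param matrix an \code{interaction_matrix}.
#' @return an object of class \code{tipf_set}: a list with \code{targets}
#'   (the universe, in matrix order) and \code{on_bits}, a named list of
#'   sorted integer index vectors, one per compound.
#' @export
build_tipfs <- function(matrix) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  idx <- match(matrix$positives$target_id, matrix$targets)
  stopifnot(!anyNA(idx))
  bits <- split(idx, factor(matrix$positives$compound_id,
                            levels = matrix$compounds))
  bits <- lapply(bits, function(v) sort(unique(as.integer(v))))
  if (any(lengths(bits) == 0L))
    stop("every compound in the matrix must have at least one positive target")
  structure(list(targets = matrix$targets, on_bits = bits),
            class = "tipf_set")
}

#' @export
print.tipf_set <- function(x, ...) {
  cat(sprintf("TIPF set: %d compounds over %d targets (%d on bits total)\n",
              length(x$on_bits), length(x$targets), sum(lengths(x$on_bits))))
  invisible(x)
}

#' Tanimoto coefficient of two fingerprints
#'
#' The similarity of two target interaction profiles: the number of targets
#' in the intersection divided by the number in the union of the two on-bit
#' sets. Symmetric, in [0, 1], exactly 1 for identical profiles and 0 for
#' disjoint ones.
#'
#' @param a,b sorted integer vectors of on-bit positions (as stored in a
#'   \code{tipf_set}), both indexed against the same target universe.
#' @return the Tanimoto coefficient as a double.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L)
    stop("Tanimoto coefficient undefined for two empty fingerprints")
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' All-pairs Tanimoto similarity
#'
#' Computes the Tanimoto coefficient between every unordered pair of
#' fingerprints and returns the pairs at or above \code{min_tc}. The search
#' is pruned through a sparse inverted-index product over targets (only
#' pairs sharing at least one target have nonzero intersection), but the
#' result is identical to the naive double loop: intersection and union
#' sizes are exact integers and appear in the output alongside the ratio.
#' When \code{min_tc} is 0, zero-similarity pairs are enumerated explicitly
#' so the complete graph is returned.
#'
#' @param tipfs a \code{tipf_set}.
#' @param min_tc similarity floor in [0, 1]; default 0.5, the retention
#'   threshold used for candidate generation.
#' @return a data frame of edges with columns \code{compound_a},
#'   \code{compound_b} (lexicographically ordered within each row),
#'   \code{n_intersect}, \code{n_union} and \code{tc}, sorted by
#'   (compound_a, compound_b).
#' @export
all_pairs_similarity <- function(tipfs, min_tc = 0.5) {
  stopifnot(inherits(tipfs, "tipf_set"))
  if (!is.numeric(min_tc) || length(min_tc) != 1L || is.na(min_tc) ||
      min_tc < 0 || min_tc > 1)
    stop("min_tc must be a single number in [0, 1]")
  ids <- names(tipfs$on_bits)
  n <- length(ids)
  if (n < 2L) stop("need at least two fingerprints")
  ord <- order(ids)
  ids <- ids[ord]
  bits <- tipfs$on_bits[ord]

  M <- .tipf_sparse_matrix(bits, length(tipfs$targets))
  I <- Matrix::tcrossprod(M)
  card <- lengths(bits)

  TI <- methods::as(methods::as(Matrix::triu(I, k = 1L), "generalMatrix"),
                    "TsparseMatrix")
  ia <- TI@i + 1L
  ib <- TI@j + 1L
  ninter <- as.integer(TI@x)
  if (min_tc == 0) {
    all_a <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    all_b <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n),
                    use.names = FALSE)
    key_nz <- ia * (n + 1) + ib
    key_all <- all_a * (n + 1) + all_b
    zero <- !(key_all %in% key_nz)
    ia <- c(ia, all_a[zero]); ib <- c(ib, all_b[zero])
    ninter <- c(ninter, integer(sum(zero)))
  }
  nunion <- card[ia] + card[ib] - ninter
  tc <- ninter / nunion
  keep <- tc >= min_tc
  edges <- data.frame(compound_a = ids[ia[keep]], compound_b = ids[ib[keep]],
                      n_intersect = ninter[keep], n_union = nunion[keep],
                      tc = tc[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$compound_a, edges$compound_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# compounds x targets sparse 0/1 pattern matrix
.tipf_sparse_matrix <- function(bits, n_targets) {
  Matrix::sparseMatrix(
    i = rep(seq_along(bits), lengths(bits)),
    j = unlist(bits, use.names = FALSE),
    x = 1,
    dims = c(length(bits), n_targets))
}

# dense compound x compound Tanimoto matrix (diagonal = 1); row/col names
# are the compound ids in tipf_set order
.tanimoto_matrix <- function(tipfs) {
  bits <- tipfs$on_bits
  M <- .tipf_sparse_matrix(bits, length(tipfs$targets))
  I <- as.matrix(Matrix::tcrossprod(M))
  card <- lengths(bits)
  U <- outer(card, card, "+") - I
  TC <- I / U
  dimnames(TC) <- list(names(bits), names(bits))
  TC
}
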