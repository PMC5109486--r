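# Independent brute-force oracles. These deliberately avoid the package's
# sparse-matrix code paths: fingerprints are materialised as dense 0/1
# vectors and every pair / triple is visited explicitly.

# Tanimoto via dense 0/1 vectors
oracle_tanimoto <- function(bits_a, bits_b, n_targets) {
  va <- integer(n_targets); va[bits_a] <- 1L
  vb <- integer(n_targets); vb[bits_b] <- 1L
  sum(va & vb) / sum(va | vb)
}

# naive double loop over all unordered fingerprint pairs
oracle_all_pairs <- function(tipfs, min_tc) {
  ids <- sort(names(tipfs$on_bits))
  nt <- length(tipfs$targets)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      tc <- oracle_tanimoto(tipfs$on_bits[[ids[i]]], tipfs$on_bits[[ids[j]]],
                            nt)
      if (tc >= min_tc)
        rows[[length(rows) + 1L]] <- data.frame(
          compound_a = ids[i], compound_b = ids[j], tc = tc,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_a = character(), compound_b = character(),
               tc = numeric(), stringsAsFactors = FALSE)
  out[order(out$compound_a, out$compound_b), , drop = FALSE]
}

# exhaustive triple loop over (compound, binder, target): the max score and
# lexicographically-smallest argmax reference per combination
oracle_score_candidates <- function(tipfs, matrix, min_tc) {
  nt <- length(matrix$targets)
  rows <- list()
  for (t_id in sort(unique(matrix$positives$target_id))) {
    binders <- sort(matrix$positives$compound_id[
      matrix$positives$target_id == t_id])
    for (c_id in matrix$compounds) {
      best <- -Inf; ref <- NA_character_
      for (b in binders) {
        if (b == c_id) next
        tc <- oracle_tanimoto(tipfs$on_bits[[c_id]], tipfs$on_bits[[b]], nt)
        if (tc > best) { best <- tc; ref <- b }
      }
      if (is.finite(best) && best >= min_tc)
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = c_id, target_id = t_id, tc_max = best,
          reference_compound_id = ref, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(), target_id = character(),
               tc_max = numeric(), reference_compound_id = character(),
               stringsAsFactors = FALSE)
  out[order(out$target_id, -out$tc_max, out$compound_id), , drop = FALSE]
}

# label every combination of the universe one by one
oracle_confusion <- function(candidates, matrix, threshold,
                             include_known_inactives = FALSE) {
  scored <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(candidates)))
    assign(paste(candidates$compound_id[i], candidates$target_id[i]),
           candidates$tc_max[i], scored)
  pos <- paste(matrix$positives$compound_id, matrix$positives$target_id)
  ina <- paste(matrix$known_inactives$compound_id,
               matrix$known_inactives$target_id)
  tp <- fp <- fn <- tn <- 0L
  for (c_id in matrix$compounds) {
    for (t_id in matrix$targets) {
      key <- paste(c_id, t_id)
      if (!include_known_inactives && key %in% ina) next
      sc <- if (exists(key, scored)) get(key, scored) else -Inf
      predicted <- sc >= threshold
      actual <- key %in% pos
      if (predicted && actual) tp <- tp + 1L
      else if (predicted && !actual) fp <- fp + 1L
      else if (!predicted && actual) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from exact binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# a small clustered world used across tests
make_world <- function(seed = 1L, ...) {
  s <- synth_generate(synthetic_spec(seed = seed, ...))
  res <- curate_bioactivity(s$records)
  tipfs <- build_tipfs(res$matrix)
  list(synth = s, matrix = res$matrix, tipfs = tipfs,
       rejections = res$rejection_log)
}

# random tipf_set over arbitrary profiles (not family-structured)
random_tipfs <- function(n_compounds, n_targets, mean_bits = 8L) {
  bits <- lapply(seq_len(n_compounds), function(i) {
    k <- max(1L, min(n_targets, stats::rpois(1, mean_bits)))
    sort(sample.int(n_targets, k))
  })
  names(bits) <- sprintf("C%04d", seq_len(n_compounds))
  structure(list(targets = sprintf("T%04d", seq_len(n_targets)),
                 on_bits = bits), class = "tipf_set")
}

# interaction_matrix straight from a tipf_set (bypasses curation filters)
matrix_from_tipfs <- function(tipfs, min_targets = 1L) {
  pos <- do.call(rbind, lapply(names(tipfs$on_bits), function(id)
    data.frame(compound_id = id,
               target_id = tipfs$targets[tipfs$on_bits[[id]]],
               stringsAsFactors = FALSE)))
  build_interaction_matrix(pos, config = curation_config(
    min_targets_per_compound = min_targets))
}
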