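#' Specification for synthetic bioactivity data
#'
#' Describes a toy compound-target world with the statistical structure the
#' profile-similarity method assumes: pharmacological families of compounds
#' that share most of a family-specific target set, sparse cross-family
#' interactions, optional masked (held-back) pairs with a closed-form
#' expected recovery score, and raw-record decorations that exercise every
#' curation rule.
#'
#' @param n_families number of compound families; each family has a
#'   disjoint base target set.
#' @param compounds_per_family compounds per family.
#' @param targets_per_family size of each family's base target set; keep at
#'   or above the curation minimum (15) when testing post-filter stages.
#' @param within_family_share fraction of the family target set each
#'   compound carries, in (0, 1]; the subset is drawn per compound (size
#'   \code{round(share * targets_per_family)}, at least 1).
#' @param cross_family_noise per compound-target probability of a random
#'   out-of-family interaction, in [0, 1).
#' @param n_masked_pairs number of within-family positives removed from the
#'   emitted records but listed in the truth with their expected recovery
#'   score ((m-1)/m when share = 1 and noise = 0, m = family set size).
#' @param decorations character subset of
#'   \code{c("not_active", "high_potency", "complex_target",
#'   "duplicate_assay", "excluded_comment")}: which classes of bad or
#'   redundant raw records to inject around the clean pairs.
#' @param seed integer seed; all randomness is driven by it.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_families = 4L, compounds_per_family = 10L,
                           targets_per_family = 20L,
                           within_family_share = 0.9,
                           cross_family_noise = 0.02,
                           n_masked_pairs = 0L,
                           decorations = c("not_active", "high_potency",
                                           "complex_target",
                                           "duplicate_assay",
                                           "excluded_comment"),
                           seed = 1L) {
  stopifnot(n_families >= 1, compounds_per_family >= 1,
            targets_per_family >= 1,
            within_family_share > 0, within_family_share <= 1,
            cross_family_noise >= 0, cross_family_noise < 1,
            n_masked_pairs >= 0)
  if (length(decorations)) decorations <- match.arg(decorations,
                                                    several.ok = TRUE)
  structure(list(n_families = as.integer(n_families),
                 compounds_per_family = as.integer(compounds_per_family),
                 targets_per_family = as.integer(targets_per_family),
                 within_family_share = within_family_share,
                 cross_family_noise = cross_family_noise,
                 n_masked_pairs = as.integer(n_masked_pairs),
                 decorations = decorations,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic raw bioactivity records with known truth
#'
#' Builds the compound-target world described by the spec and wraps every
#' clean positive pair in a raw assay record (nM potency below the curation
#' ceiling, SINGLE PROTEIN target, binding assay). Requested decorations
#' add records that each trip exactly one curation rule — an explicit "not
#' active" pair per family, a ">" 60000 nM record, a PROTEIN COMPLEX
#' record, a duplicate assay for an existing pair, and a "not determined"
#' comment — so the rejection reasons can be checked one-to-one. Masked
#' pairs are removed from the emitted records and listed in the truth with
#' their expected recovery score. Output is fully deterministic given the
#' seed. Compound and target ids are zero-padded (C0001, T0001) so
#' lexicographic and numeric order coincide.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list with \code{records} (raw bioactivity data frame in the
#'   dialect \code{\link{read_bioactivity_table}} reads), and \code{truth}:
#'   \code{positives} (all clean pairs incl. masked), \code{masked} (pairs
#'   with \code{expected_tc}), \code{families} (per-compound labels), and
#'   \code{decorations} (injected record keys with their intended curation
#'   outcome).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  nf <- spec$n_families; cpf <- spec$compounds_per_family
  tpf <- spec$targets_per_family
  n_targets <- nf * tpf
  compound_ids <- sprintf("C%04d", seq_len(nf * cpf))
  target_ids <- sprintf("T%04d", seq_len(n_targets))
  family_of <- rep(seq_len(nf), each = cpf)
  fam_targets <- split(target_ids, rep(seq_len(nf), each = tpf))

  k_within <- max(1L, round(spec$within_family_share * tpf))
  pos <- vector("list", length(compound_ids))
  for (i in seq_along(compound_ids)) {
    fam <- family_of[i]
    own <- if (k_within >= tpf) fam_targets[[fam]] else
      sort(sample(fam_targets[[fam]], k_within))
    noise <- character()
    if (spec$cross_family_noise > 0) {
      other <- setdiff(target_ids, fam_targets[[fam]])
      hit <- stats::runif(length(other)) < spec$cross_family_noise
      noise <- other[hit]
    }
    pos[[i]] <- data.frame(compound_id = compound_ids[i],
                           target_id = c(own, noise),
                           stringsAsFactors = FALSE)
  }
  positives <- do.call(rbind, pos)
  positives <- positives[order(positives$compound_id, positives$target_id), ,
                         drop = FALSE]
  rownames(positives) <- NULL

  if (spec$n_masked_pairs > nrow(positives))
    stop("cannot mask more pairs than exist (", nrow(positives), ")")
  masked_idx <- if (spec$n_masked_pairs > 0)
    sort(sample.int(nrow(positives), spec$n_masked_pairs)) else integer()
  masked <- positives[masked_idx, , drop = FALSE]
  emitted <- positives[setdiff(seq_len(nrow(positives)), masked_idx), ,
                       drop = FALSE]
  noiseless_identical <- spec$within_family_share == 1 &&
    spec$cross_family_noise == 0
  masked$expected_tc <- if (nrow(masked))
    (if (noiseless_identical) (tpf - 1) / tpf else NA_real_) else numeric()

  rec <- function(compound, target, assay, comment = "", value = NA,
                  units = NA, relation = NA, target_type = "SINGLE PROTEIN",
                  assay_type = "B", organism = "Homo sapiens") {
    data.frame(compound_id = compound, target_id = target,
               target_type = target_type, assay_id = assay,
               activity_comment = comment, potency_value = value,
               potency_units = units, potency_relation = relation,
               assay_type = assay_type, organism = organism,
               stringsAsFactors = FALSE)
  }
  n_emit <- nrow(emitted)
  records <- rec(emitted$compound_id, emitted$target_id,
                 sprintf("A%05d", seq_len(n_emit)),
                 value = round(stats::rlnorm(n_emit, log(100), 1.2), 2),
                 units = "nM", relation = "=")
  # potencies stay under the ceiling so clean pairs always survive curation
  records$potency_value <- pmin(records$potency_value, 40000)

  deco <- list(); extra <- list(); k <- n_emit
  fresh_assay <- function() { k <<- k + 1L; sprintf("A%05d", k) }
  if ("not_active" %in% spec$decorations) {
    # an in-universe target the compound is not positive for, so the pair
    # survives into the matrix as a known inactive
    c1_pos <- positives$target_id[positives$compound_id == compound_ids[1L]]
    cand_t <- setdiff(target_ids, c1_pos)
    deco_target <- if (length(cand_t)) cand_t[1L] else
      sprintf("T%04d", n_targets + 1L)
    extra$na <- rec(compound_ids[1L], deco_target, fresh_assay(),
                    comment = "Not Active")
    deco$not_active <- data.frame(compound_id = compound_ids[1L],
                                  target_id = deco_target,
                                  outcome = "known_inactive")
  }
  if ("high_potency" %in% spec$decorations) {
    t2 <- sprintf("T%04d", n_targets + 2L)
    extra$hp <- rec(compound_ids[1L], t2, fresh_assay(), value = 60000,
                    units = "nM", relation = ">")
    deco$high_potency <- data.frame(compound_id = compound_ids[1L],
                                    target_id = t2,
                                    outcome = "POTENCY_CEILING")
  }
  if ("complex_target" %in% spec$decorations) {
    t3 <- sprintf("T%04d", n_targets + 3L)
    extra$ct <- rec(compound_ids[1L], t3, fresh_assay(), value = 50,
                    units = "nM", relation = "=",
                    target_type = "PROTEIN COMPLEX")
    deco$complex_target <- data.frame(compound_id = compound_ids[1L],
                                      target_id = t3,
                                      outcome = "TARGET_TYPE")
  }
  if ("duplicate_assay" %in% spec$decorations && n_emit > 0) {
    extra$da <- rec(emitted$compound_id[1L], emitted$target_id[1L],
                    fresh_assay(), value = 120, units = "nM", relation = "=",
                    assay_type = "F")
    deco$duplicate_assay <- data.frame(compound_id = emitted$compound_id[1L],
                                       target_id = emitted$target_id[1L],
                                       outcome = "collapsed")
  }
  if ("excluded_comment" %in% spec$decorations) {
    t4 <- sprintf("T%04d", n_targets + 4L)
    extra$ec <- rec(compound_ids[1L], t4, fresh_assay(),
                    comment = "Not Determined")
    deco$excluded_comment <- data.frame(compound_id = compound_ids[1L],
                                        target_id = t4,
                                        outcome = "COMMENT_EXCLUDED")
  }
  records <- do.call(rbind, c(list(records), unname(extra)))
  records <- records[order(records$compound_id, records$target_id,
                           records$assay_id), , drop = FALSE]
  rownames(records) <- NULL

  list(records = records,
       truth = list(positives = positives, masked = masked,
                    families = data.frame(compound_id = compound_ids,
                                          family = family_of,
                                          stringsAsFactors = FALSE),
                    decorations = if (length(deco)) do.call(rbind, deco)
                                  else NULL,
                    spec = spec))
}

#' Write a synthetic data set to disk
#'
#' Emits the raw bioactivity table in the TSV dialect the curation module
#' reads (with a seed-stamped header comment line) and the truth as JSON.
#'
#' @param synth output of \code{\link{synth_generate}}.
#' @param out_dir writable directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(synth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "bioactivity.tsv")
  con <- file(tsv, "w")
  writeLines(sprintf("# synthetic bioactivity records, seed=%d",
                     synth$truth$spec$seed), con)
  close(con)
  suppressWarnings(
    utils::write.table(synth$records, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", append = TRUE, eol = "\n"))
  truth_path <- file.path(out_dir, "truth.json")
  truth <- synth$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(c(records = tsv, truth = truth_path))
}

#' Read a synthetic bioactivity table back
#'
#' @param path a file written by \code{\link{write_synthetic}} (the header
#'   comment line is skipped).
#' @return a bioactivity record data frame.
#' @export
read_synthetic_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  read_bioactivity_table(textConnection(lines))
}

#' Emit the named fixture suite used by the unit tests
#'
#' Writes three small deterministic fixtures plus a manifest of the
#' downstream values they pin: a curation edge-case table (one record per
#' rejection reason), the two-compound closed-form case (two compounds with
#' identical 15-target profiles plus one private target each, expected
#' cross-candidate score 15/16), and a clustered multi-family table for
#' oracle comparisons.
#'
#' @param out_dir writable directory.
#' @param seed seed for the oracle fixture.
#' @return invisibly, the manifest as a list.
#' @export
emit_fixture_suite <- function(out_dir, seed = 7L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  edge <- synth_generate(synthetic_spec(n_families = 1L,
                                        compounds_per_family = 2L,
                                        targets_per_family = 16L,
                                        within_family_share = 1,
                                        cross_family_noise = 0,
                                        seed = seed))
  write_synthetic(edge, file.path(out_dir, "curation_edge_cases"))

  two <- two_compound_fixture()
  utils::write.table(two, file.path(out_dir, "two_compound.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "", eol = "\n")

  oracle <- synth_generate(synthetic_spec(n_families = 5L,
                                          compounds_per_family = 12L,
                                          targets_per_family = 18L,
                                          within_family_share = 0.85,
                                          cross_family_noise = 0.03,
                                          decorations = character(0),
                                          seed = seed))
  write_synthetic(oracle, file.path(out_dir, "oracle_60"))

  manifest <- list(
    seed = seed,
    curation_edge_cases = list(
      n_records = nrow(edge$records),
      decorations = nrow(edge$truth$decorations)),
    two_compound = list(
      n_shared_targets = 15L,
      expected_cross_tc = 15 / 16,
      note = "C0001's candidate for C0002's sixteenth target scores 15/16"),
    oracle_60 = list(n_compounds = 60L,
                     n_records = nrow(oracle$records)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Two compounds differing by one target (closed-form fixture)
#'
#' Both compounds bind the same fifteen targets and the second binds one
#' more: the first compound's candidate for that sixteenth target scores
#' exactly 15/16 (intersection 15, union 16) with the second compound as
#' reference — the (m-1)/m closed form for a masked pair in an m-target
#' family profile.
#'
#' @return a raw bioactivity record data frame.
#' @export
two_compound_fixture <- function() {
  shared <- sprintf("T%04d", 1:15)
  pairs <- rbind(
    data.frame(compound_id = "C0001", target_id = shared,
               stringsAsFactors = FALSE),
    data.frame(compound_id = "C0002", target_id = c(shared, "T0016"),
               stringsAsFactors = FALSE))
  data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
             target_type = "SINGLE PROTEIN",
             assay_id = sprintf("A%05d", seq_len(nrow(pairs))),
             activity_comment = "", potency_value = 100,
             potency_units = "nM", potency_relation = "=",
             assay_type = "B", organism = "Homo sapiens",
             stringsAsFactors = FALSE)
}
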