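make_record <- function(compound = "C0001", target = "T0001",
                        target_type = "SINGLE PROTEIN", assay = "A00001",
                        comment = "", value = 100, units = "nM",
                        relation = "=", assay_type = "B",
                        organism = "Homo sapiens") {
  data.frame(compound_id = compound, target_id = target,
             target_type = target_type, assay_id = assay,
             activity_comment = comment, potency_value = value,
             potency_units = units, potency_relation = relation,
             assay_type = assay_type, organism = organism,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

test_that("parsing round-trips populated rows and handles degenerate cells", {
  df <- rbind(make_record(), make_record("C0002", "T0002", assay = "A00002"),
              make_record("C0003", "T0003", assay = "A00003", value = 12.5))
  rec <- read_bioactivity_table(write_tsv(df))
  expect_equal(nrow(rec), 3L)
  expect_identical(rec$compound_id, df$compound_id)
  expect_identical(rec$target_id, df$target_id)
  expect_equal(rec$potency_value, df$potency_value)
  expect_identical(rec$potency_relation, df$potency_relation)

  bad <- make_record()
  bad$potency_value <- "ND"
  expect_warning(rec2 <- read_bioactivity_table(write_tsv(bad)),
                 "unparsable potency")
  expect_true(is.na(rec2$potency_value))

  df2 <- df
  names(df2)[names(df2) == "compound_id"] <- "molecule_chembl_id"
  path <- write_tsv(df2)
  expect_error(read_bioactivity_table(path), "molecule_chembl_id|compound_id")
  rec3 <- read_bioactivity_table(path,
                                 column_map = c(compound_id = "molecule_chembl_id"))
  expect_identical(rec3$compound_id, df$compound_id)
})

test_that("parsing round-trips a generated fixture against its truth", {
  s <- synth_generate(synthetic_spec(n_families = 2L,
                                     compounds_per_family = 3L,
                                     targets_per_family = 4L,
                                     within_family_share = 1,
                                     cross_family_noise = 0,
                                     decorations = "duplicate_assay",
                                     seed = 42L))
  dir <- tempfile()
  write_synthetic(s, dir)
  rec <- read_synthetic_table(file.path(dir, "bioactivity.tsv"))
  expect_equal(nrow(rec), nrow(s$records))
  expect_identical(rec$compound_id, s$records$compound_id)
  expect_identical(rec$target_id, s$records$target_id)
  expect_equal(rec$potency_value, s$records$potency_value)
})

test_that("assays over the same protein collapse to one case per pair and class", {
  two <- rbind(make_record(assay = "A00001"),
               make_record(assay = "A00002", value = 50, assay_type = "F"))
  col <- cluster_assays_by_protein(two)
  expect_equal(nrow(col), 1L)
  expect_equal(col$potency_value, 50)       # most favourable potency kept
  expect_identical(col$assay_id, "A00001;A00002")
  expect_identical(col$assay_type, "B;F")

  one <- make_record()
  expect_identical(cluster_assays_by_protein(one)[, names(one)], one)

  # 12 records over 5 pairs; pair (C0001,T0001) has both active and
  # explicit-inactive evidence -> 6 collapsed records
  many <- rbind(
    make_record(assay = "A1"), make_record(assay = "A2"),
    make_record(assay = "A3", comment = "Not Active", value = NA),
    make_record("C0001", "T0002", assay = "A4"),
    make_record("C0001", "T0002", assay = "A5"),
    make_record("C0002", "T0001", assay = "A6"),
    make_record("C0002", "T0001", assay = "A7"),
    make_record("C0002", "T0002", assay = "A8"),
    make_record("C0002", "T0003", assay = "A9"),
    make_record("C0002", "T0003", assay = "A10"),
    make_record("C0002", "T0003", assay = "A11"),
    make_record("C0001", "T0001", assay = "A12"))
  col <- cluster_assays_by_protein(many)
  expect_equal(nrow(col), 6L)
  c11 <- col[col$compound_id == "C0001" & col$target_id == "T0001", ]
  expect_equal(nrow(c11), 2L)  # active + inactive evidence both retained
})

test_that("curation rules reject with exactly one machine-readable reason", {
  recs <- rbind(
    make_record("C0001", "T0001"),
    make_record("C0001", "T0002", value = 50000, relation = ">"),
    make_record("C0001", "T0003", comment = "Not Active", value = NA),
    make_record("C0001", "T0004", target_type = "PROTEIN COMPLEX"),
    make_record("C0001", "T0005", comment = "Not Determined", value = NA),
    make_record("C0001", "T0006", value = 2, units = "uM"),
    make_record("C0001", "T0007", value = 60001, relation = "="))
  cur <- curate_records(recs)
  expect_identical(cur$positives$target_id, "T0001")
  expect_identical(cur$known_inactives$target_id, "T0003")
  got <- setNames(cur$rejection_log$reason, cur$rejection_log$target_id)
  expect_identical(got[["T0002"]], "POTENCY_CEILING")
  expect_identical(got[["T0004"]], "TARGET_TYPE")
  expect_identical(got[["T0005"]], "COMMENT_EXCLUDED")
  expect_identical(got[["T0006"]], "UNIT_UNSUPPORTED")
  expect_identical(got[["T0007"]], "POTENCY_CEILING")
  # one reason per rejected record, and every record lands in one bucket
  expect_equal(nrow(cur$rejection_log), 5L)
  expect_equal(nrow(cur$positives) + nrow(cur$known_inactives) +
                 nrow(cur$rejection_log), nrow(recs))

  # measured-above-ceiling rejection is configurable off
  cur2 <- curate_records(recs, curation_config(
    reject_measured_above_ceiling = FALSE))
  expect_true("T0007" %in% cur2$positives$target_id)
})

test_that("potency ceiling boundary: '>' at exactly 50000 nM is excluded", {
  at <- make_record(value = 50000, relation = ">")
  below <- make_record("C0001", "T0002", value = 49999, relation = ">")
  cur <- curate_records(rbind(at, below))
  expect_identical(cur$rejection_log$target_id, "T0001")
  expect_identical(cur$rejection_log$reason, "POTENCY_CEILING")
  expect_identical(cur$positives$target_id, "T0002")
})

test_that("conflicting active/inactive evidence is arbitrated to positive", {
  recs <- rbind(make_record(assay = "A1"),
                make_record(assay = "A2", comment = "Not Active", value = NA))
  cur <- curate_records(cluster_assays_by_protein(recs))
  expect_equal(nrow(cur$positives), 1L)
  expect_equal(nrow(cur$known_inactives), 0L)
  expect_equal(nrow(cur$conflicts), 1L)
})

test_that("min-target filter drops compounds below the threshold", {
  mk_pairs <- function(compound, n)
    data.frame(compound_id = compound, target_id = sprintf("T%04d", seq_len(n)),
               stringsAsFactors = FALSE)
  pos <- rbind(mk_pairs("C0001", 16), mk_pairs("C0002", 15),
               mk_pairs("C0003", 3))
  m <- build_interaction_matrix(pos)
  expect_identical(m$compounds, c("C0001", "C0002"))
  expect_equal(nrow(m$positives), 31L)

  m1 <- build_interaction_matrix(pos, config = curation_config(
    min_targets_per_compound = 1L))
  expect_equal(nrow(m1$positives), nrow(pos))
  expect_identical(m1$compounds, c("C0001", "C0002", "C0003"))

  expect_error(build_interaction_matrix(mk_pairs("C0001", 3)),
               "empty reference standard")
})

test_that("survivor count matches a brute-force per-compound tally", {
  set.seed(99)
  pos <- data.frame(
    compound_id = sprintf("C%04d", sample.int(40, 900, replace = TRUE)),
    target_id = sprintf("T%04d", sample.int(60, 900, replace = TRUE)),
    stringsAsFactors = FALSE)
  pos <- unique(pos)
  m <- build_interaction_matrix(pos)
  expected <- sum(vapply(split(pos$target_id, pos$compound_id),
                         function(t) length(unique(t)) >= 15, logical(1)))
  expect_equal(length(m$compounds), expected)
  tally <- table(m$positives$compound_id)
  expect_true(all(tally >= 15))
})

test_that("curation is idempotent through serialization", {
  w <- make_world(seed = 5L, n_masked_pairs = 3L)
  path <- tempfile(fileext = ".tsv")
  write_reference_standard(w$matrix, path)
  m2 <- read_reference_standard(path, min_targets = w$matrix$min_targets)
  expect_identical(m2$compounds, w$matrix$compounds)
  expect_identical(m2$targets, w$matrix$targets)
  expect_identical(m2$positives, w$matrix$positives)
  expect_identical(m2$known_inactives, w$matrix$known_inactives)
})
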