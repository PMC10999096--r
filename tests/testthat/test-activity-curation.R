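test_that("table loading drops missing-SMILES and malformed rows with counts", {
  tab <- data.frame(compound_id = c("a", "b", "c"),
                    smiles = c("CCO", "", "CCN"),
                    relation = "=", value_nM = c(100, 200, 300),
                    assay_kind = "biochemical")
  rec <- read_activity_table(tab)
  expect_equal(nrow(rec), 2)
  expect_equal(unname(attr(rec, "curation_log")["missing_smiles"]), 1L)

  tab$value_nM <- c("100", "200", "oops")
  rec2 <- read_activity_table(tab)
  expect_equal(nrow(rec2), 1)  # "" smiles and bad value both dropped
  expect_equal(unname(attr(rec2, "curation_log")["bad_value"]), 1L)

  expect_warning(empty <- read_activity_table(tab[0, , drop = FALSE]),
                 "empty")
  expect_equal(nrow(empty), 0)

  # configurable column mapping
  tab3 <- data.frame(id = "x", smi = "CC", rel = "=", ic50 = 10,
                     kind = "cellular")
  rec3 <- read_activity_table(tab3, col_map = c(
    compound_id = "id", smiles = "smi", relation = "rel",
    value_nM = "ic50", assay_kind = "kind"))
  expect_equal(rec3$compound_id, "x")
  expect_error(read_activity_table(tab3), "column mapping")
})

test_that("relation filter keeps = and > only, and is idempotent", {
  rec <- data.frame(compound_id = letters[1:4], smiles = "CC",
                    relation = c("eq", "gt", "lt", "~"),
                    value_nM = 100, assay_kind = "biochemical")
  kept <- filter_certain(rec)
  expect_equal(kept$relation, c("eq", "gt"))
  expect_equal(filter_certain(kept)$relation, kept$relation)
  all_lt <- rec[rec$relation == "lt", , drop = FALSE]
  expect_equal(nrow(filter_certain(all_lt)), 0)
})

test_that("pIC50 transform is exact, strictly decreasing, and self-inverse", {
  expect_identical(ic50_to_pic50(1000), 6)
  expect_equal(ic50_to_pic50(1), 9)
  expect_equal(ic50_to_pic50(10), 8)
  expect_error(ic50_to_pic50(0), "positive")
  expect_error(ic50_to_pic50(-5), "positive")
  v <- sort(10^runif(50, -1, 6))
  expect_true(all(diff(ic50_to_pic50(v)) < 0))
  x <- runif(20, 2, 10)
  expect_equal(ic50_to_pic50(10^(9 - x)), x)
  expect_equal(pic50_to_ic50(ic50_to_pic50(v)), v)
})

test_that("replicate aggregation follows the nM-mean convention and the dispersion filter", {
  mk <- function(vals, relation = "eq", kind = "biochemical",
                 id = "c1", smi = "CCO") {
    data.frame(compound_id = id, smiles = smi, relation = relation,
               value_nM = vals, assay_kind = kind)
  }
  # replicates at 100 and 1000 nM: pIC50 7 and 6, population SD 0.5 -> kept;
  # the nM-mean convention gives pIC50 of the 550 nM mean
  agg <- aggregate_activities(mk(c(100, 1000)))
  expect_equal(nrow(agg), 1)
  expect_equal(agg$pic50, ic50_to_pic50(550))
  expect_equal(agg$label, "active")  # 6.2596 >= 6

  # alternative convention: mean of pIC50s
  agg_log <- aggregate_activities(mk(c(100, 1000)), average = "pic50")
  expect_equal(agg_log$pic50, 6.5)

  # single record needs no aggregation
  single <- aggregate_activities(mk(500))
  expect_equal(single$pic50, ic50_to_pic50(500), tolerance = 1e-12)
  expect_equal(round(single$pic50, 3), 6.301)
  expect_equal(single$label, "active")

  # pIC50 replicates 1 and 9: population SD 4 on the log scale -> rejected
  wide <- aggregate_activities(mk(pic50_to_ic50(c(1, 9))))
  expect_equal(nrow(wide), 0)
  rej <- attr(wide, "rejections")
  expect_equal(rej$reason, "replicate_dispersion_biochemical")

  # conflicting structures under one id are rejected, never overwritten
  conflict <- rbind(mk(100), mk(200, smi = "CCC"))
  out <- aggregate_activities(conflict)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")$reason, "conflicting_structures")
})

test_that("labeling: active iff certain pIC50 >= 6; censored and weak go inactive at target 2", {
  mk <- function(vals, relation = "eq", id = "c1") {
    data.frame(compound_id = id, smiles = "CCO", relation = relation,
               value_nM = vals, assay_kind = "biochemical")
  }
  at_threshold <- aggregate_activities(mk(1000))  # exactly 1 uM
  expect_equal(at_threshold$label, "active")
  just_below <- aggregate_activities(mk(pic50_to_ic50(5.9)))
  expect_equal(just_below$label, "inactive")
  expect_equal(just_below$target, 2.0)
  censored <- aggregate_activities(mk(10000, relation = "gt"))
  expect_equal(censored$label, "inactive")
  expect_equal(censored$target, 2.0)
})

test_that("assay split: biochemical-only trains, cellular tests, cellular potency decides test inactives", {
  rows <- rbind(
    data.frame(compound_id = "train1", smiles = "CC", relation = "eq",
               value_nM = 200, assay_kind = "biochemical"),
    data.frame(compound_id = "testA", smiles = "CCO", relation = "eq",
               value_nM = c(500, 200),
               assay_kind = c("cellular", "biochemical")),
    data.frame(compound_id = "testI", smiles = "CCN", relation = "eq",
               value_nM = c(5000, 500),
               assay_kind = c("cellular", "biochemical")),
    data.frame(compound_id = "bind1", smiles = "CCS", relation = "eq",
               value_nM = 100, assay_kind = "binding"))
  split <- split_by_assay(aggregate_activities(rows))
  expect_equal(split$training$compound_id, "train1")
  expect_equal(split$test_true$compound_id, c("testA", "testI"))
  # cellular 0.5 uM + biochemical 0.2 uM -> active
  expect_equal(split$test_true$label[1], "active")
  # cellular 5 uM despite biochemical 0.5 uM -> inactive (cellular decides)
  expect_equal(split$test_true$label[2], "inactive")
  # binding-only excluded
  expect_equal(split$excluded$compound_id, "bind1")
  # partition: each compound in exactly one bucket
  all_ids <- c(split$training$compound_id, split$test_true$compound_id,
               split$excluded$compound_id)
  expect_setequal(all_ids, c("train1", "testA", "testI", "bind1"))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("curation counts equal brute-force row-by-row recomputation on a synthetic table", {
  spec <- fixture_spec(seed = 21, n_compounds = 60)
  tab <- gen_activity_table(spec)
  split <- curate_activities(tab)
  gt <- attr(tab, "ground_truth")

  # brute force: recompute per-compound outcomes directly from the rows
  keep <- tab$relation %in% c("=", ">") & nzchar(tab$smiles)
  kept <- tab[keep, , drop = FALSE]
  expected_rejected <- character(0)
  lab <- list()
  for (cid in unique(kept$compound_id)) {
    rc <- kept[kept$compound_id == cid, , drop = FALSE]
    eqb <- rc[rc$relation == "=" & rc$assay_kind == "biochemical", ]
    if (nrow(eqb) > 1) {
      p <- -log10(eqb$value_nM * 1e-9)
      if (sqrt(mean((p - mean(p))^2)) >= 2) {
        expected_rejected <- c(expected_rejected, cid)
        next
      }
    }
    has_bio <- any(rc$assay_kind == "biochemical")
    has_cell <- any(rc$assay_kind == "cellular")
    bucket <- if (has_bio && !has_cell) "training" else
      if (has_cell) "test" else "excluded"
    lab[[cid]] <- bucket
  }
  expect_setequal(attr(split, "rejections")$compound_id, expected_rejected)
  buckets <- unlist(lab)
  expect_equal(nrow(split$training), sum(buckets == "training"))
  expect_equal(nrow(split$test_true), sum(buckets == "test"))
  # planted drop counts recovered exactly
  log <- attr(split, "curation_log")
  expect_equal(unname(log["missing_smiles"]),
               unname(gt$planted["missing_smiles"]))
  expect_equal(unname(log["uncertain_relation"]),
               unname(gt$planted["uncertain"]))
})

test_that("structure standardization strips salts, neutralizes, and unifies tautomers", {
  expect_equal(standardize_structure("CCO.[Na+].[Cl-]"), "CCO")
  # idempotent on an already-standard molecule
  once <- standardize_structure("CCOC")
  expect_equal(standardize_structure(once), once)
  # charged amine is neutralized
  expect_equal(standardize_structure("CC[NH3+]"), "CCN")
  # two tautomer entries give identical output (enol/ketone, amide/imidol)
  expect_equal(standardize_structure("CC(O)=C"), standardize_structure("CC(=O)C"))
  expect_equal(standardize_structure("CC(N)=O"), standardize_structure("CC(=N)O"))
  # unparsable input is rejected with a warning, not an error
  expect_warning(bad <- standardize_structure("not_a_smiles(("), "rejected")
  expect_true(is.na(bad))
})
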