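#' @title Bioactivity curation and assay-aware splitting
#' @description Parses ChEMBL-export-style activity tables, filters to
#'   certain ("=") and censored-above (">") records, aggregates replicate
#'   measurements, applies the replicate-dispersion filter, labels
#'   compounds at the 1 micromolar threshold, and partitions compounds into
#'   a biochemical training set and a cellular test set.
#' @name activity-curation
NULL

#' Convert IC50 (nM) to pIC50
#'
#' `pIC50 = -log10(IC50 * 1e-9)` with IC50 in nanomolar, so 1000 nM
#' (1 micromolar, the activity threshold) maps to exactly 6.
#'
#' @param value_nM positive IC50 (or Kd) in nanomolar.
#' @return pIC50 in log10 units.
#' @export
#' @examples
#' ic50_to_pic50(1000)  # 6
#' ic50_to_pic50(1)     # 9
ic50_to_pic50 <- function(value_nM) {
  if (any(!is.finite(value_nM) | value_nM <= 0))
    stop("IC50 values must be positive and finite")
  -log10(value_nM * 1e-9)
}

#' Inverse transform: pIC50 to IC50 in nM
#' @param pic50 pIC50 value(s).
#' @return IC50 in nanomolar.
#' @export
pic50_to_ic50 <- function(pic50) 10^(9 - pic50)

#' Read activity records from a delimited table
#'
#' One record per row. Rows with missing SMILES are dropped and counted;
#' rows with non-numeric activity values are rejected with a log entry.
#' Relations other than "=" and ">" are retained here and removed by
#' [filter_certain()].
#'
#' @param table a file path or a data.frame.
#' @param col_map named character vector mapping the required fields
#'   (`compound_id`, `smiles`, `relation`, `value_nM`, `assay_kind`) to
#'   column names in the table.
#' @param sep field separator when `table` is a path (default `","`).
#' @return data.frame of activity records with a `curation_log` attribute
#'   (named integer counts of dropped rows).
#' @export
read_activity_table <- function(table,
                                col_map = c(compound_id = "compound_id",
                                            smiles = "smiles",
                                            relation = "relation",
                                            value_nM = "value_nM",
                                            assay_kind = "assay_kind"),
                                sep = ",") {
  df <- if (is.data.frame(table)) table else
    utils::read.table(table, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
  req <- c("compound_id", "smiles", "relation", "value_nM", "assay_kind")
  if (!all(req %in% names(col_map)) || !all(col_map[req] %in% names(df))) {
    stop("column mapping does not match the table; needed: ",
         paste(req, collapse = ", "))
  }
  rec <- data.frame(compound_id = as.character(df[[col_map["compound_id"]]]),
                    smiles = as.character(df[[col_map["smiles"]]]),
                    relation = as.character(df[[col_map["relation"]]]),
                    value_nM = suppressWarnings(
                      as.numeric(df[[col_map["value_nM"]]])),
                    assay_kind = as.character(df[[col_map["assay_kind"]]]),
                    stringsAsFactors = FALSE)
  if (nrow(rec) == 0) {
    warning("empty activity table")
    attr(rec, "curation_log") <- c(missing_smiles = 0L, bad_value = 0L)
    return(rec)
  }
  rec$relation[rec$relation == "="] <- "eq"
  rec$relation[rec$relation == ">"] <- "gt"
  rec$relation[rec$relation == "<"] <- "lt"
  miss_smi <- is.na(rec$smiles) | !nzchar(trimws(rec$smiles))
  bad_val <- !miss_smi & (is.na(rec$value_nM) | rec$value_nM <= 0)
  bad_kind <- !miss_smi & !bad_val &
    !rec$assay_kind %in% c("biochemical", "cellular", "binding")
  out <- rec[!(miss_smi | bad_val | bad_kind), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curation_log") <- c(missing_smiles = sum(miss_smi),
                                 bad_value = sum(bad_val),
                                 bad_assay_kind = sum(bad_kind))
  out
}

#' Keep only certain ("=") and censored-above (">") records
#'
#' "=" records carry certain potencies; ">" records are inactive
#' candidates regardless of their value. Everything else ("<", "~", ...)
#' is discarded. Idempotent.
#'
#' @param records activity-record data.frame.
#' @return filtered data.frame (the `curation_log` attribute gains a
#'   `uncertain_relation` count).
#' @export
filter_certain <- function(records) {
  keep <- records$relation %in% c("eq", "gt")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  log0 <- attr(records, "curation_log")
  if (is.null(log0)) log0 <- integer(0)
  attr(out, "curation_log") <- c(log0, uncertain_relation = sum(!keep))
  out
}

# population standard deviation (the replicate sets here are complete
# measurement sets, not samples)
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate replicate records and label compounds
#'
#' Per compound and assay kind, "=" potencies are averaged — by default
#' the arithmetic mean of IC50 in nM is taken and then log-transformed
#' (`average = "nM"`); averaging on the pIC50 scale is the alternative.
#' Replicates are kept only if their dispersion is below `sd_threshold`;
#' the dispersion is computed on the pIC50 (log) scale by default. A kind
#' with only ">" records is censored and treated as inactive. Compounds
#' whose records disagree on the SMILES string are rejected rather than
#' silently overwritten.
#'
#' A compound is labeled `active` iff it has an "="-derived pIC50 >= 6
#' (IC50 <= 1 micromolar) for the labeling assay kind (biochemical when
#' present, else cellular); inactives carry a regression target pIC50
#' of 2.
#'
#' @param records filtered activity-record data.frame.
#' @param sd_threshold replicate dispersion threshold (default 2).
#' @param sd_scale `"pic50"` (default) or `"nM"` — scale on which the
#'   replicate standard deviation is computed.
#' @param average `"nM"` (default) or `"pic50"` — averaging convention.
#' @return data.frame of curated compounds: `compound_id`, `smiles`,
#'   `pic50_biochemical`, `pic50_cellular`, `gt_biochemical`,
#'   `gt_cellular`, `has_biochemical`, `has_cellular`, `has_binding`,
#'   `pic50`, `label`, `target` (regression target). Rejected compounds
#'   are recorded in the `rejections` attribute with reason codes.
#' @export
aggregate_activities <- function(records, sd_threshold = 2,
                                 sd_scale = c("pic50", "nM"),
                                 average = c("nM", "pic50")) {
  sd_scale <- match.arg(sd_scale)
  average <- match.arg(average)
  stopifnot(all(records$relation %in% c("eq", "gt")))
  rejections <- data.frame(compound_id = character(0), reason = character(0))
  out <- list()
  for (cid in unique(records$compound_id)) {
    rc <- records[records$compound_id == cid, , drop = FALSE]
    if (length(unique(rc$smiles)) > 1) {
      rejections <- rbind(rejections, data.frame(
        compound_id = cid, reason = "conflicting_structures"))
      next
    }
    row <- list(compound_id = cid, smiles = rc$smiles[1],
                pic50_biochemical = NA_real_, pic50_cellular = NA_real_,
                gt_biochemical = FALSE, gt_cellular = FALSE,
                has_biochemical = FALSE, has_cellular = FALSE,
                has_binding = any(rc$assay_kind == "binding"))
    rejected <- FALSE
    for (kind in c("biochemical", "cellular")) {
      rk <- rc[rc$assay_kind == kind, , drop = FALSE]
      if (nrow(rk) == 0) next
      row[[paste0("has_", kind)]] <- TRUE
      eq <- rk[rk$relation == "eq", , drop = FALSE]
      if (nrow(eq) > 0) {
        if (nrow(eq) > 1) {
          disp <- if (sd_scale == "pic50")
            .pop_sd(ic50_to_pic50(eq$value_nM)) else .pop_sd(eq$value_nM)
          if (disp >= sd_threshold) {
            rejections <- rbind(rejections, data.frame(
              compound_id = cid,
              reason = paste0("replicate_dispersion_", kind)))
            rejected <- TRUE
            break
          }
        }
        row[[paste0("pic50_", kind)]] <- if (average == "nM")
          ic50_to_pic50(mean(eq$value_nM)) else mean(ic50_to_pic50(eq$value_nM))
      } else {
        row[[paste0("gt_", kind)]] <- TRUE
      }
    }
    if (rejected) next
    out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  cur <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(compound_id = character(0))
  if (nrow(cur) > 0) {
    # labeling potency: biochemical when available, else cellular
    cur$pic50 <- ifelse(!is.na(cur$pic50_biochemical),
                        cur$pic50_biochemical, cur$pic50_cellular)
    cur$label <- ifelse(!is.na(cur$pic50) & cur$pic50 >= 6,
                        "active", "inactive")
    cur$target <- ifelse(cur$label == "active", cur$pic50, 2.0)
    rownames(cur) <- NULL
  }
  attr(cur, "rejections") <- rejections
  attr(cur, "curation_log") <- attr(records, "curation_log")
  cur
}

#' Split curated compounds by assay annotation
#'
#' Training: compounds with biochemical but not cellular potency. Test:
#' compounds with cellular potency; a test compound is active iff both its
#' cellular and biochemical pIC50 are >= 6, inactive iff its cellular
#' potency is below the threshold (censored ">" counts as inactive) —
#' cellular potency alone decides test inactivity. Compounds with neither
#' annotation (e.g. binding-affinity-only) are excluded and logged.
#'
#' @param compounds curated-compound data.frame from
#'   [aggregate_activities()].
#' @param include_binding_only treat binding-affinity-only compounds as
#'   trainable (default `FALSE`: excluded, since the partitions are
#'   IC50-defined).
#' @return object of class `data_split`: list with `training`,
#'   `test_true`, `excluded` data.frames and a `counts` summary.
#' @export
split_by_assay <- function(compounds, include_binding_only = FALSE) {
  cmp <- compounds
  is_train <- cmp$has_biochemical & !cmp$has_cellular
  is_test <- cmp$has_cellular
  excluded <- cmp[!is_train & !is_test, , drop = FALSE]
  if (!include_binding_only && nrow(excluded) > 0) {
    # stays excluded; flag retained for the manifest
  }
  training <- cmp[is_train, , drop = FALSE]
  test <- cmp[is_test, , drop = FALSE]
  if (nrow(test) > 0) {
    cell_active <- !is.na(test$pic50_cellular) & test$pic50_cellular >= 6
    bio_active <- !is.na(test$pic50_biochemical) & test$pic50_biochemical >= 6
    test$label <- ifelse(cell_active & bio_active, "active", "inactive")
    ambiguous <- cell_active & !bio_active
    test$target <- ifelse(test$label == "active", test$pic50_cellular, 2.0)
    if (any(ambiguous)) {
      excluded <- rbind(excluded, test[ambiguous, , drop = FALSE])
      test <- test[!ambiguous, , drop = FALSE]
    }
  }
  rownames(training) <- rownames(test) <- NULL
  structure(list(training = training, test_true = test,
                 test_decoys = character(0), excluded = excluded,
                 counts = c(
                   train_total = nrow(training),
                   train_active = sum(training$label == "active"),
                   train_inactive = sum(training$label == "inactive"),
                   test_total = nrow(test),
                   test_active = sum(test$label == "active"),
                   test_inactive = sum(test$label == "inactive"),
                   excluded = nrow(excluded))),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split>\n")
  cat(sprintf("  training: %d (%d active / %d inactive)\n",
              x$counts["train_total"], x$counts["train_active"],
              x$counts["train_inactive"]))
  cat(sprintf("  test:     %d (%d active / %d inactive) + %d decoys\n",
              x$counts["test_total"], x$counts["test_active"],
              x$counts["test_inactive"], length(x$test_decoys)))
  cat(sprintf("  excluded: %d\n", x$counts["excluded"]))
  invisible(x)
}

#' Curate an activity table end to end
#'
#' Convenience pipeline: [read_activity_table()] then [filter_certain()],
#' optional structure standardization, [aggregate_activities()] and
#' [split_by_assay()].
#'
#' @inheritParams read_activity_table
#' @inheritParams aggregate_activities
#' @param standardize standardize structures before aggregation (default
#'   `FALSE`; curation counts do not depend on it and bulk standardization
#'   is the costliest step).
#' @param ... passed to [aggregate_activities()].
#' @return a `data_split`; curated compounds in the `compounds` attribute.
#' @export
curate_activities <- function(table, col_map = c(compound_id = "compound_id",
                                                 smiles = "smiles",
                                                 relation = "relation",
                                                 value_nM = "value_nM",
                                                 assay_kind = "assay_kind"),
                              standardize = FALSE, ...) {
  rec <- read_activity_table(table, col_map)
  rec <- filter_certain(rec)
  if (standardize && nrow(rec) > 0) {
    std <- standardize_structure(unique(rec$smiles))
    names(std) <- unique(rec$smiles)
    rec$smiles <- unname(std[rec$smiles])
    rec <- rec[!is.na(rec$smiles), , drop = FALSE]
  }
  cmp <- aggregate_activities(rec, ...)
  split <- split_by_assay(cmp)
  attr(split, "compounds") <- cmp
  attr(split, "curation_log") <- attr(cmp, "curation_log")
  attr(split, "rejections") <- attr(cmp, "rejections")
  split
}

#' Write a split manifest as JSON
#'
#' @param split a `data_split`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_split_manifest <- function(split, file) {
  man <- list(
    counts = as.list(split$counts),
    training = split$training[, c("compound_id", "label", "target")],
    test_true = split$test_true[, c("compound_id", "label", "target")],
    test_decoys = split$test_decoys)
  jsonlite::write_json(man, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
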