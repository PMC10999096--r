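#' @title Early-enrichment evaluation of ranked screens
#' @description Enrichment factor at the top 1% (EF1%), its normalized
#'   form (NEF1%), precision-recall curves, dissimilar-test-set filtering,
#'   nearest-training-neighbor analysis, similarity clustering of hits,
#'   and group comparison of NEF distributions.
#' @name screen-eval
NULL

#' Rank a screen by score
#'
#' Stable descending sort by score; exact ties are broken by ascending
#' compound id (deterministic), or by a seeded shuffle within tie groups
#' when `tie_seed` is given.
#'
#' @param scores numeric scores (higher = predicted more active).
#' @param labels logical (or 0/1) activity labels.
#' @param ids compound identifiers; defaults to `1..N` as characters.
#' @param tie_seed optional integer; when given, ties are shuffled
#'   reproducibly instead of id-ordered.
#' @return object of class `ranked_screen`: data.frame (`compound_id`,
#'   `score`, `is_active`) ordered best-first, with `N` and `A` attributes.
#' @export
rank_screen <- function(scores, labels, ids = NULL, tie_seed = NULL) {
  n <- length(scores)
  if (n == 0) stop("empty screen")
  if (length(labels) != n) stop("scores and labels differ in length")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  labels <- as.logical(labels)
  if (is.null(tie_seed)) {
    ord <- order(-scores, ids)
  } else {
    old <- .Random.seed_save()
    set.seed(tie_seed)
    shuffle <- sample.int(n)
    .Random.seed_restore(old)
    ord <- order(-scores, shuffle)
  }
  out <- data.frame(compound_id = ids[ord], score = scores[ord],
                    is_active = labels[ord], stringsAsFactors = FALSE)
  structure(out, class = c("ranked_screen", "data.frame"),
            N = n, A = sum(labels))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Enrichment factor at the top fraction of a ranked screen
#'
#' The recall-over-fraction form: with `n_top = floor(f * N)` (minimum 1),
#' `EF = (actives in top n_top / A) / f`. This is the definitional variant
#' that exactly reproduces the maxima attainable on inactive-enriched test
#' sets; the precision-ratio form (`hit rate in top bin / overall hit
#' rate`) is available via `form = "precision"`.
#'
#' @param screen a `ranked_screen` with at least one active.
#' @param f top fraction (default 0.01 for EF1%).
#' @param form `"recall"` (default) or `"precision"`.
#' @return enrichment factor (fold change over random).
#' @export
ef_fraction <- function(screen, f = 0.01, form = c("recall", "precision")) {
  form <- match.arg(form)
  stopifnot(f > 0, f <= 1)
  N <- attr(screen, "N"); A <- attr(screen, "A")
  if (A < 1) stop("enrichment undefined without actives")
  n_top <- max(1L, floor(f * N))
  hits <- sum(screen$is_active[seq_len(n_top)])
  if (form == "recall") (hits / A) / f else (hits / n_top) / (A / N)
}

#' Maximal enrichment factor attainable on a test set
#'
#' `min(floor(f * N), A) / A / f` — the EF of a perfect ranking under the
#' recall-over-fraction convention.
#'
#' @param N library size.
#' @param A number of actives (>= 1).
#' @param f top fraction (default 0.01).
#' @return maximal enrichment factor.
#' @export
#' @examples
#' round(max_ef_fraction(3443, 67), 2)  # 50.75
#' round(max_ef_fraction(3426, 57), 2)  # 59.65
max_ef_fraction <- function(N, A, f = 0.01) {
  stopifnot(A >= 1, f > 0, f <= 1)
  n_top <- max(1L, floor(f * N))
  min(n_top, A) / A / f
}

#' Normalized enrichment factor
#'
#' `EF / max EF` on the same test set; lies in `[0, 1]`, equals 1 for a
#' perfect ranking, and permits comparison across test sets of different
#' sizes. The random baseline is `1 / max EF`.
#'
#' @inheritParams ef_fraction
#' @return NEF in `[0, 1]`.
#' @export
nef_fraction <- function(screen, f = 0.01) {
  ef_fraction(screen, f) /
    max_ef_fraction(attr(screen, "N"), attr(screen, "A"), f)
}

#' Precision-recall curve of a ranked screen
#'
#' Precision and recall at every distinct score threshold (ties share a
#' threshold), best-first. The area is computed by step integration
#' (sum of precision times recall increment), not trapezoids.
#'
#' @param screen a `ranked_screen` with at least one active.
#' @return list with `points` (data.frame `recall`, `precision`,
#'   `threshold`) and `auc`.
#' @export
pr_curve <- function(screen) {
  A <- attr(screen, "A")
  if (A < 1) stop("precision-recall undefined without actives")
  k <- seq_len(nrow(screen))
  tp <- cumsum(screen$is_active)
  precision <- tp / k
  recall <- tp / A
  # one point per distinct threshold: keep the last row of each tie group
  last <- c(screen$score[-1] != screen$score[-length(k)], TRUE)
  pts <- data.frame(recall = recall[last], precision = precision[last],
                    threshold = screen$score[last])
  auc <- sum(pts$precision * diff(c(0, pts$recall)))
  list(points = pts, auc = auc)
}

#' Full enrichment report for a ranked screen
#'
#' @param screen a `ranked_screen`.
#' @param f top fraction (default 0.01).
#' @return object of class `enrichment_report`: list with `n_top`, `ef`,
#'   `max_ef`, `nef`, `random_nef`, `pr` (precision-recall curve), `N`,
#'   `A`.
#' @export
enrichment_report <- function(screen, f = 0.01) {
  N <- attr(screen, "N"); A <- attr(screen, "A")
  maxef <- max_ef_fraction(N, A, f)
  ef <- ef_fraction(screen, f)
  structure(list(n_top = max(1L, floor(f * N)), ef = ef, max_ef = maxef,
                 nef = ef / maxef, random_nef = 1 / maxef,
                 pr = pr_curve(screen), N = N, A = A, f = f),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report: N=%d, A=%d, top %d>\n", x$N, x$A, x$n_top))
  cat(sprintf("  EF%g%% = %.2f (max %.2f)   NEF%g%% = %.3f (random %.3f)\n",
              100 * x$f, x$ef, x$max_ef, 100 * x$f, x$nef, x$random_nef))
  cat(sprintf("  PR-AUC = %.3f\n", x$pr$auc))
  invisible(x)
}

#' Select the run whose NEF is closest to the group median
#'
#' Given per-run NEF values (e.g. 10 training-test runs), returns the
#' index of the run with NEF equal (or closest) to the median, chosen at
#' random among ties with a seeded, reproducible draw.
#'
#' @param nef_values numeric vector of per-run NEF values.
#' @param tie_seed seed for the tie-breaking draw (default 1).
#' @return integer run index.
#' @export
select_median_run <- function(nef_values, tie_seed = 1) {
  stopifnot(length(nef_values) >= 1)
  med <- stats::median(nef_values)
  d <- abs(nef_values - med)
  cand <- which(d == min(d))
  if (length(cand) == 1) return(cand)
  old <- .Random.seed_save()
  set.seed(tie_seed)
  pick <- cand[sample.int(length(cand), 1)]
  .Random.seed_restore(old)
  pick
}

# Pairwise max similarity of each test fingerprint to any training
# fingerprint; fps are lists of feature_vectors or binary vectors.
.max_train_similarity <- function(test_fps, train_fps) {
  vapply(test_fps, function(ft) {
    max(vapply(train_fps, function(fr) tanimoto(ft, fr), numeric(1)))
  }, numeric(1))
}

#' Filter a test set down to molecules dissimilar to the training set
#'
#' Retains test entries whose maximum Tanimoto similarity to any training
#' molecule is strictly below `cutoff` (decoys are subject to the same
#' rule).
#'
#' @param test_fps list of test fingerprints (`feature_vector`s or binary
#'   vectors; conventionally Morgan, 2048 bits, radius 2).
#' @param train_fps list of training fingerprints.
#' @param cutoff similarity cutoff (default 0.70).
#' @return logical vector: `TRUE` for retained test entries.
#' @export
dissimilar_filter <- function(test_fps, train_fps, cutoff = 0.70) {
  if (length(test_fps) == 0) return(logical(0))
  .max_train_similarity(test_fps, train_fps) < cutoff
}

#' Nearest training molecule of a test molecule
#'
#' @param test_fp one fingerprint.
#' @param train_fps non-empty list of training fingerprints.
#' @param train_ids training compound ids (default positional).
#' @param train_labels optional training labels, reported for the nearest
#'   neighbor (supports negative-nearest-neighbor analysis).
#' @return list with `similarity`, `train_id`, `train_label`; ties broken
#'   by ascending id.
#' @export
nearest_training_similarity <- function(test_fp, train_fps,
                                        train_ids = NULL,
                                        train_labels = NULL) {
  if (length(train_fps) == 0) stop("empty training set")
  if (is.null(train_ids)) train_ids <- as.character(seq_along(train_fps))
  sims <- vapply(train_fps, function(fr) tanimoto(test_fp, fr), numeric(1))
  best <- which(sims == max(sims))
  best <- best[order(train_ids[best])][1]
  list(similarity = sims[best], train_id = train_ids[best],
       train_label = if (is.null(train_labels)) NA else train_labels[best])
}

#' Cluster molecules by fingerprint similarity
#'
#' Connected components of the graph with an edge between every pair at
#' similarity >= `cutoff` (single linkage / transitive closure: a chain
#' a~b~c clusters together even if sim(a, c) < cutoff). Cluster indices
#' are stable under input reordering up to relabeling; they are assigned
#' in order of each cluster's smallest member id.
#'
#' @param fps list of fingerprints.
#' @param ids compound ids (default positional).
#' @param cutoff similarity cutoff (default 0.70).
#' @return list with `assignment` (named integer vector id -> cluster)
#'   and `n_clusters`.
#' @export
cluster_by_similarity <- function(fps, ids = NULL, cutoff = 0.70) {
  n <- length(fps)
  stopifnot(n >= 1)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    sim <- apply(pairs, 2, function(p) tanimoto(fps[[p[1]]], fps[[p[2]]]))
    edges <- t(pairs[, sim >= cutoff, drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  memb <- igraph::components(g)$membership[as.character(seq_len(n))]
  # relabel clusters by their smallest member id so the partition labels
  # do not depend on input order
  smallest <- tapply(ids, memb, min)
  relabel <- rank(smallest)
  assignment <- as.integer(relabel[as.character(memb)])
  names(assignment) <- ids
  list(assignment = assignment, n_clusters = max(assignment))
}

#' Compare two groups of NEF values
#'
#' Shapiro-Wilk normality check per group, then Welch's unequal-variance
#' two-sided t-test, as used to compare scoring-function families.
#'
#' @param group_a,group_b numeric vectors (length >= 3 each).
#' @return list with `normality_p` (length 2), `welch_p`, `medians`, and
#'   `constant` flags (normality undefined for constant groups).
#' @export
compare_nef_groups <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 values")
  const <- c(a = stats::var(group_a) == 0, b = stats::var(group_b) == 0)
  norm_p <- c(a = if (const["a"]) NA_real_ else
                stats::shapiro.test(group_a)$p.value,
              b = if (const["b"]) NA_real_ else
                stats::shapiro.test(group_b)$p.value)
  welch_p <- if (const["a"] && const["b"] &&
                 stats::var(c(group_a, group_b)) == 0) {
    NA_real_  # identical constant groups: statistic is 0/0
  } else {
    stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
  }
  list(normality_p = norm_p, welch_p = welch_p,
       medians = c(a = stats::median(group_a), b = stats::median(group_b)),
       constant = const)
}
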