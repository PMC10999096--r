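#' @title Tree-structured Parzen estimator (TPE) optimization
#' @description Sequential Bayesian minimization over hyperparameter
#'   search spaces. After a random start-up phase the observations are
#'   split into a "good" quantile and the rest; candidates are drawn from
#'   a Parzen (kernel) estimator of the good set and ranked by the density
#'   ratio good/rest, independently per dimension (the standard
#'   flat-space factorization). Fully deterministic given the seed.
#' @name tpe
NULL

#' Define one hyperparameter axis
#'
#' @param type `"uniform"`, `"loguniform"`, `"quniform"` (uniform rounded
#'   to a grid step `q`), or `"choice"`.
#' @param low,high numeric bounds (ignored for `"choice"`).
#' @param q grid step for `"quniform"`.
#' @param values candidate values for `"choice"`.
#' @return a parameter-axis specification list.
#' @export
hp <- function(type = c("uniform", "loguniform", "quniform", "choice"),
               low = NULL, high = NULL, q = NULL, values = NULL) {
  type <- match.arg(type)
  if (type == "choice") {
    stopifnot(length(values) >= 1)
  } else {
    stopifnot(is.numeric(low), is.numeric(high), low <= high)
    if (type == "quniform") stopifnot(is.numeric(q), q > 0)
    if (type == "loguniform") stopifnot(low > 0)
  }
  list(type = type, low = low, high = high, q = q, values = values)
}

.hp_sample_one <- function(spec) {
  switch(spec$type,
         uniform = stats::runif(1, spec$low, spec$high),
         loguniform = exp(stats::runif(1, log(spec$low), log(spec$high))),
         quniform = {
           v <- stats::runif(1, spec$low, spec$high)
           min(spec$high, max(spec$low, round(v / spec$q) * spec$q))
         },
         choice = spec$values[[sample.int(length(spec$values), 1)]])
}

.space_sample <- function(space, n) {
  lapply(seq_len(n), function(k) lapply(space, .hp_sample_one))
}

# Parzen density of value v under observations obs for one axis; numeric
# axes use a Gaussian mixture with a common data-driven bandwidth (on the
# log scale for loguniform), choice axes a Laplace-smoothed categorical.
.parzen_density <- function(spec, obs, v) {
  if (spec$type == "choice") {
    keys <- vapply(spec$values, function(x) paste(x, collapse = "/"),
                   character(1))
    ok <- vapply(obs, function(x) paste(x, collapse = "/"), character(1))
    counts <- table(factor(ok, levels = keys))
    p <- (counts + 1) / (length(obs) + length(keys))
    return(as.numeric(p[paste(v, collapse = "/")]))
  }
  tr <- if (spec$type == "loguniform") log else identity
  x <- tr(unlist(obs)); xv <- tr(v)
  span <- tr(spec$high) - tr(spec$low)
  bw <- max(stats::sd(x), span / 20, 1e-9)
  mean(stats::dnorm(xv, mean = x, sd = bw))
}

#' Minimize an objective over a search space with TPE
#'
#' @param objective function taking a named list of hyperparameter values
#'   and returning a scalar loss to minimize.
#' @param space named list of [hp()] axes.
#' @param max_evals total number of objective evaluations (default 50).
#' @param seed RNG seed; the full optimization trajectory is reproducible.
#' @param n_startup random evaluations before the TPE model kicks in
#'   (default 10).
#' @param gamma quantile defining the "good" observation set (default
#'   0.25).
#' @param n_candidates candidates drawn from the good-set density per
#'   iteration (default 24).
#' @return list with `best` (hyperparameter list), `best_loss`, and
#'   `trace` (data.frame of losses in evaluation order).
#' @export
tpe_optimize <- function(objective, space, max_evals = 50, seed = 1,
                         n_startup = 10, gamma = 0.25, n_candidates = 24) {
  stopifnot(length(space) >= 1, max_evals >= 1)
  set.seed(seed)
  configs <- list(); losses <- numeric(0)
  evaluate <- function(cfg) {
    loss <- objective(cfg)
    configs[[length(configs) + 1]] <<- cfg
    losses[length(losses) + 1] <<- loss
  }
  degenerate <- all(vapply(space, function(s) {
    (s$type == "choice" && length(s$values) == 1) ||
      (s$type != "choice" && isTRUE(s$low == s$high))
  }, logical(1)))
  if (degenerate) {
    # single-point space: nothing to search
    evaluate(.space_sample(space, 1)[[1]])
    return(list(best = configs[[1]], best_loss = losses[1],
                trace = data.frame(eval = 1L, loss = losses)))
  }
  for (cfg in .space_sample(space, min(n_startup, max_evals))) evaluate(cfg)
  while (length(losses) < max_evals) {
    n_good <- max(1, ceiling(gamma * length(losses)))
    ord <- order(losses)
    good <- configs[ord[seq_len(n_good)]]
    rest <- configs[ord[-seq_len(n_good)]]
    if (length(rest) == 0) rest <- configs
    cand <- list()
    for (k in seq_len(n_candidates)) {
      cfg <- list()
      for (nm in names(space)) {
        spec <- space[[nm]]
        base <- good[[sample.int(length(good), 1)]][[nm]]
        cfg[[nm]] <- if (spec$type == "choice") {
          # resample from the smoothed good-set categorical
          keys <- seq_along(spec$values)
          okeys <- vapply(good, function(g) {
            which(vapply(spec$values, identical, logical(1), g[[nm]]))[1]
          }, numeric(1))
          w <- tabulate(okeys, nbins = length(keys)) + 1
          spec$values[[sample(keys, 1, prob = w)]]
        } else {
          tr <- if (spec$type == "loguniform") log else identity
          inv <- if (spec$type == "loguniform") exp else identity
          span <- tr(spec$high) - tr(spec$low)
          obs <- vapply(good, function(g) tr(g[[nm]]), numeric(1))
          bw <- max(stats::sd(obs), span / 20, 1e-9)
          v <- inv(stats::rnorm(1, tr(base), bw))
          v <- min(spec$high, max(spec$low, v))
          if (spec$type == "quniform")
            v <- min(spec$high, max(spec$low, round(v / spec$q) * spec$q))
          v
        }
      }
      cand[[k]] <- cfg
    }
    score <- vapply(cand, function(cfg) {
      lg <- 0
      for (nm in names(space)) {
        dg <- .parzen_density(space[[nm]], lapply(good, `[[`, nm), cfg[[nm]])
        dr <- .parzen_density(space[[nm]], lapply(rest, `[[`, nm), cfg[[nm]])
        lg <- lg + log(dg + 1e-12) - log(dr + 1e-12)
      }
      lg
    }, numeric(1))
    evaluate(cand[[which.max(score)]])
  }
  best <- which.min(losses)
  list(best = configs[[best]], best_loss = losses[best],
       trace = data.frame(eval = seq_along(losses), loss = losses))
}
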