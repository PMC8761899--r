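#' @title Inter-environment cross-validation of genomic predictions
#' @description Implements the two prediction scenarios of the study design:
#'   intra-population (stratified 10-fold x 10-repetition CV on the pooled
#'   panel, training on the mean of two environments, validating held-out
#'   lines in the third, with predictive ability scored within population)
#'   and inter-population (train on all lines of one population, validate
#'   each other population in the held-out environment).
#' @name crossval
NULL

#' Fit a genomic prediction model by name
#'
#' @param X Training genotypes.
#' @param y Training phenotypes.
#' @param model One of `"rrblup"`, `"bayesA"`, `"bayesC"`, `"bayesLasso"`.
#' @param ... Passed to the fitter (chain settings, seeds, `lambda`).
#' @return A `gs_fit`.
#' @export
fit_gs <- function(X, y, model = "rrblup", ...) {
  switch(model,
    rrblup = fit_rrblup(X, y, ...),
    bayesA = fit_bayes(X, y, model = "A", ...),
    bayesC = fit_bayes(X, y, model = "C", ...),
    bayesLasso = fit_bayes(X, y, model = "Lasso", ...),
    stop("unknown model '", model, "'")
  )
}

#' Predictive ability
#'
#' Pearson correlation between observed and predicted values; `NA` (never 0)
#' when either side has zero variance or fewer than 3 pairs are available.
#'
#' @param observed,predicted Paired numeric vectors.
#' @return Correlation, or `NA_real_` when undefined.
#' @export
predictive_ability <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) return(NA_real_)
  o <- observed[ok]; p <- predicted[ok]
  if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
  stats::cor(o, p)
}

#' Training targets: mean of environment-wise BLUPs over a training pair
#'
#' @param blups Lines x environments matrix of BLUPs (from [env_blups()]).
#' @param train_envs Character length-2 vector of training environments.
#' @return Named numeric vector over the lines present (non-missing) in both
#'   environments; excluded lines are recorded in attribute `excluded`.
#' @export
make_training_targets <- function(blups, train_envs) {
  stopifnot(length(train_envs) == 2, all(train_envs %in% colnames(blups)))
  sub <- blups[, train_envs, drop = FALSE]
  ok <- stats::complete.cases(sub)
  out <- rowMeans(sub[ok, , drop = FALSE])
  attr(out, "excluded") <- rownames(blups)[!ok]
  out
}

#' Stratified fold assignment
#'
#' Lines are shuffled within population and dealt into `k` folds so each
#' fold's per-population counts differ from proportionality by at most one.
#'
#' @param lines Data frame with columns `line`, `population`.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer fold id per line, named by line.
#' @export
cv_folds <- function(lines, k = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(nrow(lines))
  names(fold) <- lines$line
  for (p in unique(lines$population)) {
    idx <- which(lines$population == p)
    idx <- sample(idx)
    # rotate the starting fold so small populations do not always load fold 1
    start <- sample.int(k, 1)
    fold[idx] <- ((seq_along(idx) - 1 + start - 1) %% k) + 1
  }
  fold
}

#' Intra-population, inter-environment cross-validation
#'
#' For each choice of two training environments (third = validation):
#' `reps` repetitions of `k`-fold stratified CV. The model is trained on the
#' two-environment mean BLUPs of the in-fold 90%, and the held-out lines are
#' predicted and scored against their validation-environment BLUPs within
#' each population separately. Cells with fewer than 3 validation lines of a
#' population, or an undefined correlation, are recorded as missing and
#' excluded from averages.
#'
#' @param geno A complete [geno_matrix()].
#' @param blups Lines x environments BLUP matrix for one trait.
#' @param model Model name for [fit_gs()].
#' @param k,reps Folds and repetitions (defaults 10 and 10; fold
#'   partitions are re-drawn independently each repetition).
#' @param seed Master seed for fold draws.
#' @param ... Extra arguments for the model fitter.
#' @return Object of class `cv_result`: `cells` (one row per population x
#'   env-set x rep x fold) and the aggregation in `summary` (see
#'   [aggregate_cv()]).
#' @export
intra_population_cv <- function(geno, blups, model = "rrblup", k = 10,
                                reps = 10, seed = 1, ...) {
  stopifnot(inherits(geno, "geno_matrix"))
  envs <- colnames(blups)
  stopifnot(length(envs) >= 3)
  lines <- geno$lines[geno$lines$line %in% rownames(blups), , drop = FALSE]
  X <- geno$geno[lines$line, , drop = FALSE]
  cells <- list()
  for (v in seq_along(envs)) {
    val_env <- envs[v]
    train_envs <- setdiff(envs, val_env)[1:2]
    targets <- make_training_targets(blups, train_envs)
    obs_val <- blups[, val_env]
    names(obs_val) <- rownames(blups)
    use <- lines[lines$line %in% names(targets), , drop = FALSE]
    for (r in seq_len(reps)) {
      fold <- cv_folds(use, k, seed = sub_seed(seed, v * 1000 + r))
      for (f in seq_len(k)) {
        hold <- names(fold)[fold == f]
        train <- setdiff(use$line, hold)
        fit <- fit_gs(X[train, , drop = FALSE], targets[train], model, ...)
        pred <- predict(fit, X[hold, , drop = FALSE])
        for (p in unique(use$population)) {
          hp <- hold[use$population[match(hold, use$line)] == p]
          r_ab <- if (length(hp) < 3) NA_real_ else {
            predictive_ability(obs_val[hp], pred[hp])
          }
          cells[[length(cells) + 1L]] <- data.frame(
            scenario = "intra_population",
            train_envs = paste(train_envs, collapse = "+"),
            val_env = val_env, population = p, rep = r, fold = f,
            n = length(hp), r_ab = r_ab, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells, summary = aggregate_cv(cells)),
            class = "cv_result")
}

#' Inter-population, inter-environment cross-validation
#'
#' For each training population and each pair of training environments, a
#' single model is fitted on all lines of that population (two-environment
#' mean BLUPs) and evaluated within each *other* population in the held-out
#' environment.
#'
#' @inheritParams intra_population_cv
#' @param train_populations,val_populations Optional restrictions of the
#'   training and validation population sets; they must not overlap (training
#'   and validating on the same population is the intra-population scenario's
#'   job and is rejected here).
#' @return A `cv_result`; `cells` has one row per training population x
#'   env-set x validation population.
#' @export
inter_population_cv <- function(geno, blups, model = "rrblup", seed = 1,
                                train_populations = NULL,
                                val_populations = NULL, ...) {
  stopifnot(inherits(geno, "geno_matrix"))
  envs <- colnames(blups)
  stopifnot(length(envs) >= 3)
  lines <- geno$lines[geno$lines$line %in% rownames(blups), , drop = FALSE]
  pops <- unique(lines$population)
  if (length(pops) < 2) stop("need >= 2 populations for inter-population CV")
  if (!is.null(train_populations) && !is.null(val_populations) &&
      length(intersect(train_populations, val_populations))) {
    stop("training and validation populations must differ in the ",
         "inter-population scenario")
  }
  X <- geno$geno[lines$line, , drop = FALSE]
  cells <- list()
  for (v in seq_along(envs)) {
    val_env <- envs[v]
    train_envs <- setdiff(envs, val_env)[1:2]
    targets <- make_training_targets(blups, train_envs)
    obs_val <- blups[, val_env]
    names(obs_val) <- rownames(blups)
    tr_pops <- if (is.null(train_populations)) pops else train_populations
    for (tp in tr_pops) {
      train <- lines$line[lines$population == tp]
      train <- intersect(train, names(targets))
      fit <- fit_gs(X[train, , drop = FALSE], targets[train], model, ...)
      vl_pops <- setdiff(if (is.null(val_populations)) pops else val_populations, tp)
      for (vp in vl_pops) {
        hold <- lines$line[lines$population == vp]
        pred <- predict(fit, X[hold, , drop = FALSE])
        cells[[length(cells) + 1L]] <- data.frame(
          scenario = "inter_population",
          train_envs = paste(train_envs, collapse = "+"),
          val_env = val_env, train_population = tp, population = vp,
          n = length(hold),
          r_ab = predictive_ability(obs_val[hold], pred[hold]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells, summary = aggregate_cv(cells)),
            class = "cv_result")
}

#' Aggregate cross-validation cells
#'
#' Fixed aggregation order with missing cells excluded at each level:
#' folds -> repetitions -> environment sets -> populations -> grand mean.
#' (For inter-population results there are no fold/rep levels; cells average
#' over validation populations within training population x env-set, then
#' env-sets, then training populations.)
#'
#' @param cells A `cv_result$cells` data frame.
#' @return List with `grand` (scalar), `by_population`, `by_env` tables.
#' @export
aggregate_cv <- function(cells) {
  mean_ <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  if ("fold" %in% names(cells)) {
    lev1 <- stats::aggregate(r_ab ~ population + train_envs + val_env + rep,
                             data = cells, FUN = mean_, na.action = stats::na.pass)
    lev2 <- stats::aggregate(r_ab ~ population + train_envs + val_env,
                             data = lev1, FUN = mean_, na.action = stats::na.pass)
    group <- "population"
  } else {
    lev2 <- stats::aggregate(r_ab ~ train_population + train_envs + val_env,
                             data = cells, FUN = mean_, na.action = stats::na.pass)
    group <- "train_population"
  }
  by_env <- stats::aggregate(r_ab ~ val_env, data = lev2, FUN = mean_,
                             na.action = stats::na.pass)
  lev3 <- stats::aggregate(stats::as.formula(paste("r_ab ~", group)),
                           data = lev2, FUN = mean_, na.action = stats::na.pass)
  list(grand = mean_(lev3$r_ab), by_population = lev3, by_env = by_env,
       by_cell = lev2)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): grand mean r_ab = %.3f\n",
              x$cells$scenario[1], x$summary$grand))
  print(x$summary$by_population, row.names = FALSE)
  invisible(x)
}
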