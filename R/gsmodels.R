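#' @title Whole-genome regression models
#' @description Ridge-regression BLUP with the penalty chosen by restricted
#'   maximum likelihood through a spectral decomposition of the marker
#'   kinship, plus Gibbs-sampled Bayesian A, Bayesian C and Bayesian Lasso.
#'   Markers are centered by training-set column means and left unscaled, so
#'   effects are in allele-dose units; incomplete matrices are refused
#'   (impute upstream).
#' @name gsmodels
NULL

prep_X <- function(X) {
  if (inherits(X, "geno_matrix")) X <- X$geno
  X <- as.matrix(X)
  if (anyNA(X)) stop("genotype matrix contains missing values: impute first")
  storage.mode(X) <- "double"
  X
}

#' Fit ridge-regression BLUP
#'
#' Solves u = (X'X + lambda I)^-1 X'(y - mu) with lambda = se2/su2. When
#' `lambda = NULL` (default) the variance ratio is estimated by maximizing
#' the restricted likelihood of y ~ N(1 mu, su2 (X X' + lambda I)) over
#' lambda in \[1e-5, 1e5\] using one eigendecomposition of the marker
#' kinship X X'. The kinship-form solution u = X'(XX' + lambda I)^-1 (y - mu)
#' is used throughout (efficient when markers outnumber lines and identical
#' to the ridge form).
#'
#' @param X Training genotypes (lines x markers), a matrix or
#'   [geno_matrix()].
#' @param y Training phenotypes (one value per line).
#' @param lambda Optional fixed ridge penalty; `NULL` to estimate by REML.
#' @return Object of class `gs_fit` with intercept, per-marker `effects`,
#'   `lambda`, variance components `su2`/`se2`, and the centering means.
#' @export
fit_rrblup <- function(X, y, lambda = NULL) {
  X <- prep_X(X)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("zero-variance phenotype")
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  K <- tcrossprod(Xc)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  ot <- crossprod(eg$vectors, rep(1, n))
  reml_parts <- function(lam) {
    v <- d + lam
    mu <- sum(ot * yt / v) / sum(ot^2 / v)
    r <- yt - mu * ot
    su2 <- sum(r^2 / v) / (n - 1)
    ll <- -0.5 * ((n - 1) * log(su2) + sum(log(v)) + log(sum(ot^2 / v)) +
                    (n - 1))
    list(ll = ll, mu = mu, su2 = su2, r = r, v = v)
  }
  bounds <- log(c(1e-5, 1e5))
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) reml_parts(exp(l))$ll,
                           interval = bounds, maximum = TRUE, tol = 1e-8)
    lambda <- exp(opt$maximum)
    if (min(abs(opt$maximum - bounds)) < 1e-3) {
      warning("REML lambda estimate at search boundary (lambda = ",
              signif(lambda, 3), ")")
    }
  }
  parts <- reml_parts(lambda)
  alpha <- eg$vectors %*% (parts$r / parts$v)
  effects <- as.numeric(crossprod(Xc, alpha))
  names(effects) <- colnames(X)
  structure(list(
    model = "rrblup",
    intercept = parts$mu,
    effects = effects,
    center = ctr,
    lambda = lambda,
    su2 = parts$su2,
    se2 = lambda * parts$su2,
    n_train = n
  ), class = "gs_fit")
}

#' Fit a Bayesian whole-genome regression by Gibbs sampling
#'
#' Models: `"A"` — per-marker effect variances with scaled-inverse-chi-square
#' priors; `"C"` — common effect variance with marker inclusion indicators
#' and a Beta-sampled inclusion probability pi; `"Lasso"` — double
#' exponential prior via the exponential mixture of normals (Park-Casella),
#' with a Gamma hyperprior on lambda^2. Returned effects are posterior means.
#'
#' Default priors follow common whole-genome-regression practice: effect
#' degrees of freedom 4.1 with scale set so the prior-mean genetic variance
#' matches `h2_prior` (default 0.5) of var(y); residual scale matched to the
#' remaining variance; pi ~ Beta(1, 9).
#'
#' @param X Training genotypes (lines x markers).
#' @param y Training phenotypes.
#' @param model `"A"`, `"C"` or `"Lasso"`.
#' @param niter,burnin,thin Chain settings (defaults 12000 / 2000 / 5).
#' @param seed Optional integer seed.
#' @param h2_prior Prior heritability used to set prior scales.
#' @param nu Prior degrees of freedom for effect variances.
#' @param pi_prior Beta prior (a, b) for the Bayes C inclusion probability.
#' @return A `gs_fit` with posterior-mean `effects`, `intercept`, posterior
#'   means of the variance parameters, per-marker `inclusion` frequencies,
#'   and the chain settings.
#' @export
fit_bayes <- function(X, y, model = c("A", "C", "Lasso"),
                      niter = 12000, burnin = 2000, thin = 5, seed = NULL,
                      h2_prior = 0.5, nu = 4.1, pi_prior = c(1, 9)) {
  model <- match.arg(model)
  X <- prep_X(X)
  stopifnot(nrow(X) == length(y), niter > burnin, burnin >= 0, thin >= 1)
  if (stats::sd(y) == 0) stop("zero-variance phenotype")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  keep <- apply(Xc, 2, function(x) any(x != 0))
  if (!all(keep)) Xc2 <- Xc[, keep, drop = FALSE] else Xc2 <- Xc
  vy <- stats::var(y)
  sum_vx <- sum(apply(Xc2, 2, stats::var))
  # prior mean of scaled-inv-chi2(nu, S) is nu S/(nu - 2)
  mean_vb <- vy * h2_prior / max(sum_vx, 1e-12)
  scale_b <- if (model == "C") {
    # only ~pi of markers carry the signal under Bayes C
    mean_vb / 0.1 * (nu - 2) / nu
  } else {
    mean_vb * (nu - 2) / nu
  }
  nu_e <- 4.1
  scale_e <- vy * (1 - h2_prior) * (nu_e - 2) / nu_e
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_wgr(Xc2, as.numeric(y),
                    model = if (model == "Lasso") "L" else model,
                    niter = as.integer(niter), burnin = as.integer(burnin),
                    thin = as.integer(thin),
                    nu = nu, scale_b = scale_b, nu_e = nu_e, scale_e = scale_e,
                    pi_a = pi_prior[1], pi_b = pi_prior[2],
                    lasso_shape = 1.1, lasso_rate = 0.1)
  effects <- numeric(ncol(Xc))
  inclusion <- numeric(ncol(Xc))
  effects[keep] <- res$effects
  inclusion[keep] <- res$inclusion
  names(effects) <- names(inclusion) <- colnames(X)
  structure(list(
    model = paste0("bayes", model),
    intercept = res$mu,
    effects = effects,
    center = ctr,
    inclusion = inclusion,
    ve = res$ve, vb = res$vb, pi = res$pi,
    chain = c(niter = niter, burnin = burnin, thin = thin,
              n_samples = res$n_samples),
    n_train = nrow(X)
  ), class = "gs_fit")
}

#' Predict from a fitted whole-genome regression
#'
#' intercept + (X_new - training column means) . effects. Columns of `X_new`
#' must match the training markers (any order).
#'
#' @param object A `gs_fit`.
#' @param X_new New genotypes (lines x markers), complete.
#' @param ... Unused.
#' @return Numeric vector of predicted values, named by line when rownames
#'   are present.
#' @export
predict.gs_fit <- function(object, X_new, ...) {
  X_new <- prep_X(X_new)
  mk <- names(object$effects)
  if (!is.null(colnames(X_new))) {
    missing <- setdiff(mk, colnames(X_new))
    if (length(missing)) {
      stop("markers missing from new genotypes: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    }
    X_new <- X_new[, mk, drop = FALSE]
  } else if (ncol(X_new) != length(mk)) {
    stop("marker count mismatch and no column names to match on")
  }
  out <- as.numeric(object$intercept +
                      sweep(X_new, 2, object$center) %*% object$effects)
  names(out) <- rownames(X_new)
  out
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit: %s, %d markers, %d training lines\n",
              x$model, length(x$effects), x$n_train))
  if (x$model == "rrblup") {
    cat(sprintf("  lambda = %.4g (su2 = %.4g, se2 = %.4g)\n",
                x$lambda, x$su2, x$se2))
  } else {
    cat(sprintf("  posterior ve = %.4g; chain %d/%d/%d\n",
                x$ve, x$chain["niter"], x$chain["burnin"], x$chain["thin"]))
  }
  invisible(x)
}
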