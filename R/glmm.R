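# GMMAT-style association: centered genetic relationship matrix, genotype
# principal components as fixed effects, penalized-quasi-likelihood fit of
# a logistic mixed model, and per-variant score tests.

#' Centered genetic relationship matrix
#'
#' GEMMA's centered convention: `K = Z Z' / p` where `Z` is the
#' column-mean-centered dosage matrix over `p` sites. Missing dosages are
#' mean-imputed per site when `impute_missing = TRUE` (the default), which
#' zeroes their centered contribution; with `impute_missing = FALSE` any
#' missing call is an error (prefilter first).
#'
#' @param x a [genotype_matrix()].
#' @param impute_missing mean-impute missing dosages per site.
#' @return Symmetric n x n matrix with the sample ids as dimnames.
#' @export
centered_grm <- function(x, impute_missing = TRUE) {
  p <- n_sites(x)
  if (p == 0L) stop("cannot build a GRM from zero sites")
  Z <- dosage_centered(x, impute_missing)
  K <- tcrossprod(Z) / p
  dimnames(K) <- list(x$samples, x$samples)
  K
}

dosage_centered <- function(x, impute_missing = TRUE, scale = FALSE) {
  D <- x$calls
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    if (!impute_missing) stop("missing calls present; prefilter or impute")
    mu <- colMeans(D, na.rm = TRUE)
    na <- which(is.na(D), arr.ind = TRUE)
    D[na] <- mu[na[, 2L]]
  }
  Z <- sweep(D, 2L, colMeans(D))
  if (scale) {
    s <- apply(Z, 2L, stats::sd)
    s[s == 0] <- 1
    Z <- sweep(Z, 2L, s, "/")
  }
  Z
}

#' Genotype principal components
#'
#' Top-`k` principal component scores of the centered dosage matrix, after
#' a MAF filter (sites with MAF below `maf_min` removed) and thinning
#' (every `thin_every`-th surviving site kept). Deterministic sign
#' convention: in each component the loading of largest magnitude is made
#' positive. Returns fewer components with a warning when the genotype
#' rank is below `k`.
#'
#' @param x a [genotype_matrix()].
#' @param maf_min MAF filter (default 0.01).
#' @param thin_every thinning stride (default 100).
#' @param k number of components (default 5).
#' @param scale scale sites to unit variance before the decomposition.
#' @return Matrix of scores, n x k, column names `PC1..PCk`.
#' @export
genotype_pca <- function(x, maf_min = 0.01, thin_every = 100L, k = 5L,
                         scale = FALSE) {
  if (n_samples(x) < k + 1L) stop("need at least k + 1 samples")
  maf <- site_maf(x)
  keep <- which(!is.na(maf) & maf >= maf_min)
  x <- subset_genotypes(x, sites = keep)
  idx <- seq_len(n_sites(x))
  x <- subset_genotypes(x, sites = idx[(idx - 1L) %% thin_every == 0L])
  Z <- dosage_centered(x, impute_missing = TRUE, scale = scale)
  pc <- stats::prcomp(Z, center = FALSE)
  kk <- min(k, ncol(pc$x), sum(pc$sdev > 1e-10))
  if (kk < k) warning(sprintf("genotype rank supports only %d component(s)",
                              kk))
  scores <- pc$x[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(kk))
  rownames(scores) <- x$samples
  scores
}

#' Fit the logistic mixed null model by penalized quasi-likelihood
#'
#' Null model `logit P(y = 1) = X beta + b`, `b ~ N(0, tau K)`, fitted by
#' PQL: iterate the logistic working response and weights, solve the mixed
#' model equations for `beta` and the BLUP, and update the variance
#' component `tau` by an average-information step with a fixed-point
#' fallback, flooring `tau` at zero, until the relative parameter change
#' drops below `tol` (default 1e-6) or `max_iter` (default 200) is
#' reached. A non-converged fit is returned with `converged = FALSE` and
#' diagnostics rather than raising. Quasi-separation is handled by
#' flooring the working weights, which bounds the coefficients.
#'
#' @param y binary 0/1 phenotype vector.
#' @param X fixed-effect design matrix (include the intercept column);
#'   defaults to intercept only.
#' @param K kinship/GRM matrix, n x n.
#' @param tau0 starting value for the variance component.
#' @param fix_tau keep `tau` fixed at `tau0` (no variance-component
#'   update); used e.g. to recover the plain logistic model at `tau = 0`.
#' @param tol,max_iter convergence control.
#' @return Object of class `glmm_null_fit`: `coefficients`, `tau`,
#'   `fitted` (mu-hat), `P` (projected inverse-variance matrix used by the
#'   score test), `weights`, `converged`, `iterations`.
#' @export
fit_null_glmm <- function(y, X = NULL, K, tau0 = 0.1, fix_tau = FALSE,
                          tol = 1e-6, max_iter = 200L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  K <- as.matrix(K)
  stopifnot(nrow(K) == n, ncol(K) == n, nrow(X) == n)
  g0 <- suppressWarnings(stats::glm.fit(X, y,
                                        family = stats::binomial()))
  beta <- g0$coefficients
  eta <- drop(X %*% beta)
  tau <- max(tau0, 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    ytil <- eta + (y - mu) / w
    V <- diag(1 / w, n) + tau * K
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    beta_new <- drop(solve(XtViX, XtVi %*% ytil))
    P <- Vi - crossprod(XtVi, solve(XtViX, XtVi))
    Py <- drop(P %*% ytil)
    tau_new <- tau
    if (!fix_tau) {
      KPy <- drop(K %*% Py)
      score <- 0.5 * (sum(Py * KPy) - sum(P * K))
      AI <- 0.5 * drop(crossprod(KPy, P %*% KPy))
      if (is.finite(AI) && AI > 1e-10) {
        tau_new <- tau + score / AI
      } else if (sum(P * K) > 0) {
        tau_new <- tau * sum(Py * KPy) / sum(P * K)
      }
      if (!is.finite(tau_new) || tau_new < 0) tau_new <- 0
    }
    b <- tau_new * drop(K %*% Py)
    eta_new <- drop(X %*% beta_new) + b
    delta <- max(abs(c(beta_new - beta, tau_new - tau))) /
      max(1, max(abs(c(beta, tau))))
    beta <- beta_new; tau <- tau_new; eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-6)
  V <- diag(1 / w, n) + tau * K
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  P <- Vi - crossprod(XtVi, solve(XtVi %*% X, XtVi))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 tau = tau, fitted = mu, residuals = y - mu,
                 P = P, weights = w, y = y, X = X,
                 converged = converged, iterations = it),
            class = "glmm_null_fit")
}

#' @export
print.glmm_null_fit <- function(x, ...) {
  cat(sprintf("logistic mixed model null fit: tau = %.4f, %s in %d iteration(s)\n",
              x$tau, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$coefficients)
  invisible(x)
}

#' Score-test scan over all sites
#'
#' GMMAT-style per-variant score test against the null fit: for dosage
#' vector `g`, `U = g'(y - mu_hat)` and `V = g' P g` with `P` the null
#' model's projected inverse-variance matrix; the statistic `U^2 / V` is
#' referred to chi-squared with 1 df. Missing dosages are replaced by the
#' per-site mean, which removes those samples' contribution to the score.
#' Monomorphic sites get `p = 1` and are flagged.
#'
#' @param fit a [fit_null_glmm()] result.
#' @param x a [genotype_matrix()] over the same samples (same order).
#' @return data.frame: `chrom pos statistic p monomorphic neg_log10_p`,
#'   one row per site (Manhattan-plot-ready).
#' @export
score_test_scan <- function(fit, x) {
  if (!fit$converged)
    warning("null model did not converge; score tests may be unreliable")
  stopifnot(n_samples(x) == length(fit$y))
  G <- x$calls
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na <- which(is.na(G), arr.ind = TRUE)
    G[na] <- mu[na[, 2L]]
  }
  U <- drop(crossprod(G, fit$residuals))
  V <- colSums(G * (fit$P %*% G))
  mono <- apply(G, 2L, function(g) length(unique(g)) == 1L) | V <= 1e-12
  stat <- ifelse(mono, 0, U^2 / pmax(V, 1e-300))
  p <- ifelse(mono, 1, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
             statistic = stat, p = p, monomorphic = mono,
             neg_log10_p = -log10(p), stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi^2) / qchisq(0.5, 1)` over a vector of 1-df
#' chi-squared statistics (or of p-values, converted).
#'
#' @param stat chi-squared statistics, or `p` p-values (one of the two).
#' @param p optional p-values.
#' @return Numeric inflation factor.
#' @export
genomic_inflation <- function(stat = NULL, p = NULL) {
  if (is.null(stat)) stat <- stats::qchisq(p, df = 1L, lower.tail = FALSE)
  stats::median(stat) / stats::qchisq(0.5, df = 1L)
}
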