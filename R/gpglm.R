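#' Fit the penalized Gamma-Poisson usage GLM for one region
#'
#' Maximizes the Gamma-Poisson log-likelihood of the paired counts
#' (k0, k1) under the mean model
#' \deqn{\log \mu_{jl} = \beta^S_j + l\,\beta^E + l\,x^{sex}_j \beta^{sex}
#'       + l\,\beta^{UT}_{u(j),t(j)},}
#' with a ridge penalty \eqn{\|\beta^{UT}\|^2/(2\sigma^2) +
#' (\beta^{sex})^2/(2\sigma^2_{sex})} on the shrunken coefficient classes;
#' the per-sample effects \eqn{\beta^S} and the mean-usage effect
#' \eqn{\beta^E} are unpenalized. Fitting is iteratively reweighted least
#' squares with step halving; convergence when the largest coefficient change
#' drops below \code{tol} or after \code{maxit} iterations. With
#' \code{priorVariance = Inf} a vanishing ridge (1e-6) selects the
#' minimum-norm representative of the otherwise unidentifiable interaction
#' decomposition, so \eqn{\beta^{UT}} is the log fold change of usage with
#' respect to the average usage.
#'
#' @param k1,k0 count vectors over samples.
#' @param design validated design table (see \code{\link{checkDesign}}).
#' @param sizeFactors per-sample size factors.
#' @param alpha Gamma-Poisson dispersion (0 = Poisson); must be >= 0.
#' @param priorVariance shrinkage prior variance for the individual-by-tissue
#'   interaction coefficients; \code{Inf} for (min-norm) unpenalized fits.
#' @param priorVarianceSex prior variance for the sex coefficient; defaults
#'   to \code{priorVariance}.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @return list with \code{betaS}, \code{betaE}, \code{betaSex},
#'   \code{betaUT} (named by sample; one entry per individual-tissue
#'   combination), \code{loglik} (unpenalized, at the optimum),
#'   \code{penLoglik}, \code{converged}, \code{iter}, and delta-method
#'   sampling variances \code{varUT}, \code{varSex} of the identifiable
#'   per-sample usage contrasts (used by the shrinkage-prior estimation).
#' @export
fitGPGLM <- function(k1, k0, design, sizeFactors, alpha,
                     priorVariance = Inf, priorVarianceSex = NULL,
                     tol = 1e-8, maxit = 100L) {
  if (alpha < 0) stop("negative dispersion")
  if (is.null(priorVarianceSex)) priorVarianceSex <- priorVariance
  n <- nrow(design)
  stopifnot(length(k1) == n, length(k0) == n, length(sizeFactors) == n)
  X <- .usageModelMatrix(design)
  hasSex <- attr(X, "hasSex")
  y <- c(k0, k1)
  off <- rep(log(sizeFactors), 2L)
  lamUT <- if (is.finite(priorVariance)) 1 / priorVariance else 1e-6
  lamSex <- if (is.finite(priorVarianceSex)) 1 / priorVarianceSex else 1e-6
  lambda <- c(rep(0, n), 0, if (hasSex) lamSex, rep(lamUT, n))
  fit <- cppGPIRLS(X, y, off, alpha, lambda, tol, as.integer(maxit))
  beta <- drop(fit$beta)
  iS <- seq_len(n); iE <- n + 1L
  iSex <- if (hasSex) n + 2L else integer(0)
  iUT <- (n + 1L + as.integer(hasSex)) + seq_len(n)
  # delta-method sampling variance of the per-sample log usage ratio
  # (the identifiable contrast behind beta_UT): var(log k1/k0) at the fit
  mu <- drop(fit$mu)
  vUsage <- 1 / mu[n + seq_len(n)] + 1 / mu[seq_len(n)] + 2 * alpha
  list(betaS = setNames(beta[iS], design$sample_id),
       betaE = beta[iE],
       betaSex = if (hasSex) beta[iSex] else NA_real_,
       betaUT = setNames(beta[iUT], design$sample_id),
       priorVariance = priorVariance,
       converged = fit$converged, iter = fit$iter,
       loglik = fit$loglik, penLoglik = fit$penloglik,
       varUT = setNames(vUsage, design$sample_id),
       varSex = if (hasSex) mean(vUsage) / n else NA_real_)
}

# Model matrix for the usage GLM: rows are the 2n observations (level 0
# block first, then level 1), columns sample effects, level, level:sex,
# level:interaction (one column per sample in a fully crossed design).
.usageModelMatrix <- function(design) {
  n <- nrow(design)
  S <- diag(n)[rep(seq_len(n), 2L), , drop = FALSE]
  l <- rep(c(0, 1), each = n)
  hasSex <- length(unique(design$sex)) > 1L
  X <- cbind(S, level = l,
             if (hasSex) matrix(l * rep(design$sex, 2L), ncol = 1,
                                dimnames = list(NULL, "level_sex")),
             diag(n)[rep(seq_len(n), 2L), , drop = FALSE] * l)
  attr(X, "hasSex") <- hasSex
  X
}

# Model matrices for the tissue LRT: sample effects + level + level:sex +
# (full) level:tissue with treatment coding, and the reduced counterpart
# without level:tissue. Optionally level:individual in both.
.testModelMatrices <- function(design, withIndividual = FALSE) {
  n <- nrow(design)
  S <- diag(n)[rep(seq_len(n), 2L), , drop = FALSE]
  l <- rep(c(0, 1), each = n)
  hasSex <- length(unique(design$sex)) > 1L
  sexcol <- if (hasSex) matrix(l * rep(design$sex, 2L), ncol = 1) else NULL
  indcols <- NULL
  if (withIndividual && nlevels(design$individual) > 1L) {
    D <- stats::model.matrix(~individual, design)[, -1, drop = FALSE]
    indcols <- D[rep(seq_len(n), 2L), , drop = FALSE] * l
  }
  Tt <- stats::model.matrix(~tissue, design)[, -1, drop = FALSE]
  tiscols <- Tt[rep(seq_len(n), 2L), , drop = FALSE] * l
  Xred <- cbind(S, level = l, sexcol, indcols)
  Xfull <- cbind(Xred, tiscols)
  list(full = Xfull, reduced = Xred, df = ncol(tiscols))
}
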