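#' Construct a Dirichlet posterior over model frequencies
#'
#' @param alpha numeric K-vector of positive Dirichlet parameters.
#' @param alpha0 numeric K-vector of positive prior counts (defaults to the
#'   uniform prior in which each model has been observed once).
#' @param nSubjects number of subjects the posterior conditions on
#'   (defaults to `sum(alpha) - sum(alpha0)`).
#' @return A [DirichletPosterior-class].
#' @export
DirichletPosterior <- function(alpha, alpha0 = rep(1, length(alpha)),
                               nSubjects = NULL) {
  assertPositive(alpha, "alpha")
  assertPositive(alpha0, "alpha0")
  if (is.null(nSubjects)) nSubjects <- round(sum(alpha) - sum(alpha0))
  new("DirichletPosterior", alpha = as.numeric(alpha),
      alpha0 = as.numeric(alpha0), nSubjects = as.integer(nSubjects))
}

#' Update posterior model-assignment beliefs
#'
#' One variational E-step of the random-effects hierarchical model: given
#' the current Dirichlet parameters `alpha`, the unnormalised belief that
#' model k generated subject n's data is
#' `u_nk = exp(log p(y_n|m_k) + psi(alpha_k) - psi(sum(alpha)))`
#' with `psi` the digamma function, and the normalised belief is
#' `g_nk = u_nk / sum_k u_nk`. For numerical stability the per-subject
#' maximum of the exponent is subtracted before exponentiation, which is a
#' row rescaling of `u` and leaves `g` unchanged.
#'
#' @param logev a [LogEvidenceMatrix-class] or numeric N x K matrix (nats).
#' @param alpha numeric K-vector of strictly positive Dirichlet parameters.
#' @return An [AssignmentPosterior-class].
#' @export
rfxUpdateAssignments <- function(logev, alpha) {
  logev <- asLogEvidence(logev)
  k <- ncol(logev@values)
  if (length(alpha) != k) {
    stop("'alpha' must have one element per model", call. = FALSE)
  }
  assertPositive(alpha, "alpha")
  lw <- sweep(logev@values, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
  m <- apply(lw, 1L, max)
  u <- exp(lw - m)
  g <- u / rowSums(u)
  new("AssignmentPosterior", g = g, u = u)
}

#' Fit the random-effects group model-selection posterior
#'
#' Inverts the hierarchical Dirichlet-multinomial generative model in which
#' each subject's data-generating model is drawn from unknown population
#' frequencies `r ~ Dirichlet(alpha0)`. Starting from `alpha = alpha0`, the
#' variational scheme iterates: update the assignment beliefs `g` (see
#' [rfxUpdateAssignments()]); accumulate the expected model counts
#' `beta_k = sum_n g_nk`; set `alpha = alpha0 + beta`; until the largest
#' absolute change in any `alpha_k` falls below `tol` or `maxIter` is
#' reached (non-convergence flags the result, it does not error).
#'
#' The fitted Dirichlet posterior `p(r|Y; alpha)` is summarised by the
#' expected model probabilities `<r_k> = alpha_k / sum(alpha)` and, when
#' `computeExceedance` is `TRUE`, the exceedance probabilities `phi_k`
#' (see [exceedanceProbs()]).
#'
#' @inheritParams rfxUpdateAssignments
#' @param alpha0 positive K-vector of Dirichlet prior counts; the default
#'   `[1, ..., 1]` states that each model has been observed once.
#' @param tol convergence tolerance on `max |delta alpha_k|` (default 1e-4).
#' @param maxIter iteration cap (default 64).
#' @param computeExceedance compute exceedance probabilities (default TRUE).
#' @param epSamples Monte-Carlo sample count for exceedance probabilities
#'   when K > 2 (ignored for K = 2, which is closed-form).
#' @param seed optional seed for the K > 2 Monte-Carlo step.
#' @return An [RfxResult-class].
#' @examples
#' # 11 subjects mildly favour model 2; one outlier strongly favours model 1
#' lev <- makeOutlierScenario(12, majorityLogbf = -1, outlierLogbf = 30)
#' expectedR(rfxFit(lev))          # model 2 wins under RFX
#' posteriorProbs(ffxPosterior(lev)) # FFX is dominated by the outlier
#' @export
rfxFit <- function(logev, alpha0 = NULL, tol = 1e-4, maxIter = 64L,
                   computeExceedance = TRUE, epSamples = 1e6, seed = NULL) {
  logev <- asLogEvidence(logev)
  n <- nrow(logev@values)
  k <- ncol(logev@values)
  if (is.null(alpha0)) alpha0 <- rep(1, k)
  if (length(alpha0) != k) {
    stop("'alpha0' must have one element per model", call. = FALSE)
  }
  assertPositive(alpha0, "alpha0")
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("'maxIter' must be >= 1", call. = FALSE)

  alpha <- alpha0
  conv <- FALSE
  iter <- 0L
  asn <- NULL
  beta <- rep(n / k, k)
  for (iter in seq_len(maxIter)) {
    asn <- rfxUpdateAssignments(logev, alpha)
    beta <- colSums(asn@g)
    alphaNew <- alpha0 + beta
    delta <- max(abs(alphaNew - alpha))
    alpha <- alphaNew
    if (delta < tol) {
      conv <- TRUE
      break
    }
  }

  post <- DirichletPosterior(alpha, alpha0 = alpha0, nSubjects = n)
  er <- expectedModelProbs(post)
  phi <- if (computeExceedance) {
    exceedanceProbs(post, nSamples = epSamples, seed = seed)
  } else {
    rep(NA_real_, k)
  }
  new("RfxResult", posterior = post, expectedR = er, exceedance = phi,
      assignment = asn, beta = beta, iterations = iter, converged = conv)
}

#' Expected model probabilities
#'
#' The posterior mean of the model frequencies under `p(r|Y; alpha)`:
#' `<r_k> = alpha_k / (alpha_1 + ... + alpha_K)`, the expected probability
#' that model k would be selected for a randomly chosen subject.
#'
#' @param posterior a [DirichletPosterior-class] (or positive alpha vector).
#' @return Numeric K-vector summing to 1.
#' @examples
#' expectedModelProbs(DirichletPosterior(c(3, 1))) # c(0.75, 0.25)
#' @export
expectedModelProbs <- function(posterior) {
  alpha <- if (is(posterior, "DirichletPosterior")) posterior@alpha
           else posterior
  assertPositive(alpha, "alpha")
  alpha / sum(alpha)
}

#' Exceedance probabilities
#'
#' The exceedance probability `phi_k` is the posterior belief that model k
#' is more frequent in the population than every other model considered:
#' `phi_k = p(r_k > r_j for all j != k | Y; alpha)`.
#'
#' For K = 2 this reduces to the upper tail of the Beta(alpha_1, alpha_2)
#' marginal beyond 1/2, `phi_1 = p(r_1 > 0.5)`, evaluated in closed form
#' with the regularised incomplete beta function so that
#' `phi_1 + phi_2 = 1` exactly. For K > 2 it is estimated by seeded
#' Monte-Carlo sampling of the Dirichlet: `phi_k` is the fraction of draws
#' in which `r_k` is strictly largest (exactly tied draws, a probability-zero
#' event under the continuous density, are discarded).
#'
#' @param posterior a [DirichletPosterior-class] (or positive alpha vector).
#' @param nSamples Monte-Carlo sample count for K > 2 (default 1e6; values
#'   below 1e4 trigger a precision warning). Ignored for K = 2.
#' @param seed optional seed for the K > 2 Monte-Carlo draw; the caller's
#'   RNG state is restored afterwards.
#' @return Numeric K-vector of exceedance probabilities.
#' @examples
#' exceedanceProbs(DirichletPosterior(c(3, 1))) # c(0.875, 0.125)
#' @export
exceedanceProbs <- function(posterior, nSamples = 1e6, seed = NULL) {
  alpha <- if (is(posterior, "DirichletPosterior")) posterior@alpha
           else posterior
  assertPositive(alpha, "alpha")
  k <- length(alpha)
  if (k == 2L) {
    phi1 <- stats::pbeta(0.5, alpha[1L], alpha[2L], lower.tail = FALSE)
    return(c(phi1, 1 - phi1))
  }
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("'nSamples' must be >= 1", call. = FALSE)
  if (nSamples < 1e4) {
    warning("fewer than 1e4 Monte-Carlo samples; exceedance probabilities ",
            "will be imprecise", call. = FALSE)
  }
  withSeed(seed, {
    # Dirichlet draws via normalised gammas; only the argmax is needed, and
    # the normalising constant does not change it, so it is skipped.
    x <- matrix(
      stats::rgamma(nSamples * k, shape = rep(alpha, each = nSamples)),
      nrow = nSamples, ncol = k
    )
    mx <- x[, 1L]
    for (j in 2:k) mx <- pmax(mx, x[, j])
    isMax <- x == mx
    keep <- rowSums(isMax) == 1L
    counts <- colSums(isMax & keep)
    counts / sum(keep)
  })
}
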