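# One augmented-backward-elimination pass on a prepared design matrix.
# Returns the surviving terms and their coefficients. `Xi` must contain an
# "(Intercept)" column; `passive` terms are never dropped.
abeCore <- function(y, Xi, candidates, passive, tau) {
  current <- colnames(Xi)
  fit <- olsCore(y, Xi[, current, drop = FALSE])
  repeat {
    droppable <- intersect(current, candidates)
    if (!length(droppable)) break
    aics <- vapply(droppable, function(term) {
      keep <- setdiff(current, term)
      olsCore(y, Xi[, keep, drop = FALSE])$aic
    }, 0)
    ord <- droppable[order(aics)]
    dropped <- FALSE
    for (term in ord) {
      if (aics[term] >= fit$aic) break  # no remaining drop lowers AIC
      keep <- setdiff(current, term)
      redFit <- olsCore(y, Xi[, keep, drop = FALSE])
      protected <- setdiff(keep, candidates)
      veto <- FALSE
      if (is.finite(tau) && length(protected)) {
        dB <- abs(redFit$coef[protected] - fit$coef[protected])
        # scale floor: a protected coefficient smaller than its SE is
        # guarded at the SE scale, not at its own (near-zero) magnitude
        ref <- pmax(abs(fit$coef[protected]), fit$se[protected])
        veto <- any(dB > tau * ref)
      }
      if (!veto) {
        current <- keep
        fit <- redFit
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(terms = current, fit = fit)
}

#' Augmented backward elimination by AIC
#'
#' Backward stepwise selection: at each step the candidate whose removal
#' most decreases the AIC is dropped, unless the drop is vetoed by the
#' change-in-estimate criterion -- removal must not change any passive
#' (protected) term's coefficient by more than `tau` times its magnitude
#' (floored at its standard error, so near-zero protected coefficients are
#' guarded on the SE scale). Passive terms, always including the
#' intercept, are never dropped themselves.
#' Selection stops when no admissible drop lowers the AIC, so the selected
#' model's AIC never exceeds the full model's. With `tau = Inf` the veto is
#' inert and the procedure reduces to plain backward elimination by AIC.
#'
#' @param y response vector.
#' @param X matrix/data.frame of candidate predictors (named columns).
#' @param passive character vector of protected terms (subset of
#'   `colnames(X)`); the intercept is always protected.
#' @param tau change-in-estimate threshold, default 0.05.
#' @return list with `selected` (candidate terms kept), `fit` (a
#'   [ModelFit-class] of the selected model), `fullFit`, `aic`, `fullAic`.
#' @export
abeSelect <- function(y, X, passive = character(0), tau = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("candidate columns must be named")
  Xi <- cbind(`(Intercept)` = 1, X)
  passive <- union("(Intercept)", passive)
  candidates <- setdiff(colnames(Xi), passive)
  res <- abeCore(y, Xi, candidates, passive, tau)
  keepX <- setdiff(res$terms, "(Intercept)")
  fit <- fitLinearModel(y, Xi[, keepX, drop = FALSE], response = "y")
  fullFit <- fitLinearModel(y, X, response = "y")
  list(selected = intersect(colnames(X), res$terms), fit = fit,
       fullFit = fullFit, aic = fit@aic, fullAic = fullFit@aic)
}

#' Bootstrap stability of model selection
#'
#' Reruns augmented backward elimination on subject-level resamples with
#' replacement and summarizes, per candidate: the bootstrap inclusion
#' frequency; the median and 2.5th/97.5th percentiles of the bootstrap
#' estimates (zero when not selected); the RMSD ratio (root mean squared
#' difference of the zero-filled bootstrap estimates around the full-model
#' estimate, divided by the full-model SE); and the relative conditional
#' bias (percent difference between the mean estimate over resamples where
#' the candidate was selected and the full-model estimate). Rank-deficient
#' resamples are redrawn and counted.
#'
#' @param y response vector.
#' @param X candidate predictor matrix (named columns).
#' @param passive protected terms (inclusion frequency 100 by construction).
#' @param tau change-in-estimate threshold for [abeSelect()].
#' @param nBoot number of bootstrap resamples (1000 in the full protocol).
#' @param seed RNG seed.
#' @return a [SelectionReport-class].
#' @export
bootstrapStability <- function(y, X, passive = character(0), tau = 0.05,
                               nBoot = 1000L, seed = 1L) {
  X <- as.matrix(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  passive <- union("(Intercept)", passive)
  candidates <- setdiff(colnames(Xi), passive)
  terms <- colnames(Xi)
  n <- length(y)

  full <- olsCore(y, Xi)
  orig <- abeCore(y, Xi, candidates, passive, tau)
  selEst <- setNames(numeric(length(terms)), terms)
  selSE <- selEst
  selEst[orig$terms] <- orig$fit$coef[orig$terms]
  selSE[orig$terms] <- orig$fit$se[orig$terms]

  est <- matrix(0, nBoot, length(terms), dimnames = list(NULL, terms))
  inc <- matrix(FALSE, nBoot, length(terms), dimnames = list(NULL, terms))
  nRedrawn <- 0L
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (qr(Xi[idx, , drop = FALSE])$rank == ncol(Xi)) break
      nRedrawn <- nRedrawn + 1L
    }
    res <- abeCore(y[idx], Xi[idx, , drop = FALSE], candidates, passive, tau)
    est[b, res$terms] <- res$fit$coef[res$terms]
    inc[b, res$terms] <- TRUE
  }

  fullEst <- full$coef[terms]
  fullSE <- full$se[terms]
  condBias <- vapply(terms, function(tm) {
    sel <- inc[, tm]
    if (!any(sel) || abs(fullEst[tm]) < 1e-12) return(NA_real_)
    100 * (mean(est[sel, tm]) - fullEst[tm]) / fullEst[tm]
  }, 0)
  tb <- data.frame(
    term = terms,
    fullEstimate = unname(fullEst),
    fullSE = unname(fullSE),
    inclusionFreq = unname(100 * colMeans(inc)),
    selectedEstimate = unname(selEst[terms]),
    selectedSE = unname(selSE[terms]),
    rmsdRatio = unname(sqrt(colMeans((est - rep(fullEst, each = nBoot))^2)) /
                         fullSE),
    relCondBias = unname(condBias),
    bootMedian = unname(apply(est, 2, median)),
    bootLower = unname(apply(est, 2, quantile, 0.025)),
    bootUpper = unname(apply(est, 2, quantile, 0.975)),
    stringsAsFactors = FALSE)
  ord <- order(!(tb$term %in% passive), -tb$inclusionFreq)
  tb <- tb[ord, , drop = FALSE]
  rownames(tb) <- NULL
  new("SelectionReport", table = tb, nBoot = as.integer(nBoot),
      seed = as.integer(seed), nRedrawn = nRedrawn,
      selected = intersect(terms, orig$terms))
}

#' Between-network model for one seed network
#'
#' Builds the candidate set for dissecting one network's between-network
#' effect -- its within-network connectivity, its pairwise between-network
#' connectivity to each other analysis network, and linear plus quadratic
#' age -- then runs augmented backward elimination with bootstrap
#' stability. All connectivity predictors are expected FD-residualized.
#'
#' @param successZ standardized reappraisal success.
#' @param wResid FD-residualized within-network connectivity of the seed
#'   network.
#' @param bPairsResid n x 12 matrix of FD-residualized pairwise between
#'   connectivity, columns named by the partner network.
#' @param ageZ standardized age.
#' @param seedNetwork seed network label used in term names (default SMd).
#' @param tau,nBoot,seed passed to selection and bootstrap.
#' @return a [SelectionReport-class] shaped like a model-stability table.
#' @export
seedBetweenModel <- function(successZ, wResid, bPairsResid, ageZ,
                             seedNetwork = "SMd", tau = 0.05,
                             nBoot = 1000L, seed = 1L) {
  bPairsResid <- as.matrix(bPairsResid)
  if (is.null(colnames(bPairsResid))) stop("pairwise columns must be named")
  X <- cbind(Within = wResid, bPairsResid,
             `Age (linear)` = ageZ, `Age (quadratic)` = ageZ^2)
  colnames(X)[1L + seq_len(ncol(bPairsResid))] <-
    paste0("Between ", seedNetwork, "-", colnames(bPairsResid))
  bootstrapStability(successZ, X, passive = character(0), tau = tau,
                     nBoot = nBoot, seed = seed)
}
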