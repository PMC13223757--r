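# Fast OLS on a design matrix (intercept included by caller); returns the
# pieces the selection loop needs without lm() overhead.
olsCore <- function(y, X) {
  fit <- lm.fit(X, y)
  k <- fit$rank
  if (k < ncol(X)) stop("rank-deficient design: ",
                        paste(colnames(X)[is.na(fit$coefficients)],
                              collapse = ", "))
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
  se <- sqrt(diag(XtXinv) * sigma2)[order(fit$qr$pivot)]
  names(se) <- names(fit$coefficients)
  list(coef = fit$coefficients, se = se, rss = rss, n = n, k = k,
       residuals = fit$residuals,
       aic = gaussianAic(rss, n, k))
}

#' Residualize a connectivity measure on mean FD
#'
#' Regresses each subject-level RSFC measure on the subject's mean
#' framewise displacement (intercept + slope) and returns the residuals,
#' which are orthogonal to mean FD. Applied cohort-wide, once, before any
#' association model, so residual motion cannot masquerade as a
#' brain-behavior effect.
#'
#' @param x per-subject metric vector (n >= 3).
#' @param meanFd per-subject mean FD, same length.
#' @return residual vector (mean 0).
#' @export
residualizeOnFd <- function(x, meanFd) {
  if (length(x) != length(meanFd)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 subjects")
  X <- cbind(1, meanFd)
  as.numeric(x - X %*% solve(crossprod(X), crossprod(X, x)))
}

#' Ordinary least squares with reporting layout
#'
#' Fits y ~ intercept + X by OLS and returns the per-coefficient table
#' (estimate, SE, two-sided t p-value), the overall F test against the
#' intercept-only model, R-squared, and the Gaussian AIC.
#'
#' @param y response vector.
#' @param X data.frame or matrix of predictors (no intercept column).
#' @param response response name for display.
#' @return a [ModelFit-class].
#' @export
fitLinearModel <- function(y, X, response = "y") {
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- if (ncol(X) > 0L) cbind(`(Intercept)` = 1, X)
        else matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- olsCore(y, Xi)
  tval <- fit$coef / fit$se
  pval <- 2 * pt(-abs(tval), fit$n - fit$k)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - fit$rss / tss
  df1 <- fit$k - 1L
  df2 <- fit$n - fit$k
  fstat <- if (df1 > 0) (tss - fit$rss) / df1 / (fit$rss / df2) else NA_real_
  new("ModelFit", response = response,
      coefficients = data.frame(term = colnames(Xi), B = unname(fit$coef),
                                SE = unname(fit$se), t = unname(tval),
                                p = unname(pval), stringsAsFactors = FALSE),
      fstat = fstat, df1 = df1, df2 = df2,
      pOverall = pf(fstat, df1, df2, lower.tail = FALSE),
      r2 = r2, aic = fit$aic, n = as.integer(fit$n))
}

#' Per-network segregation models with FDR
#'
#' One linear model per network predicting (standardized) reappraisal
#' success from that network's FD-residualized segregation plus linear and
#' quadratic standardized age. The overall-model p-values are
#' Benjamini-Hochberg adjusted across the networks; per-coefficient
#' p-values are reported unadjusted.
#'
#' @param successZ standardized success vector.
#' @param segResid n x networks matrix of FD-residualized segregation.
#' @param ageZ standardized age.
#' @return list with `fits` (named list of [ModelFit-class]) and `summary`
#'   (data.frame with segregation B/SE/t/p, overall F, p, FDR-adjusted
#'   overall p, R2 per network). Because the age covariate contributes to
#'   every network's overall fit, the summary also carries `pSegFdr`, the
#'   BH adjustment of the 13 segregation-coefficient p-values -- the
#'   multiplicity correction relevant to asking *which* network's
#'   segregation predicts the outcome.
#' @export
segregationModels <- function(successZ, segResid, ageZ) {
  segResid <- as.matrix(segResid)
  nets <- colnames(segResid)
  if (is.null(nets)) stop("segResid must have network column names")
  fits <- lapply(nets, function(k) {
    X <- cbind(Segregation = segResid[, k], AgeLinear = ageZ,
               AgeQuadratic = ageZ^2)
    fitLinearModel(successZ, X, response = paste0("success~", k))
  })
  names(fits) <- nets
  pOverall <- vapply(fits, function(f) f@pOverall, 0)
  segRow <- function(f) f@coefficients[f@coefficients$term == "Segregation", ]
  summary <- data.frame(
    network = nets,
    B = vapply(fits, function(f) segRow(f)$B, 0),
    SE = vapply(fits, function(f) segRow(f)$SE, 0),
    t = vapply(fits, function(f) segRow(f)$t, 0),
    p = vapply(fits, function(f) segRow(f)$p, 0),
    F = vapply(fits, function(f) f@fstat, 0),
    pModel = pOverall,
    pModelFdr = p.adjust(pOverall, method = "BH"),
    pSegFdr = p.adjust(vapply(fits, function(f) segRow(f)$p, 0), method = "BH"),
    R2 = vapply(fits, function(f) f@r2, 0),
    row.names = NULL)
  list(fits = fits, summary = summary)
}

#' Within/between connectivity models with age interactions
#'
#' Per network: success ~ between + within + age + age^2 +
#' between x age + within x age (interactions with the linear age term;
#' set `quadraticInteractions = TRUE` to add quadratic-age interactions).
#' Connectivity predictors are expected FD-residualized.
#'
#' @param successZ standardized success.
#' @param wResid,bResid n x networks matrices of FD-residualized within-
#'   and between-network connectivity (matching column names).
#' @param ageZ standardized age.
#' @param quadraticInteractions also interact connectivity with age^2.
#' @return named list of [ModelFit-class], one per network.
#' @export
withinBetweenModels <- function(successZ, wResid, bResid, ageZ,
                                quadraticInteractions = FALSE) {
  wResid <- as.matrix(wResid); bResid <- as.matrix(bResid)
  nets <- colnames(wResid)
  if (is.null(nets) || !identical(nets, colnames(bResid)))
    stop("wResid and bResid must share network column names")
  fits <- lapply(nets, function(k) {
    X <- cbind(Between = bResid[, k], Within = wResid[, k],
               AgeLinear = ageZ, AgeQuadratic = ageZ^2,
               `Between:Age` = bResid[, k] * ageZ,
               `Within:Age` = wResid[, k] * ageZ)
    if (quadraticInteractions)
      X <- cbind(X, `Between:Age2` = bResid[, k] * ageZ^2,
                 `Within:Age2` = wResid[, k] * ageZ^2)
    fitLinearModel(successZ, X, response = paste0("success~", k))
  })
  names(fits) <- nets
  fits
}

#' Per-network one-sample t-test on task-contrast values
#'
#' Averages subject x ROI contrast values over each network's ROIs and
#' tests the averages against zero. The default tests across subjects
#' (df = n_subjects - 1); `axis = "rois"` instead averages across subjects
#' and tests across the network's ROIs (df = n_rois - 1).
#'
#' @param roiBetas subjects x ROI matrix of contrast values (ROI columns
#'   named as in the parcellation).
#' @param parc parcellation data.frame.
#' @param networks networks to test (default the 13 analysis networks).
#' @param axis "subjects" (default) or "rois".
#' @return data.frame with network, mean, t, df, p.
#' @export
networkContrastTtest <- function(roiBetas, parc,
                                 networks = analysisNetworks(),
                                 axis = c("subjects", "rois")) {
  axis <- match.arg(axis)
  roiBetas <- as.matrix(roiBetas)
  if (is.null(colnames(roiBetas))) colnames(roiBetas) <- parc$roi_id
  rows <- lapply(networks, function(k) {
    ids <- parc$roi_id[parc$network == k]
    sub <- roiBetas[, colnames(roiBetas) %in% ids, drop = FALSE]
    if (ncol(sub) < 1L) stop("no ROIs for network ", k)
    vals <- if (axis == "subjects") rowMeans(sub) else colMeans(sub)
    if (var(vals) == 0 && mean(vals) == 0) {
      data.frame(network = k, mean = 0, t = 0,
                 df = length(vals) - 1L, p = 1)
    } else {
      tt <- t.test(vals, mu = 0)
      data.frame(network = k, mean = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  do.call(rbind, rows)
}
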