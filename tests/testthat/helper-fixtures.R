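# Shared fixtures and independent reference implementations used as oracles.

# small parcellation: every analysis network present with a few ROIs each
smallParc <- function(roisPerNet = 4L, unassigned = 2L) {
  labs <- c(rep(analysisNetworks(), each = roisPerNet),
            rep("Unassigned", unassigned))
  data.frame(roi_id = sprintf("ROI%03d", seq_along(labs)), network = labs,
             stringsAsFactors = FALSE)
}

# two-network toy parcellation for hand-computable metrics
toyParc <- function(n1 = 3L, n2 = 3L, nets = c("DMN", "DAN")) {
  labs <- c(rep(nets[1], n1), rep(nets[2], n2))
  data.frame(roi_id = sprintf("ROI%03d", seq_along(labs)), network = labs,
             stringsAsFactors = FALSE)
}

makeRun <- function(signal, tr = 1.0) {
  signal <- as.matrix(signal)
  if (is.null(colnames(signal)))
    colnames(signal) <- sprintf("ROI%03d", seq_len(ncol(signal)))
  new("RoiRun", signal = signal, tr = tr)
}

# a symmetric z-matrix with NA diagonal from a random draw
randomZMatrix <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n, 0, 0.4), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- NA_real_
  m
}

# frame-by-frame reference implementation of the censoring cascade
# (deliberately naive: explicit loops, no rle tricks)
oracleCascade <- function(masks, minContig = 5L, minFrames = 50L, n = 800L) {
  out <- lapply(masks, function(m) {
    keep <- m
    i <- 1L
    while (i <= length(m)) {
      if (m[i]) {
        j <- i
        while (j < length(m) && m[j + 1L]) j <- j + 1L
        if (j - i + 1L < minContig) keep[i:j] <- FALSE
        i <- j + 1L
      } else i <- i + 1L
    }
    keep
  })
  out <- lapply(out, function(m) if (sum(m) < minFrames) rep(FALSE, length(m)) else m)
  flat <- unlist(out)
  total <- sum(flat)
  eligible <- total >= n
  sel <- rep(FALSE, length(flat))
  if (eligible) {
    cnt <- 0L
    for (i in seq_along(flat)) {
      if (flat[i] && cnt < n) { sel[i] <- TRUE; cnt <- cnt + 1L }
    }
  }
  lens <- lengths(out)
  split(sel, rep(seq_along(out), lens)) -> selRuns
  list(retained = out, selected = unname(selRuns), eligible = eligible)
}

# naive OLS via the normal equations
oracleOls <- function(y, X) {
  Xi <- cbind(1, as.matrix(X))
  beta <- solve(t(Xi) %*% Xi) %*% t(Xi) %*% y
  res <- y - Xi %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(Xi))
  se <- sqrt(diag(solve(t(Xi) %*% Xi)) * s2)
  list(beta = as.numeric(beta), se = as.numeric(se), rss = sum(res^2))
}

# Benjamini-Hochberg step-up, written from the definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# naive greedy backward elimination by AIC using lm()/stats::AIC
oracleBackwardAic <- function(y, X) {
  df <- data.frame(y = y, X)
  terms <- colnames(X)
  repeat {
    cur <- stats::AIC(lm(reformulate(c("1", terms), "y"), df))
    if (!length(terms)) break
    aics <- sapply(terms, function(tm)
      stats::AIC(lm(reformulate(c("1", setdiff(terms, tm)), "y"), df)))
    if (min(aics) < cur) terms <- setdiff(terms, names(which.min(aics)))
    else break
  }
  sort(terms)
}

# double-loop reference for within/between network means on a z matrix
oracleWithinBetween <- function(z, parc, betweenMode = "brainwide") {
  nets <- intersect(analysisNetworks(), unique(parc$network))
  allIdx <- if (betweenMode == "brainwide") seq_len(nrow(parc))
            else which(parc$network %in% nets)
  W <- B <- setNames(numeric(length(nets)), nets)
  for (k in nets) {
    ik <- which(parc$network == k)
    wvals <- c(); bvals <- c()
    for (a in ik) for (b in ik) if (a < b) wvals <- c(wvals, z[a, b])
    for (a in ik) for (b in setdiff(allIdx, ik)) bvals <- c(bvals, z[a, b])
    W[k] <- mean(wvals); B[k] <- mean(bvals)
  }
  list(W = W, B = B, S = (W - B) / W)
}
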