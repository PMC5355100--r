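#' Mann-Whitney AUC with midrank ties
#'
#' The area under the empirical ROC curve equals the Mann-Whitney
#' probability estimate
#' \eqn{(\#\{pos > neg\} + \tfrac12 \#\{ties\}) / (n_+ n_-)},
#' computed here from midranks.
#'
#' @param pos,neg numeric scores of the positive and negative class
#'   (higher score = more positive).
#' @return AUC in [0, 1].
#' @examples
#' aucMannWhitney(c(3, 5), c(1, 4))  # 0.75
#' @export
aucMannWhitney <- function(pos, neg) {
  nPos <- length(pos); nNeg <- length(neg)
  if (nPos < 1L || nNeg < 1L) stop("both classes must be non-empty")
  if (anyNA(pos) || anyNA(neg)) stop("scores must not contain NA")
  r <- rank(c(pos, neg))
  nPos <- as.numeric(nPos); nNeg <- as.numeric(nNeg)  # avoid int overflow
  (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Hanley-McNeil standard error of an AUC
#'
#' \eqn{SE = \sqrt{(A(1-A) + (n_+ - 1)(Q_1 - A^2) +
#' (n_- - 1)(Q_2 - A^2)) / (n_+ n_-)}} with
#' \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param auc AUC in [0, 1].
#' @param nPos,nNeg class sizes.
#' @return standard error (0 when \code{auc} is exactly 1).
#' @export
aucSeHanley <- function(auc, nPos, nNeg) {
  stopifnot(auc >= 0, auc <= 1, nPos >= 1, nNeg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
          (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg)
  sqrt(max(v, 0))
}

#' Youden-optimal operating threshold
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the observed
#' cut points, under the rule score >= threshold calls positive. Ties in
#' J are broken toward higher specificity (the larger threshold).
#'
#' @param pos,neg numeric scores per class.
#' @return list with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{j}.
#' @export
youdenThreshold <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")
  cand <- sort(unique(c(pos, neg)))
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  ## specificity is non-decreasing in the threshold, so the largest
  ## tied threshold is the most specific one
  best <- max(which(j == max(j)))
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Binormal AUC from group means and SDs
#'
#' Closed form for the AUC of two normal score distributions:
#' \eqn{\Phi((\mu_+ - \mu_-)/\sqrt{\sigma_-^2 + \sigma_+^2})}. Useful as
#' a desk approximation when only group-level means and SDs are reported.
#'
#' @param muNeg,sdNeg,muPos,sdPos group parameters (negative = control).
#' @return AUC in (0, 1).
#' @examples
#' binormalAuc(2.16, 2.44, 6.91, 5.40)  # ~0.789
#' @export
binormalAuc <- function(muNeg, sdNeg, muPos, sdPos) {
  stopifnot(sdNeg >= 0, sdPos >= 0)
  s <- sqrt(sdNeg^2 + sdPos^2)
  if (s == 0) {
    if (muPos == muNeg)
      stop("AUC undefined for two identical point masses")
    return(as.numeric(muPos > muNeg))
  }
  stats::pnorm((muPos - muNeg) / s)
}

#' Full ROC summary of a score
#'
#' Bundles [aucMannWhitney()], [aucSeHanley()] and [youdenThreshold()]
#' into a [RocSummary-class].
#'
#' @param pos,neg numeric scores per class.
#' @return a \code{RocSummary}.
#' @export
rocSummary <- function(pos, neg) {
  a <- aucMannWhitney(pos, neg)
  y <- youdenThreshold(pos, neg)
  new("RocSummary", auc = a,
      se = aucSeHanley(a, length(pos), length(neg)),
      threshold = y$threshold, sensitivity = y$sensitivity,
      specificity = y$specificity,
      nPos = length(pos), nNeg = length(neg))
}

#' @rdname RocSummary-class
#' @export
setMethod("auc", "RocSummary", function(object) object@auc)

#' @rdname RocSummary-class
#' @export
setMethod("aucSE", "RocSummary", function(object) object@se)

#' @describeIn RocSummary-class sensitivity/specificity/threshold
#'   accessors.
#' @param x a \code{RocSummary}.
#' @export
operatingPoint <- function(x) {
  c(threshold = x@threshold, sensitivity = x@sensitivity,
    specificity = x@specificity)
}

setMethod("show", "RocSummary", function(object) {
  cat(sprintf(
    "RocSummary: AUC %.3f (SE %.3f), sens %.2f / spec %.2f at %.4g (n+ %d, n- %d)\n",
    object@auc, object@se, object@sensitivity, object@specificity,
    object@threshold, object@nPos, object@nNeg))
})

#' Fit a logistic multi-marker panel
#'
#' Binary logistic regression of class on marker values, fit by
#' iteratively reweighted least squares with a small ridge penalty on the
#' slopes so separable data still yield a finite, deterministic fit.
#' Constant markers are dropped with a warning. The panel score is the
#' linear predictor; any monotone transform (e.g. the fitted probability)
#' gives the same ROC.
#'
#' @param markers numeric matrix, samples x markers, column names = marker
#'   ids.
#' @param labels per-sample class: logical, 0/1, or values
#'   \code{"tumor"}/\code{"normal"}.
#' @param ridge ridge penalty on slopes (default 1e-6).
#' @param maxIter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return a [PanelModel-class].
#' @export
fitPanel <- function(markers, labels, ridge = 1e-6, maxIter = 100L,
                     tol = 1e-10) {
  markers <- as.matrix(markers)
  if (is.null(colnames(markers)))
    colnames(markers) <- paste0("m", seq_len(ncol(markers)))
  y <- normalizeLabels(labels)
  if (length(y) != nrow(markers))
    stop("one label per sample row is required")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  keep <- apply(markers, 2, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning("dropping constant marker(s): ",
            paste(colnames(markers)[!keep], collapse = ", "))
    markers <- markers[, keep, drop = FALSE]
  }
  if (ncol(markers) == 0L) stop("no non-constant markers left")
  X <- cbind("(Intercept)" = 1, markers)
  P <- diag(c(0, rep(ridge, ncol(markers))))
  beta <- numeric(ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    betaNew <- tryCatch(
      drop(solve(XtW %*% X + P, XtW %*% z)),
      error = function(e) stop("IRLS step failed: ", conditionMessage(e)))
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (!all(is.finite(beta)))
      stop("IRLS diverged (non-finite coefficients at iteration ", iter, ")")
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
  }
  if (!converged)
    stop("IRLS did not converge in ", maxIter,
         " iterations (last step ", format(delta), ")")
  names(beta) <- colnames(X)
  new("PanelModel", markers = colnames(markers), coefficients = beta,
      ridge = ridge, iterations = iter, converged = converged)
}

normalizeLabels <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("tumor", "normal")))
    stop("labels must be logical, 0/1, or 'tumor'/'normal'")
  as.numeric(lab == "tumor")
}

#' @rdname PanelModel-class
#' @export
setMethod("panelMarkers", "PanelModel", function(object) object@markers)

#' @describeIn PanelModel-class model coefficients (intercept first).
#' @param object a \code{PanelModel}.
#' @export
setMethod("coef", "PanelModel", function(object) object@coefficients)

setMethod("show", "PanelModel", function(object) {
  cat("PanelModel:", length(object@markers), "markers, ridge",
      object@ridge, "\n")
  print(round(object@coefficients, 4))
})

#' Panel score (linear predictor) for new samples
#'
#' @param model a [PanelModel-class].
#' @param markers matrix samples x markers; must contain the model's
#'   marker columns.
#' @return numeric score per sample.
#' @export
panelScore <- function(model, markers) {
  markers <- as.matrix(markers)
  miss <- setdiff(panelMarkers(model), colnames(markers))
  if (length(miss))
    stop("marker(s) missing from data: ", paste(miss, collapse = ", "))
  X <- cbind(1, markers[, panelMarkers(model), drop = FALSE])
  drop(X %*% coef(model))
}

#' Evaluate single markers and a combined panel on cohorts
#'
#' Fits the logistic panel on the training cohort only, scores any
#' validation cohort with the frozen coefficients, and reports, per
#' marker and per cohort, the group means/SDs, a two-sided Student
#' t-test p-value, and the ROC summary, plus a panel row per cohort.
#'
#' @param train list with \code{markers} (samples x markers) and
#'   \code{group} (\code{"tumor"}/\code{"normal"}), e.g. from
#'   [markerMatrix()].
#' @param validation optional second cohort of the same shape; its marker
#'   columns must include the panel's.
#' @param panel marker ids to combine; default all training columns.
#' @param ridge passed to [fitPanel()].
#' @return list with \code{table} (one row per marker/panel per cohort:
#'   means, SDs, p, AUC, SE, sensitivity, specificity), \code{model}
#'   (the [PanelModel-class]) and \code{roc} (named list of
#'   [RocSummary-class] objects).
#' @export
evaluateCohorts <- function(train, validation = NULL,
                            panel = colnames(train$markers),
                            ridge = 1e-6) {
  checkCohort <- function(co, what) {
    if (!all(c("markers", "group") %in% names(co)))
      stop(what, " must be a list with 'markers' and 'group'")
    if (nrow(co$markers) != length(co$group))
      stop(what, ": one group label per sample row required")
  }
  checkCohort(train, "train")
  if (!is.null(validation)) {
    checkCohort(validation, "validation")
    miss <- setdiff(panel, colnames(validation$markers))
    if (length(miss))
      stop("validation lacks panel marker(s): ",
           paste(miss, collapse = ", "))
  }
  model <- fitPanel(train$markers[, panel, drop = FALSE], train$group,
                    ridge = ridge)
  cohorts <- list(training = train)
  if (!is.null(validation)) cohorts$validation <- validation
  rows <- list(); rocs <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    isPos <- normalizeLabels(co$group) == 1
    evalScore <- function(id, score) {
      pos <- score[isPos]; neg <- score[!isPos]
      rs <- rocSummary(pos, neg)
      rocs[[paste(cn, id, sep = ".")]] <<- rs
      p <- tryCatch(stats::t.test(pos, neg, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      data.frame(cohort = cn, marker = id,
                 meanNormal = mean(neg), sdNormal = stats::sd(neg),
                 meanTumor = mean(pos), sdTumor = stats::sd(pos),
                 p = p, auc = auc(rs), se = aucSE(rs),
                 sensitivity = rs@sensitivity,
                 specificity = rs@specificity,
                 stringsAsFactors = FALSE)
    }
    for (id in colnames(co$markers))
      rows[[paste(cn, id)]] <- evalScore(id, co$markers[, id])
    rows[[paste(cn, "panel")]] <-
      evalScore("panel", panelScore(model, co$markers))
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       model = model, roc = rocs)
}
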