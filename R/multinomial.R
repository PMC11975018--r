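#' Maximum-likelihood multinomial logistic regression
#'
#' Newton-Raphson fit of a baseline-category multinomial logit with class 1
#' as reference. Standard errors come from the inverse observed information;
#' they coincide with the Wald intervals reported in clinical tables.
#'
#' @param X design matrix (n x p, including intercept column).
#' @param y integer class labels in 1..K (1 = reference).
#' @param K number of classes (default \code{max(y)}).
#' @param max_iter,tol Newton iteration controls.
#' @return list: \code{coef} (p x (K-1)), \code{vcov} (p(K-1) square, block
#'   order class-major), \code{se} (p x (K-1)), \code{loglik},
#'   \code{converged}, \code{separation} (TRUE when estimates diverge, e.g.
#'   complete separation).
#' @export
multinom_ml <- function(X, y, K = max(y), max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < p) {
    cc <- suppressWarnings(stats::cor(X[, apply(X, 2, stats::sd) > 0, drop = FALSE]))
    pair <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(pair))
      stop("perfectly collinear predictors: ",
           rownames(cc)[pair[1, 1]], " and ", colnames(cc)[pair[1, 2]])
    stop("design matrix is rank deficient")
  }
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[, k - 1L] <- as.numeric(y == k)

  B <- matrix(0, p, K - 1L)
  ll_of <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(rowSums(Y * eta)) - sum(lse)
  }
  ll <- ll_of(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    P <- exp(eta - m) / denom                      # n x (K-1)
    g <- as.vector(crossprod(X, Y - P))            # class-major gradient
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (k in seq_len(K - 1L)) for (l in k:(K - 1L)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(X, X * w)
      ik <- (k - 1L) * p + 1:p; il <- (l - 1L) * p + 1:p
      H[ik, il] <- blk
      if (k != l) H[il, ik] <- t(blk)
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new_B <- B + matrix(step, p, K - 1L)
    new_ll <- ll_of(new_B)
    halvings <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2; halvings <- halvings + 1L
      if (halvings > 30L) break
      new_B <- B + matrix(step, p, K - 1L)
      new_ll <- ll_of(new_B)
    }
    done <- abs(new_ll - ll) < tol * (abs(ll) + 1)
    B <- new_B; ll <- new_ll
    if (done) { converged <- TRUE; break }
  }
  # observed information at the optimum
  eta <- X %*% B
  m <- pmax(apply(eta, 1, max), 0)
  P <- exp(eta - m) / (exp(-m) + rowSums(exp(eta - m)))
  H <- matrix(0, p * (K - 1L), p * (K - 1L))
  for (k in seq_len(K - 1L)) for (l in k:(K - 1L)) {
    w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
    blk <- crossprod(X, X * w)
    ik <- (k - 1L) * p + 1:p; il <- (l - 1L) * p + 1:p
    H[ik, il] <- blk
    if (k != l) H[il, ik] <- t(blk)
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nrow(H), ncol(H)))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1L)
  separation <- !converged || any(abs(B) > 15) || any(!is.finite(se)) ||
    any(se > 1e3, na.rm = TRUE)
  dimnames(B) <- dimnames(se) <- list(colnames(X), paste0("class", 2:K))
  list(coef = B, vcov = V, se = se, loglik = ll,
       converged = converged, separation = separation, K = K, n = n)
}

#' Wald confidence interval on the odds-ratio scale
#'
#' @param coefficient log odds ratio.
#' @param se standard error (> 0).
#' @param level confidence level in [0, 1).
#' @return numeric \code{c(lower, upper)} = \code{exp(coefficient -/+ z se)}.
#' @export
wald_ci <- function(coefficient, se, level = 0.95) {
  if (any(se <= 0)) stop("se must be > 0")
  z <- stats::qnorm((1 + level) / 2)
  c(exp(coefficient - z * se), exp(coefficient + z * se))
}

transform_predictor <- function(x, transform) {
  switch(transform,
         none = x,
         log10 = log10(x),
         sqrt = sqrt(x),
         stop("unknown transform '", transform, "'"))
}

contrast_names <- function(K) paste0("P", 2:K, " vs P1")

#' Univariable multinomial regression of phenotype on one predictor
#'
#' Fits intercepts + one predictor; reports per-contrast odds ratios with
#' Wald 95\% CIs and p-values, a Benjamini-Hochberg adjustment over the
#' K-1 contrasts, and the overall likelihood-ratio p for the predictor
#' block (df = K-1). For a binary predictor the model is saturated, so
#' fitted ORs equal the 2x2 contingency-table sample odds ratios.
#'
#' @param x predictor values (one per participant).
#' @param labels integer phenotype labels 1..K (1 = reference).
#' @param name predictor name for reporting.
#' @param transform \code{"none"}, \code{"log10"} or \code{"sqrt"}, applied
#'   before fitting.
#' @param level confidence level (default 0.95).
#' @return object of class \code{mlbpsp_predictor_result}: data.frame
#'   \code{table} (one row per contrast), \code{overall_p}, \code{fit},
#'   \code{separation}, \code{stage = "univariable"}.
#' @export
univariable_multinomial <- function(x, labels, name = "x",
                                    transform = "none", level = 0.95) {
  ok <- !is.na(x) & !is.na(labels)
  x <- transform_predictor(x[ok], transform)
  y <- as.integer(labels[ok])
  if (stats::sd(x) == 0) stop("predictor '", name, "' is constant")
  K <- max(y)
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2] <- name
  fit <- multinom_ml(X, y, K)
  # intercept-only null has closed-form ML: log class frequency ratios
  counts <- tabulate(y, nbins = K)
  ll0 <- sum(counts * log(counts / sum(counts)))
  lr <- 2 * (fit$loglik - ll0)
  overall_p <- stats::pchisq(max(lr, 0), df = K - 1L, lower.tail = FALSE)
  co <- fit$coef[2, ]; se <- fit$se[2, ]
  z <- qn <- stats::qnorm((1 + level) / 2)
  p <- 2 * stats::pnorm(-abs(co / se))
  tab <- data.frame(
    predictor = name, transform = transform, contrast = contrast_names(K),
    coefficient = unname(co), or = unname(exp(co)), se = unname(se),
    ci_lower = unname(exp(co - qn * se)), ci_upper = unname(exp(co + qn * se)),
    p = unname(p), p_adj = bh_adjust(unname(p)),
    stage = "univariable", row.names = NULL)
  structure(list(table = tab, overall_p = overall_p, fit = fit,
                 separation = fit$separation, stage = "univariable",
                 predictor = name),
            class = "mlbpsp_predictor_result")
}

#' Screen predictors for the multivariable model
#'
#' @param results list of \code{mlbpsp_predictor_result}.
#' @param threshold inclusion threshold on the overall p (default 0.10,
#'   inclusive).
#' @return character vector of predictor names passing, in input order.
#' @export
screen_predictors <- function(results, threshold = 0.10) {
  keep <- vapply(results, function(r) r$overall_p <= threshold, logical(1))
  vapply(results[keep], `[[`, character(1), "predictor")
}

#' Multivariable multinomial model with backward elimination
#'
#' Jointly fits the screened predictors plus forced covariates, then
#' iteratively removes the predictor whose best (minimum) contrast p is
#' largest and above \code{retain_threshold}, refitting until every retained
#' predictor has some contrast p at or below it. Forced covariates are never
#' removed. BH adjustment (over the K-1 contrasts) is applied per predictor
#' in the final model.
#'
#' @param baseline data.frame of baseline covariates keyed by participant
#'   order matching \code{labels}.
#' @param predictors screened predictor names (columns of \code{baseline}).
#' @param labels integer phenotype labels 1..K.
#' @param forced covariate names always kept (default \code{"education"}).
#' @param transforms named character vector of per-predictor transforms.
#' @param retain_threshold retention threshold on the minimum contrast p
#'   (default 0.05, inclusive).
#' @param level confidence level for Wald CIs.
#' @return list: \code{results} (one \code{mlbpsp_predictor_result} per term
#'   in the final model, stage "multivariable"), \code{trace}
#'   (\code{ModelSelectionTrace}: screened, forced, eliminated in order,
#'   retained), \code{fit}.
#' @export
multivariable_multinomial <- function(baseline, predictors, labels,
                                      forced = "education",
                                      transforms = NULL,
                                      retain_threshold = 0.05,
                                      level = 0.95) {
  forced <- intersect(forced, names(baseline))
  terms_now <- unique(c(forced, setdiff(predictors, forced)))
  if (!length(setdiff(terms_now, forced)) && !length(forced))
    stop("no predictors to fit")
  y <- as.integer(labels)
  K <- max(y)
  get_col <- function(v) {
    tr <- if (!is.null(transforms) && v %in% names(transforms)) transforms[[v]] else "none"
    transform_predictor(baseline[[v]], tr)
  }
  eliminated <- character(0)
  repeat {
    X <- cbind(`(Intercept)` = 1,
               do.call(cbind, stats::setNames(lapply(terms_now, get_col), terms_now)))
    ok <- stats::complete.cases(X) & !is.na(y)
    fit <- multinom_ml(X[ok, , drop = FALSE], y[ok], K)
    co <- fit$coef[-1, , drop = FALSE]; se <- fit$se[-1, , drop = FALSE]
    pmat <- 2 * stats::pnorm(-abs(co / se))
    min_p <- apply(pmat, 1, min)
    removable <- setdiff(terms_now, forced)
    cand <- removable[min_p[removable] > retain_threshold]
    if (!length(cand)) break
    drop_term <- removable[which.max(min_p[removable])]
    eliminated <- c(eliminated, drop_term)
    terms_now <- setdiff(terms_now, drop_term)
  }
  qn <- stats::qnorm((1 + level) / 2)
  results <- lapply(terms_now, function(v) {
    co <- fit$coef[v, ]; se <- fit$se[v, ]
    p <- 2 * stats::pnorm(-abs(co / se))
    tr <- if (!is.null(transforms) && v %in% names(transforms)) transforms[[v]] else "none"
    tab <- data.frame(
      predictor = v, transform = tr, contrast = contrast_names(K),
      coefficient = unname(co), or = unname(exp(co)), se = unname(se),
      ci_lower = unname(exp(co - qn * se)), ci_upper = unname(exp(co + qn * se)),
      p = unname(p), p_adj = bh_adjust(unname(p)),
      stage = "multivariable", row.names = NULL)
    structure(list(table = tab, overall_p = NA_real_, fit = fit,
                   separation = fit$separation, stage = "multivariable",
                   predictor = v),
              class = "mlbpsp_predictor_result")
  })
  names(results) <- terms_now
  retained <- setdiff(terms_now, forced)
  list(results = results,
       trace = list(screened = setdiff(predictors, forced), forced = forced,
                    eliminated = eliminated, retained = retained),
       fit = fit)
}
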