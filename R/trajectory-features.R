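#' Feature specification
#'
#' @param name feature (column) name.
#' @param transform \code{"none"} or \code{"sqrt"}; the square-root transform
#'   is used to normalise right-skewed non-negative raw scores before mixed
#'   modelling.
#' @param nonneg logical; must be \code{TRUE} when \code{transform = "sqrt"}.
#' @return object of class \code{mlbpsp_feature_spec}.
#' @export
feature_spec <- function(name, transform = c("sqrt", "none"),
                         nonneg = transform == "sqrt") {
  transform <- match.arg(transform)
  if (transform == "sqrt" && !nonneg)
    stop("square-root transform requires the non-negativity flag")
  structure(list(name = name, transform = transform, nonneg = nonneg),
            class = "mlbpsp_feature_spec")
}

#' Default specs for the 17-feature roster (all square-root transformed)
#' @return named list of \code{\link{feature_spec}} objects.
#' @export
default_feature_specs <- function() {
  roster <- default_feature_roster()
  stats::setNames(lapply(roster, feature_spec), roster)
}

#' Transform a feature vector per its spec
#'
#' Missing values pass through unchanged; negative observed values under a
#' square-root spec are a data error reporting the offending positions.
#'
#' @param values numeric vector of raw values (may contain NA).
#' @param spec a \code{\link{feature_spec}}.
#' @param context optional data.frame (e.g. \code{pid}, \code{visit_month})
#'   used to name offending rows in error messages.
#' @return transformed numeric vector.
#' @export
transform_feature <- function(values, spec, context = NULL) {
  if (spec$transform == "none") return(values)
  bad <- which(!is.na(values) & values < 0)
  if (length(bad)) {
    where <- if (!is.null(context))
      paste(utils::capture.output(print(context[bad[1L], , drop = FALSE])), collapse = " ")
    else paste("position", bad[1L])
    stop("negative value for '", spec$name, "' under square-root transform (",
         where, ")")
  }
  sqrt(values)
}

#' Fit a per-feature trajectory mixed model
#'
#' Fits, by maximum likelihood on all observed rows (valid under MAR, no
#' imputation),
#' \deqn{y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 t_{ij}^2 +
#'   b_{0i} + b_{1i} t_{ij} + b_{2i} t_{ij}^2 + \epsilon_{ij}}
#' with \eqn{b_i \sim N(0, G)} (unstructured 3x3) and
#' \eqn{\epsilon \sim N(0, \sigma^2)}; time is coded in visit units
#' \code{t = visit_month / 6}. If the unstructured fit fails to converge, the
#' model is refit with independent (diagonal-G) random effects and the
#' fallback flag set. Empirical-Bayes effects are the conditional modes
#' \eqn{\hat b_i = G Z_i' V_i^{-1}(y_i - X_i\hat\beta)}.
#'
#' @param panel an \code{mlbpsp_panel} (long format).
#' @param spec a \code{\link{feature_spec}} naming a panel column.
#' @return object of class \code{mlbpsp_lmm_fit}: \code{beta} (length 3),
#'   \code{G} (3x3), \code{sigma2}, \code{ranef} (data.frame pid/intercept/
#'   slope/quad), \code{converged}, \code{fallback}, \code{n_obs}.
#' @export
fit_feature_lmm <- function(panel, spec) {
  f <- spec$name
  if (!f %in% names(panel)) stop("feature '", f, "' not in panel")
  d <- data.frame(pid = factor(panel$pid), t = panel$visit_month / 6,
                  y = transform_feature(panel[[f]], spec,
                                        context = panel[c("pid", "visit_month")]))
  d <- d[!is.na(d$y), , drop = FALSE]
  if (length(unique(d$t)) < 3L)
    stop("feature '", f, "': fewer than 3 distinct visit times; quadratic term inestimable")

  pids <- levels(d$pid)
  # Degenerate constant feature: variance components are all zero and every
  # empirical-Bayes effect is zero; lmer cannot fit a zero-variance response.
  if (stats::var(d$y) < 1e-12) {
    re <- data.frame(pid = pids, intercept = 0, slope = 0, quad = 0)
    return(structure(list(feature = f, beta = c(d$y[1L], 0, 0),
                          G = matrix(0, 3, 3), sigma2 = 0, ranef = re,
                          converged = TRUE, fallback = FALSE, degenerate = TRUE,
                          n_obs = nrow(d)),
                     class = "mlbpsp_lmm_fit"))
  }

  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            optCtrl = list(maxfun = 1e5))
  fit <- suppressWarnings(suppressMessages(
    try(lme4::lmer(y ~ t + I(t^2) + (t + I(t^2) | pid), data = d,
                   REML = FALSE, control = ctrl), silent = TRUE)))
  fallback <- FALSE
  if (inherits(fit, "try-error") || !lmm_converged(fit)) {
    fallback <- TRUE
    fit <- suppressWarnings(suppressMessages(
      try(lme4::lmer(y ~ t + I(t^2) + (t + I(t^2) || pid), data = d,
                     REML = FALSE, control = ctrl), silent = TRUE)))
    if (inherits(fit, "try-error") || !lmm_converged(fit))
      stop("feature '", f, "': mixed model failed to converge under both ",
           "unstructured and diagonal covariance structures")
  }

  beta <- unname(lme4::fixef(fit))
  vc <- lme4::VarCorr(fit)
  G <- matrix(0, 3, 3)
  for (blk in vc) {
    # map block rows (named "(Intercept)", "t", "I(t^2)") into the 3x3 G
    idx <- match(rownames(blk), c("(Intercept)", "t", "I(t^2)"))
    G[idx, idx] <- G[idx, idx] + as.matrix(blk[, , drop = FALSE])
  }
  sigma2 <- stats::sigma(fit)^2

  rr <- lme4::ranef(fit)
  re <- matrix(0, length(pids), 3, dimnames = list(pids, NULL))
  for (blk in rr) {
    idx <- match(colnames(blk), c("(Intercept)", "t", "I(t^2)"))
    re[rownames(blk), idx] <- re[rownames(blk), idx] + as.matrix(blk)
  }
  structure(list(feature = f, beta = beta, G = G, sigma2 = sigma2,
                 ranef = data.frame(pid = pids, intercept = re[, 1],
                                    slope = re[, 2], quad = re[, 3],
                                    row.names = NULL),
                 converged = TRUE, fallback = fallback, degenerate = FALSE,
                 n_obs = nrow(d)),
            class = "mlbpsp_lmm_fit")
}

lmm_converged <- function(fit) {
  if (!inherits(fit, "merMod")) return(FALSE)
  cc <- fit@optinfo$conv$lme4
  is.null(cc$code) || cc$code >= 0
}

#' Assemble the participant random-effects matrix
#'
#' Binds the per-feature empirical-Bayes effects into the N x 3F matrix used
#' for clustering, columns named \code{<feature>__intercept/slope/quad} in
#' declared feature order. Participants with zero observations for a feature
#' receive that feature's prior mean (0, 0, 0); those cells are recorded in
#' \code{attr(, "provenance")}.
#'
#' @param fits named or ordered list of \code{mlbpsp_lmm_fit}.
#' @param pids optional character vector fixing the participant universe and
#'   order; default is the union over fits.
#' @return numeric matrix with rownames \code{pid}.
#' @export
extract_random_effects <- function(fits, pids = NULL) {
  if (is.null(pids)) pids <- sort(unique(unlist(lapply(fits, function(f) f$ranef$pid))))
  seen <- unique(unlist(lapply(fits, function(f) f$ranef$pid)))
  orphan <- setdiff(pids, seen)
  if (length(orphan))
    stop("participant(s) present in no fit: ", paste(orphan, collapse = ", "))
  cols <- unlist(lapply(fits, function(f)
    paste0(f$feature, "__", c("intercept", "slope", "quad"))))
  M <- matrix(0, length(pids), length(cols), dimnames = list(pids, cols))
  prov <- NULL
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    jj <- (j - 1L) * 3L + 1:3
    idx <- match(f$ranef$pid, pids)
    M[idx[!is.na(idx)], jj] <- as.matrix(f$ranef[!is.na(idx), c("intercept", "slope", "quad")])
    missing_pid <- setdiff(pids, f$ranef$pid)
    if (length(missing_pid))
      prov <- rbind(prov, data.frame(pid = missing_pid, feature = f$feature))
  }
  attr(M, "provenance") <- prov
  M
}

#' Fit all roster features and assemble the matrix
#'
#' Convenience wrapper for step one of the pipeline.
#'
#' @inheritParams fit_feature_lmm
#' @param specs named list of \code{\link{feature_spec}}.
#' @return list with \code{fits} (per-feature) and \code{matrix}
#'   (\code{\link{extract_random_effects}} output over all panel pids).
#' @export
fit_trajectories <- function(panel, specs = default_feature_specs()) {
  fits <- lapply(specs, function(s) fit_feature_lmm(panel, s))
  list(fits = fits,
       matrix = extract_random_effects(fits, pids = sort(unique(panel$pid))))
}
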