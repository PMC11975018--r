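#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by m/i, enforces
#' monotonicity from the largest down, caps at 1, and returns the adjusted
#' values in input order.
#'
#' @param p numeric p-values in [0, 1].
#' @param m family size, at least \code{length(p)} (default
#'   \code{length(p)}).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

#' Baseline group comparison for one variable
#'
#' One-way ANOVA (numeric) or Pearson chi-square without continuity
#' correction (categorical) across phenotype groups, plus pairwise tests of
#' the same kind over the declared comparison family with BH adjustment.
#'
#' @param values variable values (numeric, or factor/character/binary for
#'   categorical).
#' @param labels integer phenotype labels.
#' @param kind \code{"numeric"} or \code{"categorical"}.
#' @param family \code{"vs1"} (each phenotype vs phenotype 1, k = K-1) or
#'   \code{"all_pairs"} (k = K(K-1)/2).
#' @return object of class \code{mlbpsp_comparison}: \code{summary}
#'   (per-group mean(sd) or n(\%)), \code{statistic}, \code{p},
#'   \code{pairwise} (data.frame with raw and BH-adjusted p), \code{kind},
#'   \code{family_size}.
#' @export
compare_baseline_variable <- function(values, labels,
                                      kind = c("numeric", "categorical"),
                                      family = c("vs1", "all_pairs")) {
  kind <- match.arg(kind); family <- match.arg(family)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.integer(labels[ok])
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(vapply(groups, function(g) sum(labels == g), integer(1)) == 0L))
    stop("a group has zero observations")

  pairs <- if (family == "vs1") {
    cbind(groups[1L], groups[-1L])
  } else t(utils::combn(groups, 2L))

  if (kind == "numeric") {
    fit <- stats::oneway.test(values ~ factor(labels), var.equal = TRUE)
    statistic <- unname(fit$statistic); p <- unname(fit$p.value)
    summ <- vapply(groups, function(g)
      sprintf("%.2f (%.2f)", mean(values[labels == g]),
              stats::sd(values[labels == g])), character(1))
    pw <- apply(pairs, 1, function(pr) {
      tt <- stats::t.test(values[labels == pr[2]], values[labels == pr[1]],
                          var.equal = TRUE)
      unname(tt$p.value)
    })
  } else {
    tab <- table(labels, values)
    if (any(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected < 1))
      warning("expected cell count below 1")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ct$statistic); p <- unname(ct$p.value)
    summ <- vapply(groups, function(g) {
      n_g <- sum(labels == g)
      lev <- sort(unique(values))
      pos <- if (length(lev) == 2L) sum(labels == g & values == lev[2L]) else n_g
      sprintf("%d (%.1f%%)", pos, 100 * pos / n_g)
    }, character(1))
    pw <- apply(pairs, 1, function(pr) {
      sub <- labels %in% pr
      t2 <- table(labels[sub], values[sub])
      unname(suppressWarnings(stats::chisq.test(t2, correct = FALSE))$p.value)
    })
  }
  k_fam <- nrow(pairs)
  structure(list(
    summary = stats::setNames(summ, paste0("P", groups)),
    statistic = statistic, p = p,
    pairwise = data.frame(group_a = pairs[, 2], group_b = pairs[, 1],
                          p = pw, p_adj = bh_adjust(pw, m = k_fam)),
    kind = kind, family_size = k_fam),
    class = "mlbpsp_comparison")
}

#' Longitudinal outcome model by phenotype
#'
#' Fits, by maximum likelihood, a mixed model for an outcome over visits
#' with fixed effects of phenotype, time (visit units, month/6) and their
#' interaction, and a participant random intercept. Reports phenotype
#' main-effect and interaction contrasts against phenotype 1 with Wald
#' normal-approximation p-values, BH-adjusted within each (K-1)-contrast
#' family.
#'
#' @param panel an \code{mlbpsp_panel}.
#' @param labels integer phenotype labels named by pid.
#' @param outcome panel column to model.
#' @param spec optional \code{\link{feature_spec}} for pre-transformation
#'   (default square-root, matching the skewed raw scores).
#' @return object of class \code{mlbpsp_trajectory_contrast}:
#'   \code{fixef} (full fixed-effect table), \code{contrasts} (data.frame of
#'   main and interaction contrasts vs P1 with p and p_adj), \code{fit}.
#' @export
fit_outcome_trajectory_lmm <- function(panel, labels, outcome,
                                       spec = feature_spec(outcome)) {
  lab <- labels[match(panel$pid, names(labels))]
  if (all(is.na(lab))) stop("labels do not match panel pids")
  if (any(table(labels) < 2L)) stop("phenotype with fewer than 2 participants")
  if (length(unique(labels)) < 2L) stop("all participants share one phenotype")
  d <- data.frame(pid = factor(panel$pid),
                  phen = factor(lab),
                  t = panel$visit_month / 6,
                  y = transform_feature(panel[[outcome]], spec,
                                        context = panel[c("pid", "visit_month")]))
  d <- d[!is.na(d$y) & !is.na(d$phen), , drop = FALSE]
  if (length(unique(d$t)) < 2L) stop("outcome observed at fewer than 2 visits")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ phen * t + (1 | pid), data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  fixef_tab <- data.frame(term = names(est), estimate = unname(est),
                          se = unname(se), z = unname(z), p = unname(p))
  is_main <- grepl("^phen[0-9]+$", fixef_tab$term)
  is_int <- grepl("^phen[0-9]+:t$", fixef_tab$term)
  ctr <- rbind(
    data.frame(type = "main", fixef_tab[is_main, ]),
    data.frame(type = "interaction", fixef_tab[is_int, ]))
  ctr$p_adj <- c(bh_adjust(ctr$p[ctr$type == "main"]),
                 bh_adjust(ctr$p[ctr$type == "interaction"]))
  structure(list(outcome = outcome, fixef = fixef_tab, contrasts = ctr,
                 fit = fit),
            class = "mlbpsp_trajectory_contrast")
}

#' Characterize phenotypes against baseline covariates
#'
#' Runs \code{\link{compare_baseline_variable}} over a covariate table.
#'
#' @param baseline data.frame with a \code{pid} column and covariates.
#' @param labels integer labels named by pid.
#' @param numeric_vars,categorical_vars covariate names by kind; defaults
#'   infer kind (<= 2 distinct non-missing values => categorical).
#' @param family comparison family passed through.
#' @return named list of \code{mlbpsp_comparison}.
#' @export
characterize_phenotypes <- function(baseline, labels,
                                    numeric_vars = NULL, categorical_vars = NULL,
                                    family = "vs1") {
  lab <- labels[match(baseline$pid, names(labels))]
  vars <- setdiff(names(baseline), "pid")
  if (is.null(numeric_vars) && is.null(categorical_vars)) {
    guess <- vapply(vars, function(v)
      length(unique(stats::na.omit(baseline[[v]]))) <= 2L, logical(1))
    categorical_vars <- vars[guess]
    numeric_vars <- vars[!guess]
  }
  out <- c(
    lapply(stats::setNames(numeric_vars, numeric_vars), function(v)
      compare_baseline_variable(baseline[[v]], lab, "numeric", family)),
    lapply(stats::setNames(categorical_vars, categorical_vars), function(v)
      compare_baseline_variable(baseline[[v]], lab, "categorical", family)))
  out[intersect(vars, names(out))]
}
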