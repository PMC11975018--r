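#' Phenotype archetype
#'
#' Defines one latent phenotype of a synthetic cohort: its mixture weight and,
#' per feature, a quadratic mean trajectory on the transformed (square-root)
#' scale, a 3x3 random-effect covariance and a residual standard deviation.
#' Trajectories are parameterized per visit unit (one unit = 6 months), so a
#' coefficient vector \code{c(a, b, c)} gives the transformed-scale mean
#' \code{a + b*t + c*t^2} at visit index \code{t = month/6}.
#'
#' @param label integer phenotype index (1-based).
#' @param weight mixture proportion in [0, 1].
#' @param trajectories named list (one entry per feature) of numeric
#'   coefficient vectors \code{c(intercept, linear, quadratic)}.
#' @param G named list of 3x3 symmetric positive semi-definite random-effect
#'   covariance matrices, or a single matrix recycled over features.
#' @param sigma named numeric vector of residual SDs, or a single value
#'   recycled over features.
#' @return an object of class \code{mlbpsp_archetype}.
#' @export
phenotype_archetype <- function(label, weight, trajectories, G, sigma) {
  stopifnot(length(label) == 1L, length(weight) == 1L,
            weight >= 0, weight <= 1, is.list(trajectories))
  features <- names(trajectories)
  if (is.null(features) || any(!nzchar(features)))
    stop("trajectories must be a named list keyed by feature")
  if (is.matrix(G)) G <- stats::setNames(rep(list(G), length(features)), features)
  if (length(sigma) == 1L) sigma <- stats::setNames(rep(sigma, length(features)), features)
  for (f in features) {
    co <- trajectories[[f]]
    if (length(co) != 3L) stop("trajectory for '", f, "' must have 3 coefficients")
    Gf <- G[[f]]
    if (is.null(Gf) || !isTRUE(all.equal(Gf, t(Gf))) ||
        min(eigen(Gf, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("random-effect covariance for '", f, "' is not symmetric PSD")
    if (is.na(sigma[[f]]) || sigma[[f]] < 0)
      stop("residual sd for '", f, "' must be >= 0")
  }
  structure(list(label = as.integer(label), weight = as.numeric(weight),
                 features = features, trajectories = trajectories,
                 G = G, sigma = sigma),
            class = "mlbpsp_archetype")
}

#' Cohort simulation configuration
#'
#' @param n_participants number of participants to simulate.
#' @param visit_months strictly increasing visit grid in months.
#' @param miss_visit_rates per-visit probability that the whole visit is
#'   missing. The first (baseline) entry is forced to 0: every participant
#'   has baseline data.
#' @param item_miss_rate per-(participant, visit, feature) independent
#'   missingness probability applied after visit-level deletion. The default
#'   solves \code{1 - (1 - r)^(17*4) = 0.283} so that about 28.3\% of
#'   participants miss at least one feature cell.
#' @param seed integer root seed; stage-level child seeds are derived from it.
#' @return an object of class \code{mlbpsp_cohort_config}.
#' @export
cohort_config <- function(n_participants = 506L,
                          visit_months = c(0, 6, 12, 18),
                          miss_visit_rates = c(0, 0, 0.083, 0.194),
                          item_miss_rate = 1 - (1 - 0.283)^(1 / 68),
                          seed = 1L) {
  if (any(diff(visit_months) <= 0)) stop("visit_months must be strictly increasing")
  if (length(miss_visit_rates) != length(visit_months))
    stop("miss_visit_rates must match visit_months in length")
  if (any(miss_visit_rates < 0 | miss_visit_rates > 1) ||
      item_miss_rate < 0 || item_miss_rate > 1)
    stop("missingness rates must lie in [0, 1]")
  miss_visit_rates[1L] <- 0
  structure(list(n_participants = as.integer(n_participants),
                 visit_months = as.numeric(visit_months),
                 miss_visit_rates = as.numeric(miss_visit_rates),
                 item_miss_rate = as.numeric(item_miss_rate),
                 seed = as.integer(seed)),
            class = "mlbpsp_cohort_config")
}

# Derive a reproducible child seed < 2^31 from a root seed and a stage tag.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

#' Default 17-feature roster
#'
#' Seven neurocognitive domain deficit scores, four BDI-II subscale scores,
#' five PAOFI component scores and one IADL dependence total. All are
#' non-negative, right-skewed raw scores analysed on the square-root scale.
#'
#' @return character vector of 17 feature names.
#' @export
default_feature_roster <- function() {
  c("dds_verbal_fluency", "dds_processing_speed", "dds_learning",
    "dds_delayed_recall", "dds_executive", "dds_working_memory", "dds_motor",
    "bdi_cognitive", "bdi_somatic", "bdi_affective", "bdi_apathy",
    "paofi_memory", "paofi_language", "paofi_hands", "paofi_sensory",
    "paofi_higher_cognitive", "iadl_total")
}

# Transformed-scale trajectory coefficients for the four study-like
# archetypes. Intercepts are anchored to the baseline group means reported
# for the study phenotypes (e.g. BDI-II totals ~7.7/18/25.5/10 spread over 4
# subscales); slopes encode the qualitative courses: P1 low and stable, P2
# depressed/disabled but improving, P3 depressed/disabled and worsening,
# P4 cognitively impaired and worsening.
archetype_coef_table <- function(scale = 1) {
  roster <- default_feature_roster()
  cog  <- grep("^dds_", roster, value = TRUE)
  mood <- grep("^bdi_", roster, value = TRUE)
  fun  <- grep("^paofi_", roster, value = TRUE)
  traj <- function(cog_a, cog_b, mood_a, mood_b, fun_a, fun_b, iadl_a, iadl_b) {
    out <- c(
      stats::setNames(rep(list(c(cog_a, cog_b * scale, 0)), length(cog)), cog),
      stats::setNames(rep(list(c(mood_a, mood_b * scale, -0.02 * sign(mood_b) * scale)), length(mood)), mood),
      stats::setNames(rep(list(c(fun_a, fun_b * scale, 0)), length(fun)), fun),
      list(iadl_total = c(iadl_a, iadl_b * scale, 0)))
    out[roster]
  }
  list(
    P1 = traj(0.60, 0.00, 1.40, 0.00, 0.90, 0.00, 0.70, 0.00),
    P2 = traj(1.00, 0.00, 2.10, -0.30, 1.80, -0.30, 1.60, -0.25),
    P3 = traj(0.75, 0.00, 2.50, 0.10, 2.20, 0.10, 2.00, 0.10),
    P4 = traj(1.60, 0.25, 1.60, 0.00, 1.20, 0.00, 1.00, 0.00))
}

#' Study-like archetype set
#'
#' Four phenotypes with mixture weights 45.6/21.3/19.2/13.8\%, quadratic mean
#' trajectories on the square-root scale encoding the qualitative courses of
#' the four study phenotypes (stably healthy; depressed but improving;
#' depressed and worsening; cognitively impaired and worsening), a common
#' random-effect covariance and residual noise.
#'
#' @param separation multiplier on between-phenotype slope differences and
#'   (inverse) subject-level noise; \code{default_archetypes()} uses 1,
#'   \code{separable_archetypes()} uses a larger separation with shrunken
#'   random-effect variance so that the two-step pipeline recovers the truth.
#' @param sigma residual SD on the transformed scale.
#' @param G 3x3 random-effect covariance on the transformed scale.
#' @return list of four \code{mlbpsp_archetype} objects with weights summing
#'   to one.
#' @export
default_archetypes <- function(separation = 1,
                               sigma = 0.25,
                               G = diag(c(0.16, 0.01, 0.002))) {
  coefs <- archetype_coef_table(scale = separation)
  weights <- c(0.456, 0.213, 0.192, 0.138)
  weights[4] <- 1 - sum(weights[1:3])  # exact unit sum
  mapply(function(lab, w, tr) phenotype_archetype(lab, w, tr, G = G, sigma = sigma),
         1:4, weights, coefs, SIMPLIFY = FALSE)
}

#' @rdname default_archetypes
#' @export
separable_archetypes <- function() {
  default_archetypes(separation = 2.5,
                     sigma = 0.15,
                     G = diag(c(0.02, 0.004, 0.001)))
}

#' Simulate a longitudinal cohort
#'
#' Each participant is assigned an archetype by weighted draw; for each
#' feature a latent Gaussian quadratic trajectory is drawn on the transformed
#' scale, \code{y* = a + b t + c t^2 + b0 + b1 t + b2 t^2 + e}, with subject
#' effects \code{(b0, b1, b2) ~ N(0, G)} and \code{e ~ N(0, sigma^2)}; the
#' stored raw value is \code{pmax(y*, 0)^2}, so the pipeline's square-root
#' transform recovers approximately Gaussian structure by construction.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param archetypes list of \code{\link{phenotype_archetype}}; weights must
#'   sum to 1 within 1e-6.
#' @return a long-format \code{data.frame} of class \code{mlbpsp_panel} with
#'   columns \code{pid}, \code{visit_month}, one column per feature, and a
#'   per-participant truth label in \code{attr(, "truth")}.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            archetypes = default_archetypes()) {
  stopifnot(inherits(config, "mlbpsp_cohort_config"))
  w <- vapply(archetypes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) stop("archetype weights must sum to 1")
  features <- archetypes[[1L]]$features
  for (a in archetypes)
    if (!identical(a$features, features)) stop("archetypes must share one feature roster")

  n  <- config$n_participants
  tt <- config$visit_months / 6  # visit-unit time coding
  nv <- length(tt)
  Zt <- cbind(1, tt, tt^2)

  set.seed(child_seed(config$seed, "simulate"))
  cls <- sample.int(length(archetypes), n, replace = TRUE, prob = w)

  panel <- data.frame(
    pid = rep(sprintf("S%04d", seq_len(n)), each = nv),
    visit_month = rep(config$visit_months, times = n))
  for (f in features) panel[[f]] <- NA_real_

  for (ci in seq_along(archetypes)) {
    idx <- which(cls == ci)
    if (!length(idx)) next
    arch <- archetypes[[ci]]
    rows <- as.vector(t(outer(idx, seq_len(nv), function(i, j) (i - 1L) * nv + j)))
    for (f in features) {
      mu <- drop(Zt %*% arch$trajectories[[f]])
      b <- draw_mvn(length(idx), arch$G[[f]])           # n_i x 3
      lat <- matrix(mu, nrow = length(idx), ncol = nv, byrow = TRUE) +
        b %*% t(Zt) +
        matrix(stats::rnorm(length(idx) * nv, sd = arch$sigma[[f]]),
               nrow = length(idx))
      panel[[f]][rows] <- as.vector(t(pmax(lat, 0)^2))
    }
  }
  attr(panel, "truth") <- stats::setNames(as.integer(cls), sprintf("S%04d", seq_len(n)))
  attr(panel, "features") <- features
  class(panel) <- c("mlbpsp_panel", "data.frame")
  panel
}

# n draws from N(0, Sigma) for PSD Sigma (3x3); rank-deficient Sigma allowed.
draw_mvn <- function(n, Sigma) {
  ed <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  L <- ed$vectors %*% diag(sqrt(lam), nrow = length(lam))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(L)
}

#' Apply visit- and item-level missingness
#'
#' Whole visits are deleted independently at the per-visit configured rates
#' (baseline never deleted); remaining feature cells are deleted
#' independently at \code{item_miss_rate}. Participants left with fewer than
#' two observed visits are removed; the removal count is recorded in
#' \code{attr(, "n_dropped")}.
#'
#' @param panel a complete \code{mlbpsp_panel}.
#' @param config the \code{\link{cohort_config}} holding the rates.
#' @return the thinned panel (rows for deleted visits removed, deleted cells
#'   set to \code{NA}).
#' @export
apply_missingness <- function(panel, config) {
  stopifnot(inherits(panel, "mlbpsp_panel"), inherits(config, "mlbpsp_cohort_config"))
  features <- attr(panel, "features")
  set.seed(child_seed(config$seed, "missingness"))

  rate <- config$miss_visit_rates[match(panel$visit_month, config$visit_months)]
  rate[is.na(rate)] <- 0
  drop_visit <- stats::runif(nrow(panel)) < rate
  out <- panel[!drop_visit, , drop = FALSE]

  if (config$item_miss_rate > 0) {
    for (f in features) {
      hit <- stats::runif(nrow(out)) < config$item_miss_rate
      out[[f]][hit] <- NA_real_
    }
  }

  obs <- table(out$pid)
  keep <- names(obs)[obs >= 2L]
  n_dropped <- length(unique(panel$pid)) - length(keep)
  out <- out[out$pid %in% keep, , drop = FALSE]
  rownames(out) <- NULL

  truth <- attr(panel, "truth")
  attr(out, "truth") <- truth[names(truth) %in% keep]
  attr(out, "features") <- features
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mlbpsp_panel", "data.frame")
  out
}

#' Default baseline covariate configuration
#'
#' Phenotype-specific parameters for the simulated baseline covariate table:
#' binary comorbidity prevalences, Poisson rates for medication counts (rates
#' chosen so the Poisson medians are 1/2/2/3 concomitant non-antiretroviral
#' medications), and Normal mean/sd pairs for continuous labs and
#' demographics, anchored to the study's published group summaries.
#'
#' @return a list with elements \code{binary}, \code{counts},
#'   \code{continuous}.
#' @export
default_baseline_config <- function() {
  bin <- rbind(
    diabetes        = c(0.0736, 0.1019, 0.0928, 0.1714),
    hypertension    = c(0.1905, 0.1481, 0.1546, 0.2571),
    hyperlipidemia  = c(0.0952, 0.1389, 0.1134, 0.1143),
    cpd             = c(0.0563, 0.0833, 0.1134, 0.2000),
    dsp             = c(0.3152, 0.3875, 0.5797, 0.5714),
    lifetime_mdd    = c(0.3870, 0.5750, 0.7830, 0.4800),
    lifetime_sud    = c(0.6600, 0.7630, 0.8440, 0.6440),
    aids            = c(0.5280, 0.5740, 0.7110, 0.6710))
  colnames(bin) <- paste0("P", 1:4)
  cnt <- rbind(polypharmacy = c(1.3, 2.3, 2.3, 3.3))
  colnames(cnt) <- paste0("P", 1:4)
  cont <- list(
    education    = list(mean = c(13.5, 12.6, 12.5, 13.0), sd = c(2.42, 2.87, 2.46, 2.63)),
    hiv_duration = list(mean = c(8.82, 9.96, 10.9, 12.4), sd = c(6.41, 6.40, 6.35, 5.74)),
    hematocrit   = list(mean = c(41.66, 41.14, 40.60, 41.22), sd = c(4.36, 4.23, 4.12, 4.98)),
    creatinine   = list(mean = c(0.97, 0.95, 0.92, 0.94), sd = c(0.23, 0.27, 0.18, 0.32)),
    albumin      = list(mean = c(4.26, 4.22, 4.20, 4.22), sd = c(0.44, 0.41, 0.38, 0.51)))
  list(binary = bin, counts = cnt, continuous = cont)
}

#' Simulate phenotype-dependent baseline covariates
#'
#' @param panel an \code{mlbpsp_panel} carrying truth labels.
#' @param config the \code{\link{cohort_config}} (for the seed).
#' @param baseline a parameter list as from
#'   \code{\link{default_baseline_config}}.
#' @return a \code{data.frame} keyed by \code{pid} with one column per
#'   covariate.
#' @export
simulate_baseline_covariates <- function(panel, config,
                                         baseline = default_baseline_config()) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) stop("panel carries no truth labels")
  k <- max(truth)
  set.seed(child_seed(config$seed, "baseline"))
  out <- data.frame(pid = names(truth))
  for (v in rownames(baseline$binary)) {
    p <- baseline$binary[v, ]
    if (length(p) < k || anyNA(p[seq_len(k)]))
      stop("missing prevalence for '", v, "' in some phenotype")
    out[[v]] <- stats::rbinom(length(truth), 1L, p[truth])
  }
  for (v in rownames(baseline$counts)) {
    lam <- baseline$counts[v, ]
    if (length(lam) < k || anyNA(lam[seq_len(k)]))
      stop("missing count rate for '", v, "' in some phenotype")
    out[[v]] <- stats::rpois(length(truth), lam[truth])
  }
  for (v in names(baseline$continuous)) {
    par <- baseline$continuous[[v]]
    if (length(par$mean) < k) stop("missing distribution for '", v, "'")
    out[[v]] <- stats::rnorm(length(truth), par$mean[truth], par$sd[truth])
  }
  out
}

#' Baseline summary scores from a panel
#'
#' Aggregates the default roster's baseline-visit features into the four
#' instrument totals used for cluster severity ordering and the baseline
#' classifiers: GDS (mean of the 7 domain deficit scores), BDI-II total (sum
#' of the 4 subscales), PAOFI total (sum of the 5 components) and the IADL
#' total.
#'
#' @param panel an \code{mlbpsp_panel}.
#' @param baseline_month visit month treated as baseline (default 0).
#' @return \code{data.frame} with columns \code{pid, gds, bdi_total,
#'   paofi_total, iadl_total} (NA where baseline components are missing).
#' @export
baseline_summary_scores <- function(panel, baseline_month = 0) {
  base <- panel[panel$visit_month == baseline_month, , drop = FALSE]
  cog  <- grep("^dds_", names(base), value = TRUE)
  mood <- grep("^bdi_", names(base), value = TRUE)
  fun  <- grep("^paofi_", names(base), value = TRUE)
  data.frame(
    pid = base$pid,
    gds = rowMeans(base[, cog, drop = FALSE]),
    bdi_total = rowSums(base[, mood, drop = FALSE]),
    paofi_total = rowSums(base[, fun, drop = FALSE]),
    iadl_total = base$iadl_total)
}
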