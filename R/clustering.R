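#' Standardize and PCA-compress a random-effects matrix
#'
#' Columns are z-scored (zero-variance columns dropped with a warning), the
#' correlation structure is eigendecomposed, and the smallest number of
#' leading components whose cumulative explained variance reaches
#' \code{threshold} is retained.
#'
#' @param M numeric matrix (participants x features), no missing cells.
#' @param threshold cumulative explained-variance fraction in (0, 1]
#'   (default 0.85).
#' @return object of class \code{mlbpsp_pca}: \code{center}, \code{scale},
#'   \code{rotation}, \code{ev_fraction}, \code{m}, \code{cumvar},
#'   \code{scores} (n x m).
#' @export
standardize_and_reduce <- function(M, threshold = 0.85) {
  if (nrow(M) < 2L) stop("need at least 2 participants")
  if (anyNA(M)) stop("matrix contains missing cells")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sds <- apply(M, 2, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance column(s): ",
            paste(utils::head(colnames(M)[zero], 5L), collapse = ", "))
    M <- M[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  mu <- colMeans(M)
  Z <- scale(M, center = mu, scale = sds)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(ev) >= threshold - 1e-12)[1L]
  structure(list(center = mu, scale = sds, rotation = pc$rotation,
                 ev_fraction = ev, m = m, cumvar = cumsum(ev)[m],
                 threshold = threshold,
                 scores = pc$x[, seq_len(m), drop = FALSE]),
            class = "mlbpsp_pca")
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (j in 2:k) {
      pick <- if (all(d2 == 0)) sample.int(n, 1L)
              else sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' k-means with k-means++ restarts
#'
#' Lloyd iterations from k-means++ initial centers; \code{nstart} restarts,
#' best solution by within-cluster sum of squares. Deterministic for a given
#' seed.
#'
#' @param scores numeric matrix (n x m).
#' @param k number of clusters, \code{1 <= k <= n}.
#' @param seed integer seed.
#' @param nstart restarts (default 50).
#' @return list: \code{labels} (length n), \code{centers} (k x m),
#'   \code{wss} (total within-cluster SS).
#' @export
kmeans_fit <- function(scores, k, seed = 1L, nstart = 50L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 1L || k > n) stop("k must be in 1..n")
  set.seed(child_seed(seed, paste0("kmeans", k)))
  if (k == 1L) {
    ctr <- matrix(colMeans(scores), 1L)
    return(list(labels = rep(1L, n), centers = ctr,
                wss = sum(sweep(scores, 2, ctr[1L, ])^2)))
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- kmeanspp_centers(scores, k)
    km <- suppressWarnings(stats::kmeans(scores, centers = init,
                                         iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(labels = as.integer(best$cluster), centers = best$centers,
       wss = best$tot.withinss)
}

#' Within-cluster sum-of-squares curve
#'
#' @inheritParams kmeans_fit
#' @param k_max largest k evaluated (default 9).
#' @return numeric vector \code{wss[1..k_max]}.
#' @export
wss_curve <- function(scores, k_max = 9L, seed = 1L, nstart = 50L) {
  vapply(seq_len(k_max),
         function(k) kmeans_fit(scores, k, seed = seed, nstart = nstart)$wss,
         numeric(1))
}

#' Elbow selection of k
#'
#' Selects the k whose point on the (k, WSS) curve lies farthest (by
#' perpendicular distance) from the chord joining the first and last points;
#' ties break toward smaller k. The curve is made non-increasing by a running
#' minimum before selection.
#'
#' @param wss numeric WSS values for k = 1..k_max (k_max >= 3).
#' @return selected k (integer).
#' @export
elbow_select_k <- function(wss) {
  k_max <- length(wss)
  if (k_max < 3L) stop("elbow selection needs k_max >= 3")
  w <- cummin(wss)
  k <- seq_len(k_max)
  # |cross product| of (point - chord start) with the chord direction
  dx <- k_max - 1
  dy <- w[k_max] - w[1L]
  dist <- abs((k - 1) * dy - (w - w[1L]) * dx) / sqrt(dx^2 + dy^2)
  which.max(dist > max(dist) - 1e-12)  # first k attaining the maximum
}

#' Severity-order cluster labels
#'
#' Relabels clusters 1..k in ascending severity, where a cluster's severity
#' is the mean of z-scored baseline summary scores (default GDS, BDI-II
#' total, PAOFI total, IADL total; higher = worse) over its members. Ties
#' break by cluster size (descending), then original label.
#'
#' @param labels integer cluster labels (named by pid, or in panel pid order).
#' @param panel the \code{mlbpsp_panel} providing baseline features.
#' @param ordering_features columns of
#'   \code{\link{baseline_summary_scores}} output used for severity.
#' @return list: \code{labels} (relabelled, named by pid), \code{severity}
#'   (per new label), \code{map} (old -> new).
#' @export
order_clusters <- function(labels, panel,
                           ordering_features = c("gds", "bdi_total",
                                                 "paofi_total", "iadl_total")) {
  pids <- names(labels)
  if (is.null(pids)) stop("labels must be named by pid")
  if (any(tabulate(labels, nbins = max(labels)) == 0L))
    stop("empty cluster in labelling")
  scores <- baseline_summary_scores(panel)
  scores <- scores[match(pids, scores$pid), ordering_features, drop = FALSE]
  sm <- as.matrix(scores)
  mu <- colMeans(sm, na.rm = TRUE)
  sd_ <- apply(sm, 2, stats::sd, na.rm = TRUE)
  sd_[sd_ < .Machine$double.eps^0.5] <- 1
  z <- sweep(sweep(sm, 2, mu), 2, sd_, "/")
  sev_i <- rowMeans(z, na.rm = TRUE)
  k <- max(labels)
  sev <- vapply(seq_len(k), function(c) mean(sev_i[labels == c], na.rm = TRUE),
                numeric(1))
  size <- tabulate(labels, nbins = k)
  ord <- order(sev, -size, seq_len(k))
  map <- integer(k); map[ord] <- seq_len(k)
  list(labels = stats::setNames(map[labels], pids),
       severity = sev[ord], map = map)
}

#' Agreement between two clusterings
#'
#' Builds the confusion matrix over the common ids, finds the one-to-one
#' label matching maximizing total overlap (assignment problem), and reports
#' the matched agreement fraction plus the adjusted Rand index.
#'
#' @param labels_a,labels_b integer labels named by id.
#' @param common_ids ids to compare on (default: intersection of names).
#' @return list: \code{agreement}, \code{ari}, \code{confusion} (rows = a,
#'   columns = b, columns permuted to the matching), \code{matching}.
#' @export
cluster_agreement <- function(labels_a, labels_b,
                              common_ids = intersect(names(labels_a), names(labels_b))) {
  if (!length(common_ids)) stop("no common ids between labelings")
  a <- labels_a[common_ids]; b <- labels_b[common_ids]
  C <- table(factor(a), factor(b))
  sq <- max(dim(C))
  Cp <- matrix(0, sq, sq)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  m <- as.integer(clue::solve_LSAP(Cp, maximum = TRUE))
  agreement <- sum(Cp[cbind(seq_len(sq), m)]) / length(common_ids)
  list(agreement = agreement, ari = adjusted_rand_index(a, b),
       confusion = C, matching = m[seq_len(nrow(C))])
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency-table closed form.
#'
#' @param a,b label vectors over the same items.
#' @return numeric ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Two-step phenotype clustering
#'
#' Step two of the pipeline: standardize + reduce the random-effects matrix,
#' compute the WSS curve, select k by the elbow (or force it), fit the final
#' k-means, and severity-order the labels against baseline scores.
#'
#' @param M random-effects matrix (\code{\link{extract_random_effects}}).
#' @param panel the panel used for severity ordering.
#' @param threshold PCA cumulative-variance threshold (default 0.85).
#' @param k_max largest k scanned (default 9).
#' @param k optional forced cluster count (bypasses elbow selection).
#' @param seed integer seed for the k-means restarts.
#' @return object of class \code{mlbpsp_clusters}: \code{labels} (named,
#'   severity-ordered), \code{k}, \code{rationale} ("elbow" or "forced"),
#'   \code{wss}, \code{pca}, \code{centers}, \code{severity}.
#' @export
cluster_phenotypes <- function(M, panel, threshold = 0.85, k_max = 9L,
                               k = NULL, seed = 1L) {
  pca <- standardize_and_reduce(M, threshold)
  wss <- wss_curve(pca$scores, k_max = k_max, seed = seed)
  if (is.null(k)) {
    k_sel <- elbow_select_k(wss); rationale <- "elbow"
  } else {
    k_sel <- as.integer(k); rationale <- "forced"
  }
  km <- kmeans_fit(pca$scores, k_sel, seed = seed)
  raw <- stats::setNames(km$labels, rownames(M))
  ord <- order_clusters(raw, panel)
  structure(list(labels = ord$labels, k = k_sel, rationale = rationale,
                 wss = wss, pca = pca, centers = km$centers,
                 severity = ord$severity, seed = seed),
            class = "mlbpsp_clusters")
}
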