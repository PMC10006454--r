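#' k-means clustering of the neuron rate table
#'
#' Lloyd iterations (via [stats::kmeans()]) on the normalized rate table,
#' best of `n_restarts` random starts by the quadratic objective
#' `J(C) = sum_k sum_{i in C_k} ||f_i - mu_k||^2`.  If a start collapses to
#' an empty cluster the start is re-seeded (up to `max_reseed` fresh
#' attempts), which is the documented empty-cluster policy.
#'
#' @param t A `spikecog_rate_table` or plain numeric matrix (rows =
#'   neurons).  Rate tables are clustered on their max-normalized entries.
#' @param k Number of clusters, `1 <= k <= N`.
#' @param n_restarts Random restarts (default 10).
#' @param max_reseed Extra attempts when a start produces an empty cluster.
#' @return A `spikecog_partition`: `labels` (per-neuron cluster id),
#'   `centroids` `[k x ncol]`, `J` (the objective), `sizes`.
#' @export
kmeans_cluster <- function(t, k, n_restarts = 10, max_reseed = 20) {
  x <- if (inherits(t, "spikecog_rate_table")) t$K_norm else as.matrix(t)
  stopifnot(k >= 1, k <= nrow(x))
  fit <- NULL
  for (attempt in seq_len(max_reseed)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, nstart = n_restarts,
                                     iter.max = 100, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed: persistent empty clusters")
  structure(list(labels = unname(fit$cluster), centroids = fit$centers,
                 J = fit$tot.withinss, sizes = unname(fit$size), k = k),
            class = "spikecog_partition")
}

#' Ward agglomerative clustering of the rate table
#'
#' Agglomerative merging by the minimal increase in within-cluster sum of
#' squares, `R(A, B) = ESS(A u B) - ESS(A) - ESS(B)` (via
#' [stats::hclust()] with Ward linkage; the reported merge heights are
#' converted to `R`).  `axis = "tasks"` clusters the task axis instead,
#' using per-task trial-averaged rates, producing the task dendrogram.
#'
#' @param t A `spikecog_rate_table` or numeric matrix (rows = items).
#' @param axis `"neurons"` (rows of the normalized table) or `"tasks"`.
#' @return A `spikecog_linkage`: `merge` (hclust merge matrix), `R`
#'   (non-decreasing Ward merge costs), `order`, `labels`, `hclust` (the
#'   underlying object, heights on the hclust scale).
#' @export
ward_linkage <- function(t, axis = c("neurons", "tasks")) {
  axis <- match.arg(axis)
  if (inherits(t, "spikecog_rate_table")) {
    x <- t$K_norm
    if (axis == "tasks") {
      # average the trial columns within each task, then cluster tasks
      grp <- rep(t$tasks, each = t$n_trials)
      x <- sapply(t$tasks, function(tk)
        rowMeans(x[, grp == tk, drop = FALSE]))
      x <- base::t(x)
      rownames(x) <- t$tasks
    }
  } else {
    x <- as.matrix(t)
  }
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(merge = hc$merge, R = hc$height^2 / 2, order = hc$order,
                 labels = rownames(x), hclust = hc),
            class = "spikecog_linkage")
}

#' Lesion or isolate a neuron cluster
#'
#' Weight convention: with `I_j = sum_k W[j, k] z_k`, the outgoing weights
#' of neuron c are column c of `W_rec` and of `W_out`.  `"lesion"` zeroes
#' the cluster neurons' outgoing entries in both matrices, silencing their
#' influence.  `"isolate"` keeps only the cluster's readout columns nonzero
#' and zeroes the recurrent links into the cluster from non-cluster
#' neurons, so only that cluster drives the output.  The input weights are
#' untouched in both modes.  A modified copy is returned; the original
#' weights are never written.
#'
#' @param w A `spikecog_weights`.
#' @param part A `spikecog_partition` (or integer label vector).
#' @param cluster Cluster id present in the partition.
#' @param mode `"lesion"` or `"isolate"`.
#' @return A new `spikecog_weights`.
#' @export
lesion <- function(w, part, cluster, mode = c("lesion", "isolate")) {
  mode <- match.arg(mode)
  labels <- if (inherits(part, "spikecog_partition")) part$labels else part
  stopifnot(length(labels) == nrow(w$W_rec))
  if (!(cluster %in% labels)) stop("unknown cluster: ", cluster)
  idx <- which(labels == cluster)
  if (mode == "lesion") {
    w$W_rec[, idx] <- 0
    w$W_out[, idx] <- 0
  } else {
    w$W_out[, -idx] <- 0
    w$W_rec[idx, setdiff(seq_len(ncol(w$W_rec)), idx)] <- 0
  }
  diag(w$W_rec) <- 0
  w
}

#' Cluster lesioning / isolation screen
#'
#' For every cluster of the partition and every task, evaluates the network
#' with that cluster lesioned (top half of the screen) and with only that
#' cluster active (bottom half), averaging over `n_trials` test trials per
#' cell, alongside the unlesioned baseline.
#'
#' @param w A `spikecog_weights` (trained network).
#' @param part A `spikecog_partition`.
#' @param tasks Task names.
#' @param n_trials Test trials per (cluster, task) cell (default 200).
#' @param p,sigma,kappa,dt,seed As in [evaluate()].
#' @return A `spikecog_lesion_screen`: matrices `lesion` and `isolate`
#'   `[n_clusters x n_tasks]` of accuracies, `baseline` (length
#'   `n_tasks`), `clusters`, `tasks`.
#' @export
lesion_screen <- function(w, part, tasks = spikecog_tasks(),
                          n_trials = 200,
                          p = neuron_params(nrow(w$W_rec)),
                          sigma = 0.05, kappa = exp(-1 / 2), dt = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clusters <- sort(unique(part$labels))
  acc <- function(ww) {
    rep_ <- evaluate(ww, p, tasks, n_trials = n_trials, sigma = sigma,
                     kappa = kappa, dt = dt, protocol = "per_task")
    rep_$per_task
  }
  les <- t(vapply(clusters, function(cl)
    acc(lesion(w, part, cl, "lesion")), numeric(length(tasks))))
  iso <- t(vapply(clusters, function(cl)
    acc(lesion(w, part, cl, "isolate")), numeric(length(tasks))))
  dimnames(les) <- dimnames(iso) <- list(paste0("cluster", clusters), tasks)
  structure(list(lesion = les, isolate = iso, baseline = acc(w),
                 clusters = clusters, tasks = tasks, n_trials = n_trials),
            class = "spikecog_lesion_screen")
}

#' Choose the number of clusters by silhouette
#'
#' The cluster count is not fixed by the protocol; the default picks the k
#' in `k_range` maximizing the mean silhouette width of the k-means
#' partition of the rate table.
#'
#' @param t A `spikecog_rate_table` or matrix.
#' @param k_range Candidate cluster counts (default 2:20, truncated to
#'   N - 1).
#' @param n_restarts Restarts per k.
#' @return List with `k` (the chosen count), `silhouette` (named vector of
#'   mean widths).
#' @export
select_k_silhouette <- function(t, k_range = 2:20, n_restarts = 10) {
  x <- if (inherits(t, "spikecog_rate_table")) t$K_norm else as.matrix(t)
  k_range <- k_range[k_range < nrow(x) & k_range >= 2]
  if (length(k_range) == 0L) stop("no feasible k in range")
  d <- as.matrix(stats::dist(x))
  sil_mean <- vapply(k_range, function(k) {
    part <- kmeans_cluster(x, k, n_restarts)
    lab <- part$labels
    s <- vapply(seq_len(nrow(x)), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
        mean(d[i, lab == cl]), 1.0))
      if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }, 1.0)
    mean(s)
  }, 1.0)
  names(sil_mean) <- k_range
  list(k = k_range[which.max(sil_mean)], silhouette = sil_mean)
}
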