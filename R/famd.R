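# Factor analysis of mixed data (FAMD) with hierarchical clustering on
# the retained components, k-means consolidation and V-test cluster
# characterisation.

#' Encode a mixed housing table for FAMD
#'
#' Quantitative columns are centred and scaled by the population (1/n)
#' standard deviation. Each category of a qualitative variable becomes an
#' indicator column divided by the square root of the category proportion
#' and then centred (the MCA weighting), so both blocks contribute on a
#' comparable scale: a quantitative column and a two-category qualitative
#' variable each carry total inertia of order one.
#'
#' @param data Data.frame; numeric columns are treated as quantitative,
#'   character/factor columns as qualitative. Non-variable columns (ids)
#'   should be excluded beforehand or named in `id_cols`.
#' @param id_cols Columns to drop before encoding (default `"farm_id"`
#'   and `"region"`-like identifiers if present).
#' @return List of class `famd_matrix`: `X` (encoded matrix, rows named
#'   by id), `meta` (per encoded column: variable, category, type,
#'   category proportion).
#' @export
famd_encode <- function(data, id_cols = intersect(c("farm_id", "region", "archetype"),
                                                  names(data))) {
  if (nrow(data) < 2) stop("at least two rows are required")
  ids <- if ("farm_id" %in% names(data)) data$farm_id else rownames(data)
  vars <- data[, setdiff(names(data), id_cols), drop = FALSE]
  n <- nrow(vars)
  cols <- list()
  meta <- list()
  for (v in names(vars)) {
    x <- vars[[v]]
    if (is.numeric(x)) {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) stop("constant quantitative column: ", v)
      cols[[v]] <- (x - mean(x)) / s
      meta[[v]] <- data.frame(variable = v, category = NA_character_,
                              type = "quantitative", proportion = NA_real_)
    } else {
      x <- as.character(x)
      lev <- sort(unique(x))
      if (length(lev) < 2)
        stop("qualitative variable with a single observed category: ", v)
      for (l in lev) {
        p <- mean(x == l)
        nm <- paste(v, l, sep = "=")
        cols[[nm]] <- ((x == l) - p) / sqrt(p)
        meta[[nm]] <- data.frame(variable = v, category = l,
                                 type = "qualitative", proportion = p)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  structure(list(X = X, meta = do.call(rbind, meta)), class = "famd_matrix")
}

#' Singular value decomposition of an encoded mixed-data matrix
#'
#' Eigenvalues are squared singular values divided by n; row scores are
#' `U %*% D` so that retaining all components reconstructs the encoded
#' matrix exactly as `scores %*% t(loadings)`.
#'
#' @param enc A `famd_matrix` from [famd_encode()].
#' @return List: `eigenvalues`, `explained` (proportions summing to 1),
#'   `scores` (rows x components), `loadings` (encoded columns x
#'   components), `enc`.
#' @export
famd_decompose <- function(enc) {
  stopifnot(inherits(enc, "famd_matrix"))
  X <- enc$X
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  eig <- d^2 / nrow(X)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  rownames(scores) <- rownames(X)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(X)
  list(eigenvalues = eig, explained = eig / sum(eig),
       scores = scores, loadings = loadings, enc = enc)
}

#' Number of components to retain for a cumulative-variance threshold
#'
#' @param explained Explained-variance proportions (must sum to 1).
#' @param threshold Cumulative share to reach, in (0, 1]; default 0.70.
#' @return Smallest m whose cumulative share is at least the threshold.
#' @export
retain_components <- function(explained, threshold = 0.70) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (abs(sum(explained) - 1) > 1e-6)
    stop("explained proportions must sum to 1")
  which(cumsum(explained) >= threshold - 1e-12)[1L]
}

# Total within-cluster inertia of points given integer labels.
.within_inertia <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    xs <- X[idx, , drop = FALSE]
    ctr <- colMeans(xs)
    sum(sweep(xs, 2, ctr)^2)
  }, numeric(1)))
}

#' Ward clustering of retained component scores with a suggested cut
#'
#' Ward linkage (squared-Euclidean implementation, `ward.D2`) on the
#' Euclidean distances of the first `m` component scores. The suggested
#' number of clusters maximises the relative inertia gain between
#' successive cuts, `(W(k-1) - W(k)) / (W(k) - W(k+1))`, over the
#' candidate range: a large ratio means cutting to k clusters removes
#' much within-cluster inertia while the next split removes little.
#'
#' @param scores Component-score matrix.
#' @param m Number of leading components to use.
#' @param k_range Candidate cluster counts (default 2:10).
#' @return List: `dendrogram` (an `hclust`), `suggested_k`, `inertia`
#'   (W(k) for the evaluated cuts), `scores_used`.
#' @export
hcluster_ward <- function(scores, m, k_range = 2:10) {
  if (nrow(scores) < 2) stop("at least two rows are required")
  stopifnot(m >= 1, m <= ncol(scores))
  X <- scores[, seq_len(m), drop = FALSE]
  if (all(stats::dist(X) < 1e-12)) {
    warning("all points identical; suggested_k = 1")
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    return(list(dendrogram = hc, suggested_k = 1L,
                inertia = NULL, scores_used = X))
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(X) - 1]
  ks <- seq(1, min(max(k_range) + 1, nrow(X)))
  W <- vapply(ks, function(k) .within_inertia(X, stats::cutree(hc, k)), numeric(1))
  names(W) <- ks
  gain <- -diff(W)                        # gain[k-1] = W(k-1) - W(k)
  ratio <- vapply(k_range, function(k) {
    num <- gain[k - 1]
    den <- if (k < length(W)) gain[k] else NA_real_
    if (is.na(den)) return(NA_real_)
    if (den <= 1e-12) return(if (num > 1e-12) Inf else NA_real_)
    num / den
  }, numeric(1))
  suggested <- k_range[which.max(ratio)]
  list(dendrogram = hc, suggested_k = as.integer(suggested),
       inertia = W, scores_used = X)
}

#' Consolidate a hierarchical cut with deterministic k-means
#'
#' Lloyd iterations started from the centroids of the hierarchical-cut
#' clusters, so the stage is reproducible without random restarts. Runs
#' until the assignment reaches a fixed point or 100 iterations. If a
#' cluster empties during iteration its centroid is re-seeded at the
#' point farthest from its assigned centroid.
#'
#' @param scores Component-score matrix.
#' @param m Number of leading components to use.
#' @param k Number of clusters (2 <= k <= n).
#' @param init Initial integer labels (default: Ward cut at k from
#'   [hcluster_ward()]).
#' @return List: `labels` (integer vector named by row), `centroids`,
#'   `inertia`, `iterations`.
#' @export
kmeans_consolidate <- function(scores, m, k, init = NULL) {
  X <- scores[, seq_len(m), drop = FALSE]
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (is.null(init)) {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    init <- stats::cutree(hc, k)
  }
  stopifnot(length(init) == n, length(unique(init)) == k)
  labels <- as.integer(factor(init))
  centroids <- t(vapply(split(seq_len(n), labels),
                        function(idx) colMeans(X[idx, , drop = FALSE]),
                        numeric(ncol(X))))
  for (iter in seq_len(100)) {
    d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") - 2 * X %*% t(centroids)
    new_labels <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(new_labels))
    for (e in empty) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      centroids[e, ] <- X[far, ]
      new_labels[far] <- e
    }
    if (identical(new_labels, labels) && !length(empty)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
    centroids <- t(vapply(split(seq_len(n), factor(labels, levels = seq_len(k))),
                          function(idx) colMeans(X[idx, , drop = FALSE]),
                          numeric(ncol(X))))
  }
  names(labels) <- rownames(X)
  list(labels = labels, centroids = centroids,
       inertia = .within_inertia(X, labels), iterations = iter)
}

#' V-test characterisation of clusters on a quantitative variable
#'
#' For each cluster, compares the cluster mean with the overall mean:
#' \deqn{v = (\bar x_k - \bar x) / \sqrt{\frac{N - n_k}{N - 1} s^2 / n_k}}
#' with s the population standard deviation over all N observations
#' (the sampling sd of a mean of n_k values drawn without replacement).
#' Two-sided p from the standard normal.
#'
#' @param labels Cluster labels.
#' @param x Quantitative variable (same length).
#' @return Data.frame: cluster, n, group mean and (population) sd,
#'   overall mean and sd, v, p. With zero overall variance v and p are NA.
#' @export
vtest_quantitative <- function(labels, x) {
  stopifnot(length(labels) == length(x))
  N <- length(x)
  xbar <- mean(x)
  s2 <- mean((x - xbar)^2)
  out <- lapply(split(x, labels), function(xk) {
    nk <- length(xk)
    if (s2 == 0) {
      v <- NA_real_; p <- NA_real_
    } else {
      v <- (mean(xk) - xbar) / sqrt((N - nk) / (N - 1) * s2 / nk)
      p <- 2 * stats::pnorm(-abs(v))
    }
    data.frame(n = nk, group_mean = mean(xk),
               group_sd = sqrt(mean((xk - mean(xk))^2)),
               overall_mean = xbar, overall_sd = sqrt(s2), v = v, p = p)
  })
  res <- do.call(rbind, out)
  res <- cbind(cluster = names(out), res)
  rownames(res) <- NULL
  res
}

#' V-test characterisation of clusters on a qualitative category
#'
#' The count of the category inside a cluster follows a hypergeometric
#' law under random assignment (drawing the cluster's n_k farms from the
#' N, of which K carry the category). p is twice the hypergeometric tail
#' in the direction of the deviation (capped at 1); v is the signed
#' standard-normal quantile of that tail, positive when the category is
#' over-represented in the cluster.
#'
#' @param labels Cluster labels.
#' @param f Qualitative variable (character/factor, same length).
#' @param category Category of `f` to test.
#' @return Data.frame: cluster, n, group %, overall %, v, p.
#' @export
vtest_categorical <- function(labels, f, category) {
  f <- as.character(f)
  stopifnot(length(labels) == length(f))
  if (!category %in% f) stop("category not present in data: ", category)
  N <- length(f)
  K <- sum(f == category)
  out <- lapply(split(f, labels), function(fk) {
    nk <- length(fk)
    x <- sum(fk == category)
    over <- x / nk >= K / N
    tail <- if (over) {
      stats::phyper(x - 1, K, N - K, nk, lower.tail = FALSE)
    } else {
      stats::phyper(x, K, N - K, nk)
    }
    v <- if (over) stats::qnorm(tail, lower.tail = FALSE) else stats::qnorm(tail)
    data.frame(n = nk, group_pct = 100 * x / nk, overall_pct = 100 * K / N,
               v = v, p = min(1, 2 * tail))
  })
  res <- do.call(rbind, out)
  res <- cbind(cluster = names(out), category = category, res)
  rownames(res) <- NULL
  res
}

#' Housing-design clustering: FAMD, Ward cut, k-means, V-tests
#'
#' End-to-end wrapper over [famd_encode()], [famd_decompose()],
#' [retain_components()], [hcluster_ward()], [kmeans_consolidate()] and
#' the V-tests. Constant columns (no information for the decomposition)
#' are dropped with a warning rather than erroring, so the wrapper is
#' robust on small generated tables.
#'
#' @param farms Housing table (see [generate_farms()]).
#' @param variance_threshold Cumulative explained-variance threshold for
#'   component retention (default 0.70).
#' @param k Number of clusters; default `NULL` uses the suggested cut.
#' @param k_range Candidate k values for the suggestion rule.
#' @param id_cols Identifier columns excluded from the analysis.
#' @return List of class `shed_hcpc`: the decomposition, retained m,
#'   dendrogram, suggested and final k, labels, and the V-test table
#'   (quantitative and categorical rows with `p < 0.05` flagged).
#' @export
cluster_housing <- function(farms, variance_threshold = 0.70, k = NULL,
                            k_range = 2:10,
                            id_cols = intersect(c("farm_id", "region", "altitude",
                                                  "latitude_class", "archetype"),
                                                names(farms))) {
  vars <- farms[, setdiff(names(farms), id_cols), drop = FALSE]
  constant <- vapply(vars, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    warning("dropping constant columns: ",
            paste(names(vars)[constant], collapse = ", "))
    vars <- vars[, !constant, drop = FALSE]
  }
  if ("farm_id" %in% names(farms)) vars$farm_id <- farms$farm_id
  enc <- famd_encode(vars)
  dec <- famd_decompose(enc)
  m <- retain_components(dec$explained, variance_threshold)
  hw <- hcluster_ward(dec$scores, m, k_range)
  final_k <- if (is.null(k)) hw$suggested_k else k
  if (final_k < 2) stop("fewer than 2 clusters; nothing to consolidate")
  km <- kmeans_consolidate(dec$scores, m,
                           k = final_k,
                           init = stats::cutree(hw$dendrogram, final_k))
  labels <- km$labels
  vt_q <- list()
  vt_c <- list()
  for (v in setdiff(names(vars), "farm_id")) {
    if (is.numeric(vars[[v]])) {
      tab <- vtest_quantitative(labels, vars[[v]])
      tab <- cbind(variable = v, tab)
      vt_q[[v]] <- tab
    } else {
      for (cat in sort(unique(as.character(vars[[v]])))) {
        tab <- vtest_categorical(labels, vars[[v]], cat)
        tab <- cbind(variable = v, tab)
        vt_c[[paste(v, cat)]] <- tab
      }
    }
  }
  structure(list(
    decomposition = dec, m = m,
    explained = dec$explained,
    dendrogram = hw$dendrogram, suggested_k = hw$suggested_k,
    k = final_k, labels = labels, inertia = km$inertia,
    vtest_quantitative = do.call(rbind, c(vt_q, list(make.row.names = FALSE))),
    vtest_categorical = do.call(rbind, c(vt_c, list(make.row.names = FALSE)))
  ), class = "shed_hcpc")
}

#' @export
print.shed_hcpc <- function(x, ...) {
  cat("Housing-design clustering (FAMD + Ward + k-means)\n")
  cat(sprintf("  components retained: %d (%.1f%% of variance)\n",
              x$m, 100 * sum(x$explained[seq_len(x$m)])))
  cat(sprintf("  suggested k: %d; final k: %d\n", x$suggested_k, x$k))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}
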