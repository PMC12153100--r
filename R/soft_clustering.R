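# Soft clustering of standardized expression time courses: fuzzy c-means
# with seeded restarts, plus Calinski-Harabasz cluster-number selection over
# hard k-means fits. The fuzzy c-means and CH computations are implemented
# here; select_k delegates the per-k hard fits to stats::kmeans.

#' Remove genes not expressed at any stage
#'
#' @param matrix An [expression_matrix()].
#' @return List with `matrix` (rows with all-zero profiles removed) and
#'   `removed_count`.
#' @export
filter_unexpressed <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  keep <- rowSums(matrix != 0) > 0
  if (!any(keep)) stop("all genes are unexpressed; nothing to cluster")
  removed <- sum(!keep)
  if (removed > 0) devhet_log("filter_unexpressed: removed %d all-zero gene(s)", removed)
  list(matrix = matrix[keep, , drop = FALSE], removed_count = removed)
}

#' Standardize expression profiles gene-wise
#'
#' Each row is centred to mean 0 and scaled to standard deviation 1
#' (denominator n - 1, the mfuzz convention). Zero-variance rows become
#' all-zero with a warning.
#'
#' @param matrix An [expression_matrix()] (filter all-zero rows first).
#' @return A standardized [expression_matrix()]. Values may be negative.
#' @export
standardize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  m <- unclass(matrix)
  mu <- rowMeans(m)
  centred <- m - mu
  sdv <- sqrt(rowSums(centred^2) / (ncol(m) - 1L))
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s) set to all-zero: ",
            paste(utils::head(rownames(m)[flat], 5L), collapse = ", "))
    sdv[flat] <- 1
  }
  out <- centred / sdv
  out[flat, ] <- 0
  # standardized profiles are signed; bypass the non-negative constructor
  structure(out, species_id = species_id(matrix),
            class = c("ExpressionMatrix", class(out)))
}

# Squared Euclidean distances between rows of x (n x p) and rows of v (k x p).
sq_dist <- function(x, v) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
  d2[d2 < 0] <- 0
  d2
}

# Fuzzy membership update: u_ic = 1 / sum_j (d_ic / d_ij)^(2/(m-1)).
# Rows coincident with a centroid get membership 1 for (the first) such
# centroid.
fcm_memberships <- function(d2, m) {
  eps <- .Machine$double.eps
  zero <- d2 < eps
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  hit <- which(rowSums(zero) > 0)
  if (length(hit)) {
    u[hit, ] <- 0
    u[cbind(hit, max.col(zero[hit, , drop = FALSE], ties.method = "first"))] <- 1
  }
  u
}

fcm_single <- function(x, v, m, tol, max_iter) {
  u <- fcm_memberships(sq_dist(x, v), m)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    um <- u^m
    v <- (t(um) %*% x) / colSums(um)
    d2 <- sq_dist(x, v)
    u_new <- fcm_memberships(d2, m)
    trace[it] <- sum(u_new^m * d2)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(u = u, v = v, trace = trace, converged = converged)
}

#' Fuzzy c-means clustering of standardized profiles
#'
#' Alternating optimisation of the fuzzy c-means objective
#' `J = sum_ic u_ic^m ||x_i - v_c||^2`: centroids
#' `v_c = sum_i u_ic^m x_i / sum_i u_ic^m`, memberships
#' `u_ic = 1 / sum_j (d_ic / d_ij)^(2/(m-1))` with Euclidean distance.
#' Iteration stops when the maximum membership change falls below `tol` or
#' at `max_iter` (then `converged` is `FALSE`). Centroids are initialised by
#' sampling `k` distinct gene profiles; `restarts` seeded restarts keep the
#' fit with the lowest final objective.
#'
#' @param matrix Standardized [expression_matrix()] (see [standardize()]).
#' @param k Number of clusters, `2 <= k < n_genes`.
#' @param m Fuzzifier, `> 1`. Larger values give fuzzier memberships;
#'   `m -> 1` approaches hard k-means. Default 1.25, usual practice for
#'   standardized time-course data; see also [estimate_fuzzifier()].
#' @param tol Convergence tolerance on the max membership change.
#' @param max_iter Maximum iterations per restart.
#' @param restarts Number of random restarts.
#' @param seed Integer seed (set once before all restarts).
#' @param centers Optional initial centroid matrix (k x stages); when given,
#'   a single deterministic fit is run from it.
#' @return A `SoftClustering` list: `k`, `m`, `memberships` (genes x k, rows
#'   sum to 1), `centroids` (k x stages), `hard_labels` (argmax membership,
#'   ties to the lowest cluster index), `objective_trace` (non-increasing),
#'   `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(matrix, k, m = 1.25, tol = 1e-6, max_iter = 1000,
                         restarts = 10, seed = NULL, centers = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  x <- unclass(matrix)
  n <- nrow(x)
  if (k < 2 || k >= n) stop("'k' must satisfy 2 <= k < n_genes")
  if (m <= 1) stop("fuzzifier 'm' must exceed 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  devhet_log("fuzzy_cmeans: n=%d, k=%d, m=%.3g, restarts=%d", n, k, m,
             if (is.null(centers)) restarts else 1L)
  fits <- list()
  if (!is.null(centers)) {
    stopifnot(nrow(centers) == k, ncol(centers) == ncol(x))
    fits[[1L]] <- fcm_single(x, centers, m, tol, max_iter)
  } else {
    uniq <- x[!duplicated(x), , drop = FALSE]
    if (nrow(uniq) < k) stop("fewer than k distinct profiles to initialise from")
    xbar <- colMeans(x)
    for (r in seq_len(restarts)) {
      v0 <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
      # shrink 1% toward the grand mean: a centroid starting exactly on a
      # gene locks that gene at membership 1 for large m
      v0 <- 0.99 * v0 + 0.01 * matrix(xbar, k, ncol(x), byrow = TRUE)
      fits[[r]] <- fcm_single(x, v0, m, tol, max_iter)
    }
  }
  best <- fits[[which.min(vapply(fits, function(f) utils::tail(f$trace, 1L),
                                 numeric(1)))]]
  u <- best$u
  rownames(u) <- rownames(x)
  colnames(best$v) <- colnames(x)
  structure(list(
    k = as.integer(k), m = m,
    memberships = u,
    centroids = best$v,
    hard_labels = stats::setNames(max.col(u, ties.method = "first"), rownames(x)),
    objective_trace = best$trace,
    converged = best$converged,
    seed = seed
  ), class = "SoftClustering")
}

#' @export
print.SoftClustering <- function(x, ...) {
  cat(sprintf("SoftClustering: %d genes, k = %d, m = %.3g, %sconverged (%d iterations)\n",
              nrow(x$memberships), x$k, x$m,
              if (x$converged) "" else "NOT ", length(x$objective_trace)))
  cat("cluster sizes (hard):", as.integer(table(factor(x$hard_labels, levels = seq_len(x$k)))), "\n")
  invisible(x)
}

#' Data-driven fuzzifier estimate
#'
#' Dimension-and-size heuristic for the fuzzifier of standardized expression
#' data (Schwaemmle-Jensen style): `m = 1 + (1418/n + 22.05) * p^-2 +
#' (12.33/n + 0.243) * p^(-0.0406 * log(n) - 0.1134)` for n genes and p
#' stages.
#'
#' @param matrix Standardized [expression_matrix()].
#' @return Estimated fuzzifier (> 1).
#' @export
estimate_fuzzifier <- function(matrix) {
  n <- nrow(matrix)
  p <- ncol(matrix)
  1 + (1418 / n + 22.05) * p^(-2) +
    (12.33 / n + 0.243) * p^(-0.0406 * log(n) - 0.1134)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion normalised by degrees of
#' freedom: `CH = (B / (k - 1)) / (W / (n - k))` with
#' `B = sum_c n_c ||v_c - xbar||^2` and
#' `W = sum_c sum_{i in c} ||x_i - v_c||^2` over cluster means `v_c`.
#' When every cluster is internally constant (`W = 0`) the index returns
#' `Inf` as a degenerate-perfect-separation sentinel.
#'
#' @param matrix Numeric matrix or [expression_matrix()] (rows = items).
#' @param labels Integer/factor vector of hard cluster labels, >= 2
#'   non-empty clusters.
#' @return The CH score (possibly `Inf`).
#' @export
calinski_harabasz <- function(matrix, labels) {
  x <- unclass(matrix)
  if (!is.matrix(x)) x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  if (length(labels) != n) stop("one label per row required")
  k <- length(unique(labels))
  if (k < 2) stop("need >= 2 non-empty clusters")
  if (k >= n) stop("need k < n")
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c, , drop = FALSE]
    vc <- colMeans(xc)
    B <- B + nrow(xc) * sum((vc - grand)^2)
    W <- W + sum(sweep(xc, 2, vc)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters with the Calinski-Harabasz index
#'
#' For each candidate k a seeded hard k-means fit ([stats::kmeans()] with
#' `nstart` restarts) is scored with [calinski_harabasz()]; the chosen k
#' maximises the score, ties broken to the smaller k. The final soft
#' clustering is then fit once at the chosen k by the caller (see
#' [cluster_timecourse()]).
#'
#' @param matrix Standardized [expression_matrix()].
#' @param k_range Integer vector of candidate cluster counts.
#' @param seed Integer seed.
#' @param nstart Restarts per k-means fit.
#' @param method `"kmeans"` (default) scores hard k-means fits per k;
#'   `"fcm"` scores hardened fuzzy c-means fits instead.
#' @param m Fuzzifier, used only for `method = "fcm"`.
#' @return A `KSelection` list: `k_values`, `ch_scores`, `chosen_k`.
#' @export
select_k <- function(matrix, k_range, seed = 1, nstart = 10,
                     method = c("kmeans", "fcm"), m = 1.25) {
  method <- match.arg(method)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("'k_range' must be non-empty")
  x <- unclass(matrix)
  if (any(k_range < 2L) || any(k_range >= nrow(x))) {
    stop("'k_range' must lie within [2, n_genes - 1]")
  }
  set.seed(as.integer(seed))
  scores <- vapply(k_range, function(k) {
    labels <- if (method == "kmeans") {
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)$cluster
    } else {
      fuzzy_cmeans(matrix, k, m = m, restarts = nstart)$hard_labels
    }
    if (length(unique(labels)) < 2L) return(-Inf)
    calinski_harabasz(x, labels)
  }, numeric(1))
  chosen <- k_range[which.max(scores)]  # which.max takes the first (smallest k) on ties
  structure(list(k_values = k_range, ch_scores = scores,
                 chosen_k = as.integer(chosen)),
            class = "KSelection")
}

#' @export
print.KSelection <- function(x, ...) {
  cat("KSelection: chosen k =", x$chosen_k, "\n")
  print(data.frame(k = x$k_values, CH = signif(x$ch_scores, 6)), row.names = FALSE)
  invisible(x)
}

#' Filter, standardize, select k and fit the soft clustering in one call
#'
#' Convenience wrapper reproducing the full clustering procedure: drop
#' all-zero genes, standardize, pick k over `k_range` with
#' [select_k()], then fit [fuzzy_cmeans()] once at the chosen k.
#'
#' @param matrix Raw (non-negative) [expression_matrix()].
#' @param k_range Candidate cluster counts; a single value skips selection.
#' @param m Fuzzifier.
#' @param seed Integer seed.
#' @param ... Passed to [fuzzy_cmeans()].
#' @return List with `clustering` (`SoftClustering`), `kselection`
#'   (`KSelection` or `NULL`), `standardized`, `removed_count`.
#' @export
cluster_timecourse <- function(matrix, k_range, m = 1.25, seed = 1, ...) {
  filt <- filter_unexpressed(matrix)
  std <- standardize(filt$matrix)
  ks <- NULL
  if (length(k_range) > 1L) {
    ks <- select_k(std, k_range, seed = seed)
    k <- ks$chosen_k
  } else {
    k <- as.integer(k_range)
  }
  cl <- fuzzy_cmeans(std, k, m = m, seed = seed, ...)
  list(clustering = cl, kselection = ks, standardized = std,
       removed_count = filt$removed_count)
}
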