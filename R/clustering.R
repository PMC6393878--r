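# Intensity clustering engines: hard k-means and fuzzy c-means (FCM).
#
# Both operate on the flattened in-brain pixel intensities. The FCM
# alternation minimizes the fuzzified within-cluster objective
#   J_m = sum_i sum_j u_ij^m (x_i - c_j)^2,  m > 1,
# with the standard center update (weighted mean with weights u_ij^m) and
# membership update u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)). The objective
# is non-increasing across iterations, which is asserted after every run.

.init_centers <- function(pixels, k, init = c("spaced", "quantile", "random"),
                          seed = NULL) {
  init <- match.arg(init)
  rng <- range(pixels)
  ctrs <- switch(init,
    spaced = rng[1] + diff(rng) * seq_len(k) / (k + 1),
    quantile = as.numeric(quantile(pixels, seq_len(k) / (k + 1), type = 7)),
    random = {
      if (!is.null(seed)) set.seed(seed)
      sort(runif(k, rng[1], rng[2]))
    })
  if (anyDuplicated(ctrs)) {
    # degenerate (e.g. quantile init on a dominant mode): fall back to the
    # deterministic equally-spaced rule
    ctrs <- rng[1] + diff(rng) * seq_len(k) / (k + 1)
  }
  ctrs
}

.new_cluster_model <- function(pixels, centers, memberships, fuzziness,
                               objective_history, method, iterations,
                               converged, notes = character()) {
  structure(list(pixels = pixels, centers = centers,
                 memberships = memberships,
                 distances = abs(outer(pixels, centers, "-")),
                 fuzziness = fuzziness,
                 objective_history = objective_history,
                 method = method, iterations = iterations,
                 converged = converged, notes = notes),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s: N = %d pixels, c = %d, %d iterations%s\n",
              x$method, length(x$pixels), length(x$centers), x$iterations,
              if (isTRUE(x$converged)) " (converged)" else ""))
  cat("  centers:", paste(sprintf("%.4f", x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Assign pixels to their nearest centers
#'
#' Hard assignment by minimal absolute intensity distance (the 1-D Euclidean
#' distance); ties break toward the lower center index.
#'
#' @param pixels numeric vector of intensities.
#' @param centers numeric vector of distinct cluster centers.
#' @return Integer vector of labels in `1..length(centers)`.
#' @export
kmeans_assign <- function(pixels, centers) {
  if (length(pixels) == 0L) stop("empty pixel set")
  if (anyDuplicated(centers)) stop("centers must be distinct")
  d <- abs(outer(pixels, centers, "-"))
  max.col(-d, ties.method = "first")
}

#' Recompute k-means centers
#'
#' Each center becomes the mean of its assigned pixels; a cluster with no
#' members keeps its previous center.
#'
#' @param pixels numeric vector.
#' @param labels integer labels in `1..k`.
#' @param k number of clusters.
#' @param centers previous centers (required to carry empty clusters).
#' @return Numeric vector of k centers.
#' @export
kmeans_update <- function(pixels, labels, k, centers = NULL) {
  if (is.null(centers)) centers <- rep(NA_real_, k)
  means <- vapply(seq_len(k), function(j) {
    sel <- labels == j
    if (any(sel)) mean(pixels[sel]) else centers[j]
  }, numeric(1))
  means
}

#' Hard k-means clustering of pixel intensities
#'
#' Alternates [kmeans_assign()] and [kmeans_update()] from a deterministic
#' initialization until the maximal center shift drops below `tol` or
#' `max_iter` is reached. The within-cluster sum of squared distances is
#' recorded per iteration and is non-increasing.
#'
#' @param pixels numeric vector of intensities.
#' @param k number of clusters (`>= 2`); reduced with a warning if it exceeds
#'   the number of distinct intensities.
#' @param tol convergence tolerance on the center shift.
#' @param max_iter iteration cap.
#' @param init initialization rule, see [fcm_cluster()].
#' @param seed optional seed for `init = "random"`.
#' @param init_centers optional explicit initial centers (overrides `init`).
#' @return A `cluster_model` with hard (0/1) memberships.
#' @export
kmeans_cluster <- function(pixels, k, tol = 1e-6, max_iter = 100L,
                           init = "spaced", seed = NULL,
                           init_centers = NULL) {
  if (length(pixels) == 0L) stop("empty pixel set")
  if (k < 2L) stop("k must be >= 2")
  notes <- character()
  ndist <- length(unique(pixels))
  if (k > ndist) {
    warning(sprintf("k = %d exceeds %d distinct intensities; reduced", k, ndist))
    notes <- c(notes, sprintf("k reduced from %d to %d", k, ndist))
    k <- ndist
  }
  centers <- init_centers %||% .init_centers(pixels, k, init, seed)
  if (anyDuplicated(centers)) centers <- centers + seq_along(centers) * 1e-9
  obj <- numeric(0)
  labels <- kmeans_assign(pixels, centers)
  for (iter in seq_len(max_iter)) {
    new_centers <- kmeans_update(pixels, labels, k, centers)
    labels <- kmeans_assign(pixels, new_centers)
    obj <- c(obj, sum((pixels - new_centers[labels])^2))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  u <- matrix(0, length(pixels), k)
  u[cbind(seq_along(pixels), labels)] <- 1
  .new_cluster_model(pixels, centers, u, fuzziness = NA_real_,
                     objective_history = obj, method = "kmeans",
                     iterations = iter, converged = shift < tol,
                     notes = notes)
}

#' Fuzzy c-means membership update
#'
#' Row-stochastic membership matrix
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))` with `d_ij = |x_i - c_j|`.
#' A pixel at zero distance from one or more centers receives membership
#' split equally over those centers and 0 elsewhere. Computed via ratios to
#' the per-pixel minimal distance, which is overflow-safe for any `m > 1`.
#'
#' @param pixels numeric vector.
#' @param centers numeric vector of distinct centers.
#' @param m fuzziness exponent, `> 1`.
#' @return `length(pixels) x length(centers)` membership matrix.
#' @export
fcm_memberships <- function(pixels, centers, m) {
  if (m <= 1) stop("fuzziness m must be > 1")
  if (anyDuplicated(centers)) stop("centers must be distinct")
  d <- abs(outer(pixels, centers, "-"))
  zero <- d < 1e-12
  anyzero <- rowSums(zero) > 0
  dmin <- d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
  w <- (dmin / d)^(2 / (m - 1))
  u <- w / rowSums(w)
  if (any(anyzero)) {
    u[anyzero, ] <- zero[anyzero, , drop = FALSE] /
      rowSums(zero[anyzero, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means center update
#'
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`. A cluster whose weight column is
#' all zero keeps its previous center (recorded in the model notes when run
#' inside [fcm_cluster()]).
#'
#' @param pixels numeric vector.
#' @param memberships row-stochastic membership matrix.
#' @param m fuzziness exponent.
#' @param centers previous centers, used for empty columns.
#' @return Numeric vector of centers.
#' @export
fcm_centers <- function(pixels, memberships, m, centers = NULL) {
  w <- memberships^m
  den <- colSums(w)
  num <- as.vector(crossprod(w, pixels))
  out <- num / den
  if (any(den == 0)) {
    if (is.null(centers)) stop("all-zero membership column and no previous centers")
    out[den == 0] <- centers[den == 0]
  }
  out
}

#' Fuzzy c-means objective J_m
#'
#' `J_m = sum_i sum_j u_ij^m (x_i - c_j)^2`, evaluated on a `cluster_model`
#' or on explicit components.
#'
#' @param model a `cluster_model`, or a list with `pixels`, `centers`,
#'   `memberships`, `fuzziness`.
#' @return Non-negative scalar.
#' @export
fcm_objective <- function(model) {
  .fcm_J(model$pixels, model$centers, model$memberships, model$fuzziness)
}

.fcm_J <- function(pixels, centers, memberships, m) {
  d2 <- outer(pixels, centers, "-")^2
  sum(memberships^m * d2)
}

#' Fuzzy c-means clustering of pixel intensities
#'
#' Alternates [fcm_centers()] and [fcm_memberships()] from deterministic
#' initial centers until the maximal absolute membership change drops below
#' `tol` or `max_iter` is reached. The objective history is recorded per
#' iteration and is non-increasing (asserted).
#'
#' The default initialization is deterministic: centers equally spaced over
#' the observed intensity range (`"spaced"`). `"quantile"` starts at the
#' `j/(c+1)` intensity percentiles (25th/50th/75th for `c = 3`), falling
#' back to the spaced rule when quantiles coincide; it can stall in a
#' degenerate optimum when one tissue dominates the histogram (see the
#' methods vignette for the measured comparison). `"random"` draws uniform
#' centers under `seed` for robustness studies.
#'
#' @param pixels numeric vector of intensities.
#' @param c number of clusters (`>= 2`).
#' @param m fuzziness exponent (`> 1`), default 2.
#' @param tol convergence tolerance on memberships, default `1e-5`.
#' @param max_iter iteration cap, default 100.
#' @param init `"spaced"`, `"quantile"`, or `"random"`.
#' @param seed optional seed for random initialization.
#' @param init_centers optional explicit initial centers (overrides `init`).
#' @return A `cluster_model`.
#' @export
fcm_cluster <- function(pixels, c = 3L, m = 2, tol = 1e-5, max_iter = 100L,
                        init = "spaced", seed = NULL, init_centers = NULL) {
  if (length(pixels) == 0L) stop("empty pixel set")
  if (c < 2L) stop("c must be >= 2")
  if (m <= 1) stop("fuzziness m must be > 1")
  notes <- character()
  centers <- init_centers %||% .init_centers(pixels, c, init, seed)
  if (anyDuplicated(centers)) centers <- centers + seq_along(centers) * 1e-9
  u <- fcm_memberships(pixels, centers, m)
  obj <- numeric(0)
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    new_centers <- fcm_centers(pixels, u, m, centers)
    if (anyDuplicated(new_centers)) {
      notes <- c(notes, "coincident centers separated by jitter")
      new_centers <- new_centers + seq_along(new_centers) * 1e-12
    }
    u_new <- fcm_memberships(pixels, new_centers, m)
    obj <- c(obj, .fcm_J(pixels, new_centers, u_new, m))
    delta <- max(abs(u_new - u))
    u <- u_new
    centers <- new_centers
    if (delta < tol) break
  }
  if (length(obj) > 1L && any(diff(obj) > 1e-9 * pmax(1, obj[-length(obj)])))
    warning("FCM objective increased across iterations")
  .new_cluster_model(pixels, centers, u, fuzziness = m,
                     objective_history = obj, method = "fcm",
                     iterations = iter, converged = delta < tol,
                     notes = notes)
}

#' Map clusters to tissue classes by center intensity
#'
#' Clusters are sorted by center intensity. In `gm_wm` mode (3 clusters over
#' skull-stripped pixels) the lowest center is CSF, the middle gray matter
#' and the highest white matter, following the T1-weighted ordering. In
#' `tumor` mode the highest center is the tumor candidate (lower clusters
#' are named by the same ordering where possible).
#'
#' @param model a converged `cluster_model`.
#' @param mode `"gm_wm"` or `"tumor"`.
#' @return Named integer vector mapping tissue name to cluster index.
#' @export
assign_tissue_labels <- function(model, mode = c("gm_wm", "tumor")) {
  mode <- match.arg(mode)
  ctrs <- model$centers
  if (min(diff(sort(ctrs))) < 1e-8 ||
      (mode == "gm_wm" && length(ctrs) != 3L))
    .stop_neuroseg("degenerate clustering: need 3 distinct centers",
                   "neuroseg_degenerate_error")
  ord <- order(ctrs)
  if (mode == "gm_wm") {
    out <- ord
    names(out) <- c("csf", "gm", "wm")
  } else {
    if (length(ctrs) < 2L)
      .stop_neuroseg("degenerate clustering: need >= 2 distinct centers",
                     "neuroseg_degenerate_error")
    nm <- if (length(ctrs) == 4L) c("csf", "gm", "wm", "tumor") else
      c(paste0("class", seq_len(length(ctrs) - 1L)), "tumor")
    out <- ord
    names(out) <- nm
  }
  out
}

# crisp per-cluster labels from a model (row-wise argmax, ties to the lower
# cluster index)
.crisp_labels <- function(model) {
  max.col(model$memberships, ties.method = "first")
}
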