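#' Dice similarity coefficient
#'
#' Standard Sorensen-Dice overlap `2 |A n B| / (|A| + |B|)` between two
#' binary masks of identical dimensions. Symmetric; 1 for identical nonempty
#' masks, 0 for disjoint ones. Comparing two empty masks is undefined and
#' raises an error.
#'
#' @param a,b logical matrices of the same dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    .stop_neuroseg("mask dimensions differ", "neuroseg_shape_error")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L)
    .stop_neuroseg("Dice undefined for two empty masks",
                   "neuroseg_undefined_measure_error")
  2 * sum(a & b) / (sa + sb)
}

#' Dice report against one or more reference mask sets
#'
#' Computes one Dice value per (automatic set, reference set, tissue) pair,
#' plus a `total` tissue defined as the union of the gray- and white-matter
#' masks on each side ("total cortical matter"). Per-tissue summaries report
#' mean, standard deviation and the five-number summary with
#' linear-interpolation (type-7) quartiles.
#'
#' @param auto a named list of tissue masks (e.g. `list(gm =, wm =)`), or a
#'   named list of such sets.
#' @param references a list of reference mask sets, each a named list of
#'   tissue masks aligned with `auto`.
#' @return An object of class `dice_report`: list with `pairs` (data frame
#'   `auto_id`, `ref_id`, `tissue`, `dice`) and `summary` (one row per
#'   tissue: `n_pairs`, `mean`, `sd`, `min`, `q1`, `median`, `q3`, `max`).
#' @export
dice_report <- function(auto, references) {
  if (all(vapply(auto, is.matrix, logical(1)))) auto <- list(auto = auto)
  if (all(vapply(references, is.matrix, logical(1))))
    references <- list(references)
  if (is.null(names(auto))) names(auto) <- paste0("auto", seq_along(auto))
  if (is.null(names(references)) || any(names(references) == ""))
    names(references) <- paste0("ref", seq_along(references))
  add_total <- function(set) {
    if (all(c("gm", "wm") %in% names(set)))
      set$total <- set$gm | set$wm
    set
  }
  auto <- lapply(auto, add_total)
  references <- lapply(references, add_total)
  rows <- list()
  for (ai in names(auto)) {
    for (ri in names(references)) {
      tissues <- intersect(names(auto[[ai]]), names(references[[ri]]))
      for (tis in tissues) {
        rows[[length(rows) + 1L]] <- data.frame(
          auto_id = ai, ref_id = ri, tissue = tis,
          dice = dice(auto[[ai]][[tis]], references[[ri]][[tis]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(pairs$dice, pairs$tissue), function(v) {
    q <- as.numeric(quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7))
    data.frame(n_pairs = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  summ <- cbind(tissue = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(pairs = pairs, summary = summ), class = "dice_report")
}

#' @export
print.dice_report <- function(x, digits = 4, ...) {
  cat("<dice_report>\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Compare segmentation engines on a phantom batch
#'
#' Structural twin of a method-comparison table: for each engine variant the
#' corresponding pipeline is run on every phantom and the mean Dice against
#' ground truth is tabulated per tissue (gm, wm, and their union as total
#' cortical matter).
#'
#' Variants:
#' \describe{
#'   \item{`kmeans`}{raw k-means on the full slice (no skull stripping, no
#'     component postprocessing), one extra cluster for the background;
#'     tissue labels by center order (background, CSF, GM, WM).}
#'   \item{`fcm`}{skull stripping + fuzzy c-means, crisp masks without
#'     component postprocessing.}
#'   \item{`full`}{the complete proposed pipeline ([segment_gm_wm()]).}
#' }
#'
#' @param phantoms list of phantoms from [make_phantom()].
#' @param engines character vector, subset of `c("kmeans", "fcm", "full")`.
#' @param params a [segment_params()] list used by the stripped variants.
#' @return Data frame with columns `engine`, `tissue`, `mean_dice`, `n`;
#'   per-phantom values in `attr(, "pairs")`.
#' @export
compare_methods <- function(phantoms, engines = c("kmeans", "fcm", "full"),
                            params = segment_params()) {
  stopifnot(length(phantoms) >= 1L)
  engines <- match.arg(engines, several.ok = TRUE)
  rows <- list()
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    truth <- list(gm = ph$truth$gm_mask, wm = ph$truth$wm_mask,
                  total = ph$truth$gm_mask | ph$truth$wm_mask)
    for (eng in engines) {
      masks <- .run_engine(ph$slice, eng, params)
      for (tis in c("gm", "wm", "total")) {
        rows[[length(rows) + 1L]] <- data.frame(
          engine = eng, phantom = i, tissue = tis,
          dice = dice(masks[[tis]], truth[[tis]]), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  agg <- aggregate(dice ~ engine + tissue, data = pairs, FUN = mean)
  names(agg)[names(agg) == "dice"] <- "mean_dice"
  agg$n <- length(phantoms)
  agg <- agg[order(match(agg$engine, engines),
                   match(agg$tissue, c("gm", "wm", "total"))), ]
  rownames(agg) <- NULL
  attr(agg, "pairs") <- pairs
  agg
}

.run_engine <- function(slice, engine, params) {
  norm <- normalize_slice(slice)
  if (engine == "full") {
    res <- segment_gm_wm(slice, params)
    return(list(gm = res$gm_mask, wm = res$wm_mask,
                total = res$gm_mask | res$wm_mask))
  }
  if (engine == "fcm") {
    strip <- strip_skull(slice, params$threshold_method,
                         params$threshold_level, params$strip_margin)
    x <- strip$slice$pixels[strip$brain_mask]
    model <- fcm_cluster(x, c = params$clusters, m = params$fuzziness,
                         tol = params$tol, max_iter = params$max_iter,
                         init = params$init)
    tissues <- assign_tissue_labels(model, "gm_wm")
    crisp <- .crisp_labels(model)
    mk <- function(name) {
      m <- matrix(FALSE, nrow(norm$pixels), ncol(norm$pixels))
      m[strip$brain_mask][crisp == tissues[[name]]] <- TRUE
      m
    }
    gm <- mk("gm"); wm <- mk("wm")
    return(list(gm = gm, wm = wm, total = gm | wm))
  }
  # raw k-means: full slice, background gets its own cluster, no pre/post
  x <- as.vector(norm$pixels)
  model <- kmeans_cluster(x, k = params$clusters + 1L, tol = params$tol,
                          max_iter = params$max_iter, init = params$init)
  ord <- order(model$centers)  # background, csf, gm, wm by intensity
  lab <- .crisp_labels(model)
  mk <- function(which_idx) {
    matrix(lab == which_idx, nrow(norm$pixels), ncol(norm$pixels))
  }
  k <- length(model$centers)
  gm <- mk(ord[k - 1L]); wm <- mk(ord[k])
  list(gm = gm, wm = wm, total = gm | wm)
}
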