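#' Cluster cycle-averaged motor primitives
#'
#' k-means (Hartigan–Wong) on the primitives for every candidate cluster
#' count in `k_range`; each count is run with `n_init` random centroid
#' initializations and the solution minimizing the within-cluster variance
#' is kept. Counts exceeding the number of distinct primitives are skipped.
#'
#' @param mean_primitives numeric matrix, one primitive per row (synergies
#'   on the 200-point grid).
#' @param k_range candidate cluster counts (default 1:11).
#' @param n_init random initializations per count (default 20).
#' @param seed integer seed.
#' @return list with `k_range`, `within_var` (total within-cluster sum of
#'   squares per count), and `labels_by_k` (list of label vectors).
#' @export
cluster_primitives <- function(mean_primitives, k_range = 1:11,
                               n_init = 20L, seed = 1L) {
  X <- as.matrix(mean_primitives)
  if (nrow(X) < 2L) stop("need at least 2 primitives to cluster")
  n_distinct <- nrow(unique(X))
  k_range <- k_range[k_range >= 1L & k_range <= n_distinct]
  if (!length(k_range)) stop("no feasible cluster count")
  with_seed(seed, {
    fits <- lapply(k_range, function(k) {
      robust_kmeans(X, k, n_init)
    })
  })
  list(k_range = k_range,
       within_var = vapply(fits, `[[`, numeric(1), "tot.withinss"),
       labels_by_k = lapply(fits, `[[`, "cluster"))
}

#' Select the number of clusters from a variance curve
#'
#' Applies the same iterative linearity pruning used for the number of
#' synergies ([select_rank()]) to the within-cluster-variance versus
#' cluster-count curve: fit a simple linear regression, stop when its MSE
#' drops below the threshold, otherwise drop the lowest count and refit;
#' the lowest count of the surviving linear section is returned. The
#' variance curve is first normalized by its maximum so that, like the
#' R^2 curve in rank selection, it lives on a unit scale on which the MSE
#' threshold is meaningful.
#'
#' @param clustering result of [cluster_primitives()] (or any list with
#'   `k_range` and `within_var`).
#' @param mse_threshold linearity threshold (default `1e-4`).
#' @return selected cluster count (integer).
#' @export
select_n_clusters <- function(clustering, mse_threshold = 1e-4) {
  k <- clustering$k_range
  v <- clustering$within_var
  if (length(k) == 1L || max(v) <= 0) return(as.integer(min(k)))
  as.integer(prune_linear_section(k, v / max(v), mse_threshold))
}

#' Cluster motor modules with an imposed cluster count
#'
#' Best-of-`n_init` k-means (Hartigan–Wong) on the module weight vectors,
#' imposing the cluster count previously selected on the primitives.
#'
#' @param modules numeric matrix, one module per row (synergies x muscles).
#' @param k_imposed cluster count from the primitive clustering.
#' @param n_init random initializations (default 20).
#' @param seed integer seed.
#' @return integer label vector.
#' @export
cluster_modules <- function(modules, k_imposed, n_init = 20L, seed = 1L) {
  X <- as.matrix(modules)
  if (k_imposed > nrow(unique(X))) {
    stop("more clusters than distinct modules")
  }
  with_seed(seed, {
    robust_kmeans(X, k_imposed, n_init)$cluster
  })
}

# k-means wrapper hardened for small or degenerate inputs:
# * stats::kmeans() refuses k == nrow(x); that solution is trivial
#   (each row its own cluster, zero within-variance), so build it directly
#   (callers cap k at the number of *distinct* rows first);
# * Hartigan-Wong's Quick-TRANSFER stage can fail to converge on
#   near-duplicate rows; retry those counts with MacQueen, which always
#   terminates, instead of surfacing the warning;
# * random center sampling can draw duplicate rows and error; retry with
#   the first k distinct rows as explicit centers.
robust_kmeans <- function(X, k, n_init, iter.max = 100L) {
  if (k >= nrow(X)) {
    return(list(cluster = seq_len(nrow(X)), tot.withinss = 0))
  }
  out <- NULL
  hw_warned <- FALSE
  tryCatch(
    withCallingHandlers(
      out <- kmeans(X, centers = k, nstart = n_init, iter.max = iter.max,
                    algorithm = "Hartigan-Wong"),
      warning = function(w) {
        hw_warned <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (hw_warned || is.null(out)) {
    out <- tryCatch(
      suppressWarnings(kmeans(X, centers = k, nstart = n_init,
                              iter.max = iter.max,
                              algorithm = "MacQueen")),
      error = function(e) {
        kmeans(X, centers = unique(X)[seq_len(k), , drop = FALSE],
               iter.max = iter.max, algorithm = "MacQueen")
      })
  }
  out
}

# greedy maximal-overlap matching between two labelings: returns a named
# map primitive-cluster -> module-cluster
match_clusters <- function(a, b) {
  tab <- table(a, b)
  map <- integer(0)
  while (length(tab) && nrow(tab) && ncol(tab) && max(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    map[rownames(tab)[ij[1L]]] <- as.integer(colnames(tab)[ij[2L]])
    tab <- tab[-ij[1L], -ij[2L], drop = FALSE]
  }
  map
}

#' Concordance of the two clusterings and functional labels
#'
#' Clusters of the primitive and module labelings are matched by maximal
#' membership overlap. A synergy whose module cluster agrees with its
#' matched primitive cluster is fundamental; discordant synergies are
#' combined (linear mixtures of simpler synergies) and carry no functional
#' label. Fundamental clusters are named in ascending order of their mean
#' center of activity — braking (first half of stance), push-off, early
#' flight, late flight. The per-synergy score `(FWHM + CoA-in-points)/200`
#' is reported as a diagnostic.
#'
#' @param primitive_labels,module_labels integer label vectors over the
#'   same synergies.
#' @param coa center of activity in degrees per synergy.
#' @param fwhm FWHM in points per synergy.
#' @param bimodal optional logical bimodality flags (default all FALSE).
#' @param n_points cycle grid size (default 200).
#' @return data.frame of class `"synergy_classification"` with columns
#'   `synergy`, `primitive_cluster`, `module_cluster`, `fundamental`,
#'   `label`, `score`, `bimodal`.
#' @export
concordance_and_label <- function(primitive_labels, module_labels, coa,
                                  fwhm, bimodal = NULL, n_points = 200L) {
  n <- length(primitive_labels)
  if (length(module_labels) != n || length(coa) != n || length(fwhm) != n) {
    stop("label and metric vectors must cover the same synergies")
  }
  if (is.null(bimodal)) bimodal <- rep(FALSE, n)
  map <- match_clusters(primitive_labels, module_labels)
  fundamental <- map[as.character(primitive_labels)] == module_labels
  fundamental[is.na(fundamental)] <- FALSE
  score <- (fwhm + coa / 360 * n_points) / n_points

  # name fundamental clusters by ascending mean CoA
  archetypes <- c("braking", "push-off", "early flight", "late flight")
  label <- rep(NA_character_, n)
  fclust <- unique(primitive_labels[fundamental])
  if (length(fclust)) {
    mean_coa <- vapply(fclust, function(cl) {
      mean(coa[fundamental & primitive_labels == cl])
    }, numeric(1))
    ord <- fclust[order(mean_coa)]
    nm <- if (length(ord) <= length(archetypes)) {
      archetypes[seq_along(ord)]
    } else {
      c(archetypes, paste0("S", seq.int(5L, length(ord))))
    }
    for (i in seq_along(ord)) {
      label[fundamental & primitive_labels == ord[i]] <- nm[i]
    }
  }
  label[!fundamental] <- "combined"
  structure(
    data.frame(synergy = seq_len(n), primitive_cluster = primitive_labels,
               module_cluster = module_labels, fundamental = fundamental,
               label = label, score = score, bimodal = bimodal),
    class = c("synergy_classification", "data.frame"))
}

#' Functionally classify the synergies of one or more fitted models
#'
#' Pools the cycle-averaged primitives and modules of the supplied fits,
#' clusters the primitives over `k_range` with cluster-count selection,
#' clusters the modules with the imposed count, and labels each synergy as
#' a fundamental type or combined.
#'
#' @param fits a `"synergy_fit"` or list of them (e.g. one per
#'   participant).
#' @param k_range candidate cluster counts (default 1:11).
#' @param n_init k-means restarts (default 20).
#' @param seed integer seed.
#' @return a `"synergy_classification"` data.frame with an extra column
#'   `fit` giving the index of the originating fit, and attribute
#'   `n_clusters`.
#' @export
classify_synergies <- function(fits, k_range = 1:11, n_init = 20L,
                               seed = 1L) {
  if (inherits(fits, "synergy_fit")) fits <- list(fits)
  P <- do.call(rbind, lapply(fits, mean_primitives))
  M <- do.call(rbind, lapply(fits, function(f) t(f$W)))
  metr <- do.call(rbind, lapply(fits, primitive_metrics))
  origin <- rep(seq_along(fits), vapply(fits, `[[`, integer(1), "rank"))
  cp <- cluster_primitives(P, k_range = k_range, n_init = n_init,
                           seed = derive_seed(seed, 301L))
  k <- select_n_clusters(cp)
  plab <- cp$labels_by_k[[match(k, cp$k_range)]]
  mlab <- cluster_modules(M, k_imposed = k, n_init = n_init,
                          seed = derive_seed(seed, 302L))
  out <- concordance_and_label(plab, mlab, coa = metr$coa_deg,
                               fwhm = metr$fwhm_points,
                               bimodal = metr$bimodal)
  out$fit <- origin
  attr(out, "n_clusters") <- k
  out
}
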