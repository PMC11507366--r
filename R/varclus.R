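#' Divisive variable clustering with first-principal-component scores
#'
#' Partitions the columns (wavelength variables) of a data matrix into `k`
#' clusters and summarizes each cluster by the first principal component of
#' its standardized members ("cluster component"). This is the dimensionality
#' reduction feeding the SVM in the VC-SVM hybrid model.
#'
#' The procedure works on the correlation matrix. Starting from a single
#' cluster, it repeatedly splits the cluster whose correlation submatrix has
#' the largest second eigenvalue: the first two principal-component loadings
#' of that cluster are rotated by a raw quartimax rotation and each variable
#' is assigned to the rotated component with which it correlates more strongly
#' in absolute value. Once `k` clusters exist, nearest-component reassignment
#' passes move each variable to the cluster component with which its squared
#' correlation is highest, refitting components after every pass, until no
#' variable moves or `max_passes` is reached (then a warning is issued).
#'
#' Eigenvector signs are fixed so the largest-magnitude loading is positive,
#' making scores reproducible across linear-algebra backends. When two
#' clusters tie on the second eigenvalue (within `tol`), the one containing
#' the smallest variable index is split.
#'
#' @param x Numeric matrix (n samples x p variables), `n >= 3`, no constant
#'   column.
#' @param k Number of clusters, `1 <= k <= p`. Default 6, the setting used for
#'   the milk spectra.
#' @param max_passes Maximum number of reassignment passes.
#' @param tol Numerical tolerance for eigenvalue ties.
#' @return An object of class `"varclus"`: a list with elements `k`,
#'   `assignment` (integer cluster id per variable), `clusters` (list of
#'   variable indices), `loadings` (per-cluster unit vectors), `col_means`,
#'   `col_sds`, `cluster_eigen1`, `variance_explained`, `p`, `n`.
#' @seealso [predict.varclus()] for cluster scores,
#'   [variance_explained()], [write_varclus()].
#' @export
varclus <- function(x, k = 6L, max_passes = 25L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n < 3L)
    stop_ls("need at least 3 rows to cluster variables",
            class = "lactospec_argument_error")
  k <- as.integer(k)
  if (k < 1L || k > p)
    stop_ls("`k` must satisfy 1 <= k <= ncol(x) = ", p,
            class = "lactospec_argument_error")
  col_means <- colMeans(x)
  col_sds <- apply(x, 2, stats::sd)
  if (any(col_sds <= 0)) {
    bad <- which(col_sds <= 0)[1]
    stop_ls("variable ", colnames(x)[bad] %||% bad,
            " is constant; drop it before clustering",
            class = "lactospec_degenerate_error")
  }
  Z <- scale(x, center = col_means, scale = col_sds)
  R <- stats::cor(x)

  second_eig <- function(idx) {
    if (length(idx) < 2L) return(0)
    eigen(R[idx, idx], symmetric = TRUE, only.values = TRUE)$values[2]
  }

  clusters <- list(seq_len(p))
  while (length(clusters) < k) {
    e2 <- vapply(clusters, function(cl)
      if (length(cl) < 2L) -Inf else second_eig(cl), numeric(1))
    best <- max(e2)
    cand <- which(e2 >= best - tol)
    # tie-break: split the cluster containing the smallest variable index
    pick <- cand[which.min(vapply(clusters[cand], min, numeric(1)))]
    halves <- split_cluster(R, clusters[[pick]])
    clusters <- c(clusters[-pick], halves)
  }

  fit_loading <- function(idx) {
    if (length(idx) == 1L) return(1)
    v <- eigen(R[idx, idx], symmetric = TRUE)$vectors[, 1]
    fix_sign(v)
  }
  loadings <- lapply(clusters, fit_loading)

  if (k > 1L) {
    pass <- 0L
    repeat {
      pass <- pass + 1L
      scores <- mapply(function(idx, w) Z[, idx, drop = FALSE] %*% w,
                       clusters, loadings)
      assignment <- integer(p)
      for (c_i in seq_along(clusters)) assignment[clusters[[c_i]]] <- c_i
      moved <- FALSE
      for (j in seq_len(p)) {
        r2 <- as.numeric(stats::cor(Z[, j], scores))^2
        tgt <- which.max(r2)
        src <- assignment[j]
        if (tgt != src && r2[tgt] > r2[src] + tol &&
            length(clusters[[src]]) > 1L) {
          clusters[[src]] <- setdiff(clusters[[src]], j)
          clusters[[tgt]] <- sort(c(clusters[[tgt]], j))
          assignment[j] <- tgt
          moved <- TRUE
        }
      }
      if (moved) loadings <- lapply(clusters, fit_loading)
      if (!moved) break
      if (pass >= max_passes) {
        warning("variable reassignment did not converge in ", max_passes,
                " passes; returning the current partition")
        break
      }
    }
  }

  # canonical cluster order: by smallest member index
  ord <- order(vapply(clusters, min, numeric(1)))
  clusters <- clusters[ord]
  loadings <- lapply(clusters, fit_loading)
  assignment <- integer(p)
  for (c_i in seq_along(clusters)) assignment[clusters[[c_i]]] <- c_i
  eigen1 <- vapply(clusters, function(idx) {
    if (length(idx) == 1L) 1
    else eigen(R[idx, idx], symmetric = TRUE, only.values = TRUE)$values[1]
  }, numeric(1))
  names(assignment) <- colnames(x)
  structure(list(k = k, assignment = assignment, clusters = clusters,
                 loadings = loadings, col_means = col_means,
                 col_sds = col_sds, cluster_eigen1 = eigen1,
                 variance_explained = sum(eigen1) / p, p = p, n = n,
                 var_names = colnames(x)),
            class = "varclus")
}

fix_sign <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

# split one cluster: quartimax-rotate the first two PC loadings and assign
# each variable to the rotated component it correlates with more strongly
split_cluster <- function(R, idx) {
  e <- eigen(R[idx, idx], symmetric = TRUE)
  lam <- pmax(e$values[1:2], 0)
  L <- e$vectors[, 1:2] %*% diag(sqrt(lam))   # PC loadings = correlations
  th <- quartimax_angle(L)
  G <- rotation2(th)
  Lr <- L %*% G
  first <- abs(Lr[, 1]) >= abs(Lr[, 2])
  # guard: an empty half cannot occur for a genuinely 2-dimensional cluster,
  # but protect against degenerate ties
  if (all(first)) first[which.max(abs(Lr[, 2]))] <- FALSE
  if (!any(first)) first[which.max(abs(Lr[, 1]))] <- TRUE
  list(sort(idx[first]), sort(idx[!first]))
}

rotation2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# raw quartimax criterion for a two-column loading matrix: maximize the sum of
# fourth powers over planar rotations (period pi/2); coarse grid + refinement
quartimax_angle <- function(L) {
  crit <- function(th) sum((L %*% rotation2(th))^4)
  grid <- seq(0, pi / 2, length.out = 181L)
  vals <- vapply(grid, crit, numeric(1))
  th0 <- grid[which.max(vals)]
  opt <- stats::optimize(crit, lower = th0 - 0.02, upper = th0 + 0.02,
                         maximum = TRUE)
  opt$maximum
}

#' @export
print.varclus <- function(x, ...) {
  cat("<varclus> ", x$k, " clusters of ", x$p, " variables (n = ", x$n, ")\n",
      sep = "")
  sizes <- lengths(x$clusters)
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  cat(sprintf("variance explained by the %d cluster components: %.1f%%\n",
              x$k, 100 * x$variance_explained))
  invisible(x)
}

#' @export
summary.varclus <- function(object, ...) {
  d <- data.frame(cluster = seq_len(object$k),
                  size = lengths(object$clusters),
                  eigen1 = object$cluster_eigen1,
                  prop_explained = object$cluster_eigen1 / lengths(object$clusters))
  attr(d, "variance_explained") <- object$variance_explained
  d
}

#' Cluster loadings
#'
#' @param object A fitted [varclus()] model.
#' @param ... Unused.
#' @return List of per-cluster unit loading vectors.
#' @export
coef.varclus <- function(object, ...) object$loadings

#' Cluster-component scores for new data
#'
#' Standardizes `newdata` with the training column means and standard
#' deviations stored in the model, then projects each cluster's variables onto
#' its unit loading. On the training matrix the sample variance of each score
#' column equals the cluster's leading eigenvalue.
#'
#' @param object A fitted [varclus()] model.
#' @param newdata Matrix with the same columns as the training data.
#' @param ... Unused.
#' @return n x k score matrix, columns `CC1..CCk`.
#' @export
predict.varclus <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop_ls("newdata has ", ncol(newdata), " columns; the model was fitted on ",
            object$p, class = "lactospec_shape_error")
  Z <- scale(newdata, center = object$col_means, scale = object$col_sds)
  out <- mapply(function(idx, w) Z[, idx, drop = FALSE] %*% w,
                object$clusters, object$loadings)
  out <- matrix(out, nrow = nrow(newdata))
  colnames(out) <- paste0("CC", seq_len(object$k))
  out
}

#' Proportion of total variance captured by the cluster components
#'
#' The sum over clusters of the leading eigenvalue of the cluster's
#' correlation submatrix, divided by the number of variables; in (0, 1].
#'
#' @param m A fitted [varclus()] model.
#' @return A single number.
#' @export
variance_explained <- function(m) {
  stopifnot(inherits(m, "varclus"))
  m$variance_explained
}

#' Serialize a varclus model to a JSON artifact
#'
#' Stores the partition, loadings and standardization constants at full
#' precision so the model can be re-applied to validation data in a separate
#' session; [read_varclus()] restores an identical model.
#'
#' @param m A fitted [varclus()] model.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_varclus <- function(m, path) {
  stopifnot(inherits(m, "varclus"))
  payload <- list(k = m$k, assignment = unname(m$assignment),
                  clusters = m$clusters, loadings = m$loadings,
                  col_means = unname(m$col_means), col_sds = unname(m$col_sds),
                  cluster_eigen1 = m$cluster_eigen1,
                  variance_explained = m$variance_explained,
                  p = m$p, n = m$n, var_names = m$var_names)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_varclus
#' @export
read_varclus <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(z) vapply(z, as.numeric, numeric(1))
  var_names <- if (length(j$var_names)) vapply(j$var_names, as.character,
                                               character(1)) else NULL
  structure(list(k = as.integer(j$k),
                 assignment = stats::setNames(as.integer(num(j$assignment)),
                                              var_names),
                 clusters = lapply(j$clusters, function(cl) as.integer(num(cl))),
                 loadings = lapply(j$loadings, num),
                 col_means = num(j$col_means),
                 col_sds = num(j$col_sds),
                 cluster_eigen1 = num(j$cluster_eigen1),
                 variance_explained = as.numeric(j$variance_explained),
                 p = as.integer(j$p), n = as.integer(j$n),
                 var_names = var_names),
            class = "varclus")
}
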