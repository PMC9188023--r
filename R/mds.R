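#' Symmetric bounded-loss distance between two species
#'
#' Distance over a set of nonnegative traits:
#' \deqn{d_{ij} = \sqrt{\frac{1}{K} \sum_k
#'   \frac{(x_{ik} - x_{jk})^2}{x_{ik}^2 + x_{jk}^2}},}
#' with 0/0 terms counted as 0. Each term lies in [0, 1] and is invariant to
#' rescaling the trait, so the distance lies in [0, 1] and does not depend on
#' trait units.
#'
#' @param x_i,x_j numeric vectors of trait values (equal length `K >= 1`,
#'   nonnegative).
#' @return Distance in [0, 1].
#' @examples
#' pair_distance(c(1, 2), c(3, 2))  # sqrt((4/10 + 0)/2) = 0.4472
#' @export
pair_distance <- function(x_i, x_j) {
  stopifnot(length(x_i) == length(x_j), length(x_i) >= 1L)
  if (any(x_i < 0, na.rm = TRUE) || any(x_j < 0, na.rm = TRUE))
    stop("pair_distance: trait values must be nonnegative", call. = FALSE)
  if (anyNA(x_i) || anyNA(x_j))
    stop("pair_distance: missing trait values", call. = FALSE)
  num <- (x_i - x_j)^2
  den <- x_i^2 + x_j^2
  term <- ifelse(den == 0, 0, num / den)
  sqrt(mean(term))
}

#' Bounded-loss distance matrix of a trait table
#'
#' Pairwise [pair_distance()] over the selected traits for all species in a
#' trait table. Species with any missing selected trait are dropped (with
#' the count recorded), unless `na_action = "error"`.
#'
#' @param table a [build_trait_table()] data frame.
#' @param traits trait (column) names; default the 12 of [deb_mds_traits()].
#' @param na_action `"omit"` (default) or `"error"`.
#' @return A symmetric matrix of class `"deb_distance"` with zero diagonal,
#'   entries in [0, 1], species ids as dimnames, and attributes `"traits"`
#'   and `"n_dropped"`.
#' @export
trait_distance_matrix <- function(table, traits = deb_mds_traits(),
                                  na_action = c("omit", "error")) {
  na_action <- match.arg(na_action)
  missing_cols <- setdiff(traits, names(table))
  if (length(missing_cols))
    stop("unknown trait name: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(table[, traits, drop = FALSE])
  complete <- stats::complete.cases(X)
  if (any(!complete) && na_action == "error")
    stop("missing trait values for species: ",
         paste(table$species_id[!complete], collapse = ", "), call. = FALSE)
  X <- X[complete, , drop = FALSE]
  ids <- table$species_id[complete]
  n <- nrow(X)
  if (n < 2L)
    stop("need at least 2 species with complete traits", call. = FALSE)
  # accumulate squared bounded-loss terms trait by trait (vectorized)
  D2 <- matrix(0, n, n)
  for (k in seq_len(ncol(X))) {
    xk <- X[, k]
    num <- outer(xk, xk, "-")^2
    den <- outer(xk^2, xk^2, "+")
    term <- num / den
    term[den == 0] <- 0
    D2 <- D2 + term
  }
  D <- sqrt(D2 / ncol(X))
  dimnames(D) <- list(ids, ids)
  structure(D, class = c("deb_distance", "matrix"),
            traits = traits, n_dropped = sum(!complete))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -1/2 J D^2 J` with
#' `J = I - 11'/n`, eigendecomposes `B`, and returns coordinates
#' `v_k sqrt(lambda_k)` for the axes with positive eigenvalues. Negative
#' eigenvalues (from non-Euclidean distances) are reported but not embedded.
#' The sign of each axis is fixed by making its largest-magnitude coordinate
#' positive, so output is reproducible.
#'
#' @param D a distance matrix ([trait_distance_matrix()] output, `dist`, or
#'   plain symmetric matrix).
#' @param n_axes number of axes to return (truncated, with a warning, to the
#'   number of positive eigenvalues).
#' @return An object of class `"deb_mds"`: `points` (species x axes),
#'   `eig` (all eigenvalues, nonincreasing), `n_positive`, `n_axes`.
#' @export
classical_mds <- function(D, n_axes = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("D must be a symmetric distance matrix", call. = FALSE)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- eg$values > max(eg$values[1], 0) * 1e-12
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning("n_axes = ", n_axes, " exceeds the ", n_pos,
            " positive eigenvalues; truncated", call. = FALSE)
    n_axes <- n_pos
  }
  idx <- seq_len(n_axes)
  pts <- eg$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(eg$values[idx]), n_axes, n_axes)
  for (k in seq_len(ncol(pts))) {          # deterministic sign convention
    i_max <- which.max(abs(pts[, k]))
    if (pts[i_max, k] < 0) pts[, k] <- -pts[, k]
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eg$values, n_positive = n_pos,
                 n_axes = n_axes),
            class = "deb_mds")
}

#' @export
print.deb_mds <- function(x, ...) {
  cat("Classical MDS:", nrow(x$points), "species,", x$n_axes, "axes (",
      x$n_positive, "positive eigenvalues)\n")
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$eig, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Trait-axis correlations of an MDS embedding
#'
#' Product-moment correlation of each trait with each retained MDS axis,
#' computed over the species present in the embedding. Traits spanning many
#' orders of magnitude are log10-transformed by default (only strictly
#' positive traits can be; others fall back to raw scale). Constant traits
#' have undefined correlation and are returned as `NA`.
#'
#' @param table a [build_trait_table()] data frame.
#' @param mds a [classical_mds()] result.
#' @param traits trait names; default [deb_mds_traits()].
#' @param log10_transform logical; transform positive traits to log10 scale
#'   before correlating (default `TRUE`).
#' @return Matrix (traits x axes) of correlations, with attribute
#'   `"ranking"`: a list, per axis, of trait names ordered by decreasing
#'   absolute correlation.
#' @export
trait_axis_correlations <- function(table, mds, traits = deb_mds_traits(),
                                    log10_transform = TRUE) {
  ids <- rownames(mds$points)
  idx <- match(ids, table$species_id)
  if (anyNA(idx))
    stop("MDS species not found in trait table", call. = FALSE)
  out <- matrix(NA_real_, length(traits), ncol(mds$points),
                dimnames = list(traits, colnames(mds$points)))
  for (tr in traits) {
    v <- table[[tr]][idx]
    if (log10_transform && all(v > 0)) v <- log10(v)
    if (stats::sd(v) == 0) next  # constant trait: correlation undefined
    out[tr, ] <- apply(mds$points, 2, function(ax) stats::cor(v, ax))
  }
  ranking <- apply(out, 2, function(col)
    rownames(out)[order(-abs(col), na.last = TRUE)], simplify = FALSE)
  attr(out, "ranking") <- ranking
  out
}
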