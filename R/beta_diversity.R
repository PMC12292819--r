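#' Square-root percent abundance transform
#'
#' Per sample, maps each count to `sqrt(100 * count / row_total)`, so
#' squared row sums equal 100. The transform is scale-invariant per row;
#' all-zero samples are rejected by name.
#'
#' @param table an `otu_table` or nonnegative matrix.
#' @return transformed numeric matrix (same dimnames).
#' @export
sqrt_percent_abundance <- function(table) {
  X <- as_count_matrix(table)
  rs <- rowSums(X)
  if (any(rs == 0)) {
    bad <- rownames(X)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero sample(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  sqrt(100 * X / rs)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` over nonnegative rows;
#' a pair of all-zero rows is assigned 0 by convention. Bray-Curtis is a
#' semimetric (the triangle inequality may fail), bounded in `[0, 1]`.
#'
#' @param x matrix (samples x features) of nonnegative values, e.g. the
#'   output of [sqrt_percent_abundance()].
#' @return a `dist_matrix`: list with `sample_ids` and the symmetric
#'   zero-diagonal `matrix`.
#' @export
bray_curtis_matrix <- function(x) {
  X <- as_count_matrix(x)
  if (any(X < 0)) stop("bray_curtis_matrix: negative entries")
  D <- as.matrix(vegan::vegdist(X, method = "bray"))
  D[!is.finite(D)] <- 0          # both-rows-zero convention
  diag(D) <- 0
  ids <- rownames(X); if (is.null(ids)) ids <- paste0("S", seq_len(nrow(X)))
  dimnames(D) <- list(ids, ids)
  structure(list(sample_ids = ids, matrix = D), class = "dist_matrix")
}

#' Principal Coordinate Analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by a symmetric
#' eigendecomposition. Coordinates are returned for eigenvalues above a
#' relative tolerance; axes are ordered by descending eigenvalue and each
#' axis is sign-fixed so its largest-magnitude loading is positive.
#' Negative eigenvalues (Bray-Curtis is non-Euclidean) are reported but
#' excluded from coordinates, and proportions explained are taken over
#' the positive spectrum only.
#'
#' @param dist a `dist_matrix` (or symmetric matrix with zero diagonal).
#' @return a `pcoa_result`: `coordinates` (samples x positive axes),
#'   `eigenvalues` (full spectrum, descending), `proportion_explained`
#'   (per positive axis) and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(dist) {
  if (inherits(dist, "dist_matrix")) {
    D <- dist$matrix; ids <- dist$sample_ids
  } else {
    D <- as.matrix(dist)
    ids <- rownames(D); if (is.null(ids)) ids <- paste0("S", seq_len(nrow(D)))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("pcoa_ordination: asymmetric input")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  E <- eigen(B, symmetric = TRUE)
  ev <- E$values
  tol <- max(abs(ev)) * 1e-8
  pos <- which(ev > tol)
  coords <- E$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(ids, paste0("Axis", seq_len(ncol(coords))))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion_explained = ev[pos] / sum(ev[pos]),
                 negative_eigenvalues = ev[ev < -tol],
                 trace = sum(diag(B))),
            class = "pcoa_result")
}

#' Beta-diversity ordination of an OTU table
#'
#' Convenience wrapper: square-root percent abundance, Bray-Curtis
#' dissimilarity, then PCoA; optionally restricted to a feature subset
#' (e.g. the extracted 64- or 19-feature sets).
#'
#' @param table an `otu_table`.
#' @param features optional feature ids to restrict to.
#' @return list with `distance` (a `dist_matrix`) and `ordination`
#'   (a `pcoa_result`).
#' @export
beta_diversity <- function(table, features = NULL) {
  if (!is.null(features)) table <- subset_otu(table, features = features)
  tx <- sqrt_percent_abundance(table)
  d <- bray_curtis_matrix(tx)
  list(distance = d, ordination = pcoa_ordination(d))
}
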