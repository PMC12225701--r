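#' @title Diversity comparison statistics
#' @description Alpha richness series and their regression, relative
#'   frequency standardisation, Bray-Curtis and Jaccard dissimilarities,
#'   NMDS/PCoA ordination, and procrustes and Mantel permutation tests.
#'   Community tables are tibbles with a `sample_id` column followed by one
#'   non-negative numeric column per feature (ASV or genus).
#' @name diversity_stats
NULL

.community_matrix <- function(tbl) {
  stopifnot("sample_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  if (!is.numeric(m)) stop("community features must be numeric", call. = FALSE)
  if (any(m < 0)) stop("community counts must be non-negative", call. = FALSE)
  rownames(m) <- tbl$sample_id
  m
}

#' Convert a long detection table to a wide community table
#'
#' @param tbl A tibble with one row per (sample, feature) observation.
#' @param feature,value Column names (strings) holding the feature label and
#'   its abundance.
#' @return A wide tibble: `sample_id` plus one column per feature, zeros for
#'   absent combinations.
#' @export
community_table <- function(tbl, feature, value) {
  tbl |>
    dplyr::mutate(.feature = as.character(.data[[feature]])) |>
    dplyr::select("sample_id", ".feature", value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = ".feature", values_from = "value",
                       values_fill = 0, values_fn = sum) |>
    dplyr::arrange(.data$sample_id)
}

#' Per-sample feature richness
#'
#' Number of features observed with a positive value in each sample.
#'
#' @param tbl A community table.
#' @return A tibble with `sample_id` and `richness`.
#' @export
richness <- function(tbl) {
  m <- .community_matrix(tbl)
  tibble::tibble(sample_id = rownames(m),
                 richness = as.integer(rowSums(m > 0)))
}

#' Least-squares comparison of two richness series
#'
#' Ordinary least-squares regression of `series2` on `series1` over the same
#' samples, with the two-sided test of the slope and the Pearson
#' correlation.
#'
#' @param series1,series2 Equal-length numeric vectors (paired by sample).
#' @return A one-row tibble: `slope`, `intercept`, `r`, `p_value`.
#' @export
compare_richness <- function(series1, series2) {
  stopifnot(length(series1) == length(series2), length(series1) >= 3)
  fit <- stats::lm(series2 ~ series1)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  tibble::tibble(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r = if (stats::sd(series1) == 0 || stats::sd(series2) == 0) NA_real_
        else stats::cor(series1, series2),
    p_value = p
  )
}

#' Standardise a community table to relative frequencies
#'
#' Each sample row is divided by its total so rows sum to one. All-zero rows
#' are rejected: a sample with no observations has no composition.
#'
#' @param tbl A community table.
#' @return The standardised community table.
#' @export
standardize_relfreq <- function(tbl) {
  m <- .community_matrix(tbl)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero sample row(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(m / tot)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x - y| / sum (x + y)` over features.
#'
#' @param tbl A community table (typically relative frequencies).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(tbl) {
  m <- .community_matrix(tbl)
  vegan::vegdist(m, method = "bray")
}

#' Jaccard dissimilarity matrix (presence/absence)
#'
#' `d = 1 - shared / union` over the feature presence sets.
#'
#' @param tbl A community table.
#' @return A `dist` object with sample labels.
#' @export
jaccard <- function(tbl) {
  m <- .community_matrix(tbl)
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Ordinate a dissimilarity matrix
#'
#' Non-metric multidimensional scaling (stress-minimising rank embedding,
#' several random restarts, seeded) or metric principal-coordinates
#' analysis.
#'
#' @param d A `dist` object.
#' @param k Embedding dimension (default 2).
#' @param method `"nmds"` or `"mds"`.
#' @param seed Integer seed for the NMDS restarts.
#' @param trymax Maximum NMDS random restarts.
#' @return An object of class `sedacomp_ordination`: `points` tibble
#'   (`sample_id`, `axis1..axisk`), `stress` (NMDS stress; for PCoA the
#'   fraction of variance unexplained by the first `k` eigenvalues),
#'   `method`, `converged`.
#' @export
ordinate <- function(d, k = 2, method = c("nmds", "mds"), seed = 1L,
                     trymax = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n <= k) stop("need more samples than ordination dimensions",
                   call. = FALSE)
  if (method == "nmds") {
    fit <- withr::with_seed(seed, vegan::metaMDS(
      d, k = k, trymax = trymax, trace = 0, autotransform = FALSE,
      wascores = FALSE
    ))
    pts <- fit$points
    stress <- fit$stress
    cv <- fit$converged
    converged <- isTRUE(cv) || (is.numeric(cv) && length(cv) == 1 && cv > 0)
  } else {
    fit <- stats::cmdscale(d, k = k, eig = TRUE)
    pts <- fit$points
    pos <- fit$eig[fit$eig > 0]
    stress <- 1 - sum(fit$eig[seq_len(k)]) / sum(pos)
    converged <- TRUE
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  structure(
    list(
      points = dplyr::bind_cols(
        tibble::tibble(sample_id = labels(d)), tibble::as_tibble(pts)
      ),
      stress = stress, method = method, k = k, converged = converged
    ),
    class = "sedacomp_ordination"
  )
}

#' @export
print.sedacomp_ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, k = %d, stress = %.4f\n",
              x$method, x$k, x$stress))
  invisible(x)
}

.ordination_coords <- function(x) {
  if (inherits(x, "sedacomp_ordination")) {
    m <- as.matrix(x$points[-1])
    rownames(m) <- x$points$sample_id
    m
  } else if (is.data.frame(x) && "sample_id" %in% names(x)) {
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    rownames(m) <- x$sample_id
    m
  } else {
    as.matrix(x)
  }
}

#' Procrustes permutation test between two ordinations
#'
#' Superimposes configuration `y` on `x` by translation, scaling and
#' rotation and tests the residual statistic `m12^2` against row
#' permutations of `y`; `t = sqrt(1 - m12^2)` is the correlation-like
#' concordance statistic. The permutation p-value uses the add-one
#' estimator, never exactly zero.
#'
#' @param x,y Ordinations ([ordinate()] results, `sample_id` + coordinate
#'   tibbles, or bare matrices) over the same samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A one-row tibble: `m12_squared`, `t`, `p_value`, `n_perm`.
#' @export
procrustes_test <- function(x, y, n_perm = 999L, seed = 1L) {
  xm <- .ordination_coords(x)
  ym <- .ordination_coords(y)
  if (!is.null(rownames(xm)) && !is.null(rownames(ym))) {
    if (!setequal(rownames(xm), rownames(ym))) {
      stop("ordinations cover different samples", call. = FALSE)
    }
    ym <- ym[rownames(xm), , drop = FALSE]
  }
  stopifnot(nrow(xm) == nrow(ym), ncol(xm) == ncol(ym))
  fit <- withr::with_seed(seed, vegan::protest(
    xm, ym, permutations = n_perm
  ))
  tibble::tibble(
    m12_squared = fit$ss,
    t = sqrt(1 - fit$ss),
    p_value = fit$signif,
    n_perm = n_perm
  )
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' Pearson correlation over the off-diagonal upper triangles, with the null
#' distribution generated by simultaneous row/column permutation of the
#' second matrix; one-sided add-one p-value.
#'
#' @param d1,d2 `dist` objects over the same samples.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A one-row tibble: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(d1, "dist"), inherits(d2, "dist"))
  if (attr(d1, "Size") != attr(d2, "Size")) {
    stop("dissimilarity matrices differ in size", call. = FALSE)
  }
  l1 <- labels(d1)
  l2 <- labels(d2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) stop("matrix labels differ", call. = FALSE)
    if (!identical(l1, l2)) {
      m2 <- as.matrix(d2)[l1, l1]
      d2 <- stats::as.dist(m2)
    }
  }
  fit <- withr::with_seed(seed, vegan::mantel(
    d1, d2, permutations = n_perm
  ))
  tibble::tibble(
    r = unname(fit$statistic),
    p_value = fit$signif,
    n_perm = n_perm
  )
}
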