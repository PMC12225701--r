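#' Fit the positional deamination damage model
#'
#' Post-mortem cytosine deamination is read as C-to-T substitutions whose
#' frequency is highest at the 5' fragment end and decays inwards. The model
#' for the mismatch frequency at 5' position `x` is
#'
#'     p(x) = A * (1 - q)^(x - 1) + c
#'
#' with amplitude `A` (excess frequency at position 1), per-position decay
#' `q` and background mismatch rate `c`. Counts `k_x` out of `n_x`
#' opportunities are treated as independent binomials and `(A, q, c)` are
#' estimated by bounded maximum likelihood; the standard error of `A` comes
#' from the observed information (inverse Hessian at the optimum) and the
#' significance statistic is the Wald ratio `z = A / se(A)`. An
#' essentially flat profile fits to `A` near 0 with small `z`.
#'
#' @param k Integer vector of C-to-T mismatch counts per position (1-based
#'   5' positions `1..length(k)`).
#' @param n Integer vector of opportunity counts per position (reads at
#'   least `x` bp long), same length as `k`.
#' @return An object of class `damage_fit`: list with elements `a`, `q`,
#'   `c`, `se_a`, `z`, `n_reads` (reads at position 1), `loglik`,
#'   `convergence`.
#' @examples
#' x <- 1:15
#' p <- 0.25 * 0.65^(x - 1) + 0.01
#' fit <- fit_damage(rbinom(15, 5000, p), rep(5000, 15))
#' fit$a
#' @export
fit_damage <- function(k, n) {
  stopifnot(length(k) == length(n), all(k >= 0), all(n >= 0), all(k <= n))
  use <- n > 0
  if (sum(use) < 4) {
    stop("fit_damage needs at least 4 positions with opportunities",
         call. = FALSE)
  }
  x <- which(use)
  k <- k[use]
  n <- n[use]

  nll <- function(par) {
    a <- par[1]; qq <- par[2]; cc <- par[3]
    p <- a * (1 - qq)^(x - 1) + cc
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(k, n, p, log = TRUE))
  }

  f <- k / n
  c0 <- min(max(stats::median(f[x >= stats::median(x)]), 1e-4), 0.5)
  a0 <- min(max(f[1] - c0, 1e-3), 0.9)
  init <- c(a = a0, q = 0.3, c = c0)
  opt <- stats::optim(
    init, nll, method = "L-BFGS-B",
    lower = c(0, 0, 1e-6), upper = c(0.99, 0.99, 0.5),
    hessian = TRUE
  )

  se_a <- tryCatch({
    vc <- solve(opt$hessian)
    sa <- suppressWarnings(sqrt(vc[1, 1]))
    if (!is.finite(sa) || sa <= 0) NA_real_ else sa
  }, error = function(e) NA_real_)
  if (is.na(se_a)) {
    # fall back to the curvature of the profile in A alone
    h <- (nll(opt$par + c(1e-5, 0, 0)) - 2 * nll(opt$par) +
            nll(opt$par - c(1e-5, 0, 0))) / 1e-10
    se_a <- if (is.finite(h) && h > 0) 1 / sqrt(h) else Inf
  }

  structure(
    list(
      a = unname(opt$par[1]), q = unname(opt$par[2]),
      c = unname(opt$par[3]),
      se_a = se_a, z = unname(opt$par[1]) / se_a,
      n_reads = n[1], loglik = -opt$value,
      convergence = opt$convergence
    ),
    class = "damage_fit"
  )
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf(
    "<damage_fit> A = %.4f (se %.4f, z = %.2f), q = %.3f, c = %.4f, n = %d\n",
    x$a, x$se_a, x$z, x$q, x$c, x$n_reads))
  invisible(x)
}

#' Tidy a damage fit
#' @param x A `damage_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`
#'   (only the amplitude carries a standard error), `statistic`.
#' @method tidy damage_fit
#' @export
tidy.damage_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "decay", "background"),
    estimate = c(x$a, x$q, x$c),
    std.error = c(x$se_a, NA_real_, NA_real_),
    statistic = c(x$z, NA_real_, NA_real_)
  )
}

#' Glance at a damage fit
#' @param x A `damage_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `amplitude`, `z`, `n_reads`, `logLik`,
#'   `converged`.
#' @method glance damage_fit
#' @export
glance.damage_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$a, z = x$z, n_reads = x$n_reads,
    logLik = x$loglik, converged = x$convergence == 0
  )
}

#' Fit the damage model for every (genus, sample) group
#'
#' Convenience wrapper running [fit_damage()] over the output of
#' [damage_counts()].
#'
#' @param counts Tibble from [damage_counts()] (`genus_taxid`, `sample_id`,
#'   `pos`, `k`, `n`).
#' @param ages Tibble with `sample_id` and `age` (years BP).
#' @return A tibble with one row per group: `genus_taxid`, `sample_id`,
#'   `age`, `a`, `q`, `c`, `se_a`, `z`, `n_reads`.
#' @export
fit_damage_groups <- function(counts, ages) {
  counts |>
    dplyr::group_by(.data$genus_taxid, .data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_damage(d$k[order(d$pos)], d$n[order(d$pos)])
      tibble::tibble(a = fit$a, q = fit$q, c = fit$c, se_a = fit$se_a,
                     z = fit$z, n_reads = fit$n_reads)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(ages[, c("sample_id", "age")], by = "sample_id") |>
    dplyr::relocate("age", .after = "sample_id")
}

#' Build the terrestrial-plant age-damage envelope
#'
#' Terrestrial plant material must have been transported into the marine
#' sediment and so carries at least the ambient damage of its depositional
#' age: its fitted amplitudes calibrate the minimum damage an authentic
#' in-situ detection of the same age should show. Calibration points are
#' plant-genus fits with at least `min_reads` reads and `z >= min_z`; the
#' envelope value at age `a` is the running minimum amplitude over
#' calibration points no older than `a`, linearly interpolated between
#' calibration ages and held constant beyond the oldest point. Ages younger
#' than the youngest calibration point are unassessable.
#'
#' @param fits Tibble from [fit_damage_groups()].
#' @param tree A [taxonomy].
#' @param plant_clade Taxon id of the reference plant clade.
#' @param exclusions Clades excluded from calibration (marine plants).
#' @param min_reads,min_z Calibration thresholds (defaults 500 reads,
#'   z of 2).
#' @param method `"running_min"` (default) or `"binned"`: per-age-bin minima
#'   instead of the running minimum.
#' @param bin_width Bin width in years for `method = "binned"`.
#' @return An object of class `damage_envelope` (calibration points plus an
#'   evaluation rule), or `NULL` with a warning when fewer than two
#'   calibration points qualify.
#' @export
build_envelope <- function(fits, tree, plant_clade, exclusions = integer(0),
                           min_reads = 500L, min_z = 2,
                           method = c("running_min", "binned"),
                           bin_width = 1000) {
  method <- match.arg(method)
  .assert_taxonomy(tree)
  is_plant <- vapply(fits$genus_taxid, function(id) {
    is_reference_plant(tree, id, plant_clade, exclusions)
  }, TRUE)
  cal <- fits[is_plant & fits$n_reads >= min_reads & fits$z >= min_z, ]
  if (nrow(cal) < 2) {
    warning("fewer than 2 qualifying plant calibration points; ",
            "envelope unavailable and observations cannot be authenticated")
    return(NULL)
  }
  pts <- cal |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(amplitude = min(.data$a), .groups = "drop") |>
    dplyr::arrange(.data$age)
  if (method == "binned") {
    pts <- cal |>
      dplyr::mutate(bin = floor(.data$age / bin_width)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(age = stats::median(.data$age),
                       amplitude = min(.data$a), .groups = "drop") |>
      dplyr::arrange(.data$age) |>
      dplyr::select("age", "amplitude")
  }
  pts$envelope <- cummin(pts$amplitude)
  structure(
    list(points = pts, method = method,
         min_reads = min_reads, min_z = min_z),
    class = "damage_envelope"
  )
}

#' @export
print.damage_envelope <- function(x, ...) {
  cat("<damage_envelope> ", nrow(x$points), " calibration ages (",
      min(x$points$age), "-", max(x$points$age), " BP), method ",
      x$method, "\n", sep = "")
  invisible(x)
}

#' Evaluate the envelope at given ages
#'
#' @param envelope A [build_envelope()] result.
#' @param age Numeric ages (years BP).
#' @return Minimum authentic amplitude at each age; `NA` for ages younger
#'   than the first calibration point (unassessable).
#' @export
envelope_at <- function(envelope, age) {
  stopifnot(inherits(envelope, "damage_envelope"))
  pts <- envelope$points
  out <- stats::approx(pts$age, pts$envelope, xout = age,
                       method = "linear", rule = 2)$y
  out[age < min(pts$age)] <- NA_real_
  out
}

#' Authenticate detections against the age-damage envelope
#'
#' An observation is `ancient` when its Wald statistic reaches `min_z` and
#' its amplitude reaches the envelope value at its age (both comparisons
#' inclusive, so boundary observations are not silently discarded);
#' `not_damaged` when assessable but failing either condition; and
#' `unassessable` at ages where the envelope is undefined.
#'
#' @param fits Tibble with columns `a`, `z`, `age` (e.g. from
#'   [fit_damage_groups()]).
#' @param envelope A [build_envelope()] result, or `NULL` (everything
#'   unassessable).
#' @param min_z Significance threshold (default 2).
#' @return `fits` with added columns `envelope` and `damage_status`.
#' @export
classify_ancient <- function(fits, envelope, min_z = 2) {
  stopifnot(all(c("a", "z", "age") %in% names(fits)))
  if (is.null(envelope)) {
    fits$envelope <- NA_real_
    fits$damage_status <- "unassessable"
    return(fits)
  }
  env <- envelope_at(envelope, fits$age)
  status <- dplyr::case_when(
    is.na(env) ~ "unassessable",
    fits$z >= min_z & fits$a >= env ~ "ancient",
    TRUE ~ "not_damaged"
  )
  fits$envelope <- env
  fits$damage_status <- status
  fits
}
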