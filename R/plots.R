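#' Bubble plot of cross-method detections
#'
#' The classic comparison panel: taxa against sample age, one facet per
#' method, bubble size showing evidence (positive PCR replicates or mapped
#' reads) and colour the age-damage authentication status.
#'
#' @param detections A [detection_matrix()] tibble.
#' @param tree Optional [taxonomy] to label taxa by name.
#' @param shared_only Plot only taxa detected by both methods (default TRUE).
#' @return A ggplot object.
#' @export
plot_detections <- function(detections, tree = NULL, shared_only = TRUE) {
  d <- detections
  if (shared_only) d <- d[d$shared, ]
  d$taxon <- as.character(d$genus_taxid)
  if (!is.null(tree)) {
    d$taxon <- unname(tree$name_of[as.character(d$genus_taxid)])
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$age, y = .data$taxon, size = .data$evidence,
    colour = .data$damage_status
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$method), ncol = 1) +
    ggplot2::scale_size_continuous(trans = "sqrt") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (cal years BP)", y = NULL,
                  size = "evidence", colour = "damage status") +
    ggplot2::theme_minimal()
}

#' Richness of both arms against sample age
#'
#' @param report A [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_richness <- function(report) {
  ages <- report$richness$ages
  d <- dplyr::bind_rows(
    dplyr::mutate(report$richness$mb, arm = "metabarcoding"),
    dplyr::mutate(report$richness$mg, arm = "metagenomics")
  ) |>
    dplyr::left_join(ages[, c("sample_id", "age")], by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$richness,
                                  colour = .data$arm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (cal years BP)", y = "richness",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ordination
#'
#' @param object A [ordinate()] result.
#' @param ages Optional tibble with `sample_id` and `age` to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sedacomp_ordination
#' @export
autoplot.sedacomp_ordination <- function(object, ages = NULL, ...) {
  d <- object$points
  if (!is.null(ages)) {
    d <- dplyr::left_join(d, ages[, c("sample_id", "age")], by = "sample_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  p <- if (!is.null(ages)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$age), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -1, size = 3) +
    ggplot2::labs(
      title = sprintf("%s (stress = %.3f)", toupper(object$method),
                      object$stress),
      x = "axis 1", y = "axis 2"
    ) +
    ggplot2::theme_minimal()
}

#' Observed and fitted positional damage profile
#'
#' @param counts One group's rows from [damage_counts()] (`pos`, `k`, `n`).
#' @param fit Optional [fit_damage()] result to overlay.
#' @return A ggplot object.
#' @export
plot_damage_profile <- function(counts, fit = NULL) {
  d <- dplyr::mutate(counts, freq = .data$k / .data$n)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$freq)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "5' position", y = "C-to-T frequency") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    curve <- tibble::tibble(
      pos = seq(min(d$pos), max(d$pos), length.out = 200)
    )
    curve$freq <- fit$a * (1 - fit$q)^(curve$pos - 1) + fit$c
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}
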