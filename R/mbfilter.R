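#' @title Metabarcoding filter cascade
#' @description Post-denoising processing of ASV-by-replicate count tables:
#'   orientation merging, singleton removal, the negative-control floor,
#'   the amplicon length window, rarefaction, cumulative sum scaling, LCA
#'   assignment and positive-replicate summarisation. All functions operate
#'   on a long "replicate table": a tibble with columns `asv_id`,
#'   `sequence`, `replicate_id`, `sample_id`, `role` (one of `sample`,
#'   `extraction_negative`, `pcr_negative`, `library_negative`) and `count`.
#'   Absent rows are implicit zeros, so "setting a cell to zero" drops the
#'   row.
#' @name mbfilter
NULL

.check_replicate_table <- function(tbl) {
  req <- c("asv_id", "sequence", "replicate_id", "sample_id", "role", "count")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    stop("replicate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$count < 0)) stop("negative counts in replicate table",
                               call. = FALSE)
  roles <- c("sample", "extraction_negative", "pcr_negative",
             "library_negative")
  bad <- setdiff(unique(tbl$role), roles)
  if (length(bad) > 0) {
    stop("unknown replicate role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Merge forward- and reverse-orientation ASV tables
#'
#' Tagged amplicon libraries sequence inserts in both orientations; the two
#' independently denoised tables are combined by reverse-complementing one
#' orientation and summing counts of ASVs with identical sequence within each
#' replicate. ASVs unique to one orientation pass through unchanged; total
#' counts are conserved.
#'
#' @param forward,reverse Long replicate tables sharing replicate columns;
#'   `reverse` may be empty.
#' @return A merged long replicate table keyed by sequence, keeping the
#'   forward table's ASV ids where sequences match.
#' @export
merge_orientations <- function(forward, reverse) {
  .check_replicate_table(forward)
  if (nrow(reverse) == 0) {
    return(dplyr::arrange(tibble::as_tibble(forward),
                          .data$asv_id, .data$replicate_id))
  }
  .check_replicate_table(reverse)
  extra <- setdiff(unique(reverse$replicate_id), unique(forward$replicate_id))
  if (length(extra) > 0) {
    stop("reverse table has replicate(s) absent from forward table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  rev2 <- reverse
  rev2$sequence <- .revcomp(rev2$sequence)
  both <- dplyr::bind_rows(forward, rev2)
  # id for each sequence: the forward id when present, else the reverse id
  key <- dplyr::bind_rows(
    dplyr::distinct(forward, .data$sequence, .data$asv_id),
    dplyr::distinct(rev2, .data$sequence, .data$asv_id)
  ) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE)
  both$asv_id <- key$asv_id[match(both$sequence, key$sequence)]
  both |>
    dplyr::group_by(.data$asv_id, .data$sequence, .data$replicate_id,
                    .data$sample_id, .data$role) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$asv_id, .data$replicate_id)
}

#' Remove singleton observations
#'
#' Sets any observation (reads per ASV in one replicate) equal to one read to
#' zero; all other cells are untouched. Singletons are the cheapest
#' false-positive class in tagged amplicon data (tag jumps, index hops,
#' polymerase error survivors).
#'
#' @param tbl A long replicate table.
#' @return The table with count-1 cells dropped.
#' @export
remove_singletons <- function(tbl) {
  .check_replicate_table(tbl)
  tibble::as_tibble(tbl[tbl$count != 1, ])
}

#' Negative-control floor filter
#'
#' For each ASV the worst-case false-positive abundance is the maximum count
#' of that ASV across all negative-control replicates (extraction, PCR and
#' library negatives pooled). Experimental cells strictly below that per-ASV
#' floor are set to zero; cells at or above it are kept. Control columns are
#' dropped from the output. With no negative controls every floor is zero
#' and the table passes through.
#'
#' @param tbl A long replicate table.
#' @param exclude_replicates Replicate ids excluded from floor computation
#'   (for known catastrophic controls, e.g. a single massively contaminated
#'   control replicate); default none.
#' @return A long replicate table containing experimental replicates only.
#' @export
negative_floor_filter <- function(tbl, exclude_replicates = character(0)) {
  .check_replicate_table(tbl)
  negs <- tbl[tbl$role != "sample" &
                !(tbl$replicate_id %in% exclude_replicates), ]
  floors <- stats::setNames(numeric(0), character(0))
  if (nrow(negs) > 0) {
    agg <- tapply(negs$count, negs$asv_id, max)
    floors <- stats::setNames(as.numeric(agg), names(agg))
  }
  out <- tbl[tbl$role == "sample", ]
  thr <- floors[out$asv_id]
  thr[is.na(thr)] <- 0
  tibble::as_tibble(out[out$count >= thr, ])
}

#' Amplicon length window filter
#'
#' Removes ASVs whose sequence length falls outside the plausible amplicon
#' window, excluding non-target amplification. Bounds are inclusive: an ASV
#' is removed only if strictly smaller than `min_bp` or strictly larger than
#' `max_bp` (defaults 75 and 150 bp, the window for a eukaryote 18S V9
#' marker; vertebrate 12S uses `max_bp = 140`).
#'
#' @param tbl A long replicate table.
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The table restricted to in-window ASVs.
#' @export
length_filter <- function(tbl, min_bp = 75L, max_bp = 150L) {
  .check_replicate_table(tbl)
  len <- nchar(tbl$sequence)
  tibble::as_tibble(tbl[len >= min_bp & len <= max_bp, ])
}

#' Rarefy replicates to a fixed depth
#'
#' Replicates with fewer total reads than `depth` are removed; every
#' surviving replicate is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads.
#'
#' @param tbl A long replicate table.
#' @param depth Target reads per replicate (default 20000).
#' @param seed Optional integer seed for reproducible subsampling.
#' @return A long replicate table whose replicate totals all equal `depth`.
#' @export
rarefy <- function(tbl, depth = 20000L, seed = NULL) {
  .check_replicate_table(tbl)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  run <- function() {
    tbl |>
      dplyr::group_by(.data$replicate_id) |>
      dplyr::filter(sum(.data$count) >= depth) |>
      dplyr::group_modify(function(d, key) {
        tot <- sum(d$count)
        if (tot == depth) return(d)
        picked <- sample(rep.int(seq_len(nrow(d)), d$count), depth)
        d$count <- tabulate(picked, nbins = nrow(d))
        d[d$count > 0, ]
      }) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(names(tbl))) |>
      dplyr::arrange(.data$asv_id, .data$replicate_id)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Cumulative sum scaling normalisation
#'
#' Scales each replicate by the sum of its counts up to a chosen quantile of
#' its positive count distribution, then rescales by the median scaling
#' factor, damping the influence of a few dominant ASVs on library-size
#' normalisation. The quantile is either fixed (`p`, default the median) or
#' chosen adaptively as the smallest quantile at which the median scaling
#' factor across replicates becomes unstable (relative change above
#' `instability`); if no stable choice emerges the fixed quantile is used.
#'
#' @param tbl A long replicate table.
#' @param quantile_mode `"adaptive"` or `"fixed"`.
#' @param p Quantile for fixed mode, in (0, 1).
#' @param instability Relative-change threshold of the adaptive search.
#' @return The table with an additional column `norm` (real-valued
#'   normalised abundance); `count` is retained.
#' @export
css_normalize <- function(tbl, quantile_mode = c("adaptive", "fixed"),
                          p = 0.5, instability = 0.1) {
  .check_replicate_table(tbl)
  quantile_mode <- match.arg(quantile_mode)
  pos <- tbl[tbl$count > 0, ]
  if (any(!unique(tbl$replicate_id) %in% unique(pos$replicate_id))) {
    stop("replicate with no positive counts cannot be CSS-normalised",
         call. = FALSE)
  }
  counts_by_rep <- split(pos$count, pos$replicate_id)
  s_at <- function(pp) {
    vapply(counts_by_rep, function(v) {
      sum(v[v <= stats::quantile(v, pp, type = 7)])
    }, 0)
  }
  p_used <- p
  if (quantile_mode == "adaptive") {
    grid <- seq(0.05, 0.95, by = 0.05)
    med <- vapply(grid, function(pp) stats::median(s_at(pp)), 0)
    relchg <- abs(diff(med)) / pmax(med[-length(med)], .Machine$double.eps)
    unstable <- which(relchg > instability)
    p_used <- if (length(unstable) > 0) grid[unstable[1]] else p
  }
  s <- s_at(p_used)
  scale_ref <- stats::median(s)
  out <- tbl
  out$norm <- out$count / s[out$replicate_id] * scale_ref
  attr(out, "css_quantile") <- p_used
  attr(out, "css_factors") <- s
  tibble::as_tibble(out)
}

#' Assign ASVs by lowest common ancestor of their reference hits
#'
#' Mirrors LCA parsing of per-ASV reference database hits: within each ASV,
#' hits whose identity falls within `top_frac` of the best hit enter the LCA;
#' the ASV is additionally screened against a high-quality match band
#' (best identity above `min_identity` and best coverage above
#' `min_coverage`), below which it is flagged low-quality.
#'
#' @param hits Tibble with columns `asv_id`, `taxid`, `identity`, `coverage`.
#' @param tree A [taxonomy].
#' @param top_frac Retention band: hits with
#'   `identity >= best * (1 - top_frac)` are kept for the LCA.
#' @param min_identity,min_coverage High-quality screen on the best hit.
#' @return A tibble with columns `asv_id`, `taxid` (assigned LCA),
#'   `best_identity`, `best_coverage`, `low_quality`.
#' @export
assign_asvs <- function(hits, tree, top_frac = 0.01,
                        min_identity = 0.99, min_coverage = 0.95) {
  stopifnot(all(c("asv_id", "taxid", "identity", "coverage") %in% names(hits)))
  .assert_taxonomy(tree)
  hits |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::group_modify(function(d, key) {
      best_i <- max(d$identity)
      best_c <- max(d$coverage)
      keep <- d$taxid[d$identity >= best_i * (1 - top_frac)]
      tibble::tibble(
        taxid = lca(tree, keep),
        best_identity = best_i,
        best_coverage = best_c,
        low_quality = best_i < min_identity | best_c < min_coverage
      )
    }) |>
    dplyr::ungroup()
}

#' Count positive PCR replicates per sample and ASV
#'
#' The metabarcoding abundance proxy: for each sample, the number of its PCR
#' replicates in which the ASV was observed with a positive count, bounded by
#' the number of replicates per sample.
#'
#' @param tbl A filtered long replicate table (experimental replicates).
#' @return A tibble with columns `sample_id`, `asv_id`, `n_positive`.
#' @export
positive_replicates <- function(tbl) {
  .check_replicate_table(tbl)
  tbl[tbl$count > 0 & tbl$role == "sample", ] |>
    dplyr::distinct(.data$sample_id, .data$asv_id, .data$replicate_id) |>
    dplyr::count(.data$sample_id, .data$asv_id, name = "n_positive")
}

#' Read or write long replicate tables as TSV
#' @param tbl A long replicate table.
#' @param path File path.
#' @return `read_replicate_table()` returns a tibble;
#'   `write_replicate_table()` returns `path` invisibly.
#' @export
write_replicate_table <- function(tbl, path) {
  .check_replicate_table(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_replicate_table
#' @export
read_replicate_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    asv_id = readr::col_character(), sequence = readr::col_character(),
    replicate_id = readr::col_character(),
    sample_id = readr::col_character(), role = readr::col_character(),
    count = readr::col_double()
  ))
  .check_replicate_table(tbl)
  tbl
}
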