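#' @title Metagenomic read profiling
#' @description Similarity-band filtering of per-read reference hits,
#'   per-read LCA classification, genus-level aggregation with a minimum
#'   read-count threshold, and positional C-to-T damage counting. Hit tables
#'   are tibbles with one row per (read, candidate taxon):
#'   `read_id`, `sample_id`, `taxid`, `identity`, `read_length`,
#'   `ct_offsets`, `ga_offsets` (comma-separated 1-based offsets from the
#'   5' and 3' ends respectively).
#' @name mgprofile
NULL

.check_hit_table <- function(hits) {
  req <- c("read_id", "sample_id", "taxid", "identity", "read_length",
           "ct_offsets", "ga_offsets")
  missing_cols <- setdiff(req, names(hits))
  if (length(missing_cols) > 0) {
    stop("hit table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(hits) > 0) {
    if (any(hits$identity < 0 | hits$identity > 1)) {
      stop("identity outside [0, 1]", call. = FALSE)
    }
    multi <- hits |>
      dplyr::distinct(.data$read_id, .data$sample_id) |>
      dplyr::count(.data$read_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi) > 0) {
      stop("read id(s) appearing in multiple samples: ",
           paste(utils::head(multi$read_id, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(hits)
}

#' Filter hits to a similarity band
#'
#' Retains hit rows whose identity lies inside the inclusive band
#' `[min_sim, max_sim]` (defaults 0.95-1.00), the band within which short
#' ancient reads are considered confidently mapped.
#'
#' @param hits A hit table.
#' @param min_sim,max_sim Inclusive identity bounds.
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, min_sim = 0.95, max_sim = 1.00) {
  .check_hit_table(hits)
  if (min_sim > max_sim) stop("min_sim must not exceed max_sim",
                              call. = FALSE)
  tibble::as_tibble(hits[hits$identity >= min_sim & hits$identity <= max_sim, ])
}

#' Classify reads by lowest common ancestor of their hits
#'
#' Each read is assigned the LCA of the taxa of all its surviving hits.
#' Reads with no surviving hits do not appear in the output (callers audit
#' the difference).
#'
#' @param hits A (band-filtered) hit table.
#' @param tree A [taxonomy].
#' @return A tibble with columns `read_id`, `sample_id`, `taxid`,
#'   `read_length`, `ct_offsets`, `ga_offsets` (one row per read).
#' @export
classify_reads <- function(hits, tree) {
  .check_hit_table(hits)
  .assert_taxonomy(tree)
  if (nrow(hits) == 0) {
    return(tibble::tibble(read_id = character(0), sample_id = character(0),
                          taxid = integer(0), read_length = integer(0),
                          ct_offsets = character(0),
                          ga_offsets = character(0)))
  }
  # single-hit reads keep their taxon directly; multi-hit reads take the LCA
  # of their taxon set, computed once per distinct set
  first <- hits[!duplicated(hits$read_id), ]
  is_multi <- hits$read_id %in% hits$read_id[duplicated(hits$read_id)]
  out <- first
  if (any(is_multi)) {
    sets <- tapply(hits$taxid[is_multi], hits$read_id[is_multi],
                   function(v) paste(sort(unique(v)), collapse = ","))
    uniq <- unique(sets)
    lca_of <- stats::setNames(
      vapply(uniq, function(k) {
        lca(tree, as.integer(strsplit(k, ",")[[1]]))
      }, 1L),
      uniq
    )
    assigned <- lca_of[sets]
    idx <- match(names(sets), out$read_id)
    out$taxid[idx] <- unname(assigned)
  }
  tibble::as_tibble(out[, c("read_id", "sample_id", "taxid", "read_length",
                            "ct_offsets", "ga_offsets")]) |>
    dplyr::arrange(.data$read_id)
}

#' Genus-level read profile
#'
#' Rolls read assignments at genus rank or below up to their genus and counts
#' reads per (genus, sample); observations with fewer than `min_reads` reads
#' (default 100, below which false-positive rates climb) are removed. Reads
#' assigned above genus are discarded from the profile and reported in the
#' `n_above_genus` attribute.
#'
#' @param assignments Output of [classify_reads()].
#' @param tree A [taxonomy].
#' @param min_reads Minimum reads per (genus, sample) observation.
#' @return A tibble with columns `genus_taxid`, `sample_id`, `n_reads`.
#' @export
genus_table <- function(assignments, tree, min_reads = 100L) {
  .assert_taxonomy(tree)
  ids <- unique(assignments$taxid)
  genus_of <- stats::setNames(
    vapply(ids, function(id) rank_ancestor(tree, id, "genus"), 1L),
    ids
  )
  assignments$genus_taxid <- genus_of[as.character(assignments$taxid)]
  n_above <- sum(is.na(assignments$genus_taxid))
  out <- assignments |>
    dplyr::filter(!is.na(.data$genus_taxid)) |>
    dplyr::count(.data$genus_taxid, .data$sample_id, name = "n_reads") |>
    dplyr::filter(.data$n_reads >= min_reads) |>
    dplyr::arrange(.data$genus_taxid, .data$sample_id)
  attr(out, "n_above_genus") <- n_above
  out
}

#' Positional C-to-T damage counts for a read group
#'
#' For every read group (by default each (genus, sample) observation in the
#' profile) and 5' position `x = 1..max_pos`: `n_x` is the number of group
#' reads at least `x` bp long (the opportunity proxy; reads rather than
#' reference cytosines, the convention under which the simulator generates
#' mismatches) and `k_x` the number of group reads carrying a C-to-T
#' mismatch at offset `x`.
#'
#' @param assignments Output of [classify_reads()] (carries per-read offsets).
#' @param profile Output of [genus_table()]; groups to tally.
#' @param tree A [taxonomy].
#' @param max_pos Deepest position tallied (default 15; the damage signal
#'   concentrates in the first 10-15 positions).
#' @return A tibble with columns `genus_taxid`, `sample_id`, `pos`, `k`, `n`.
#' @export
damage_counts <- function(assignments, profile, tree, max_pos = 15L) {
  .assert_taxonomy(tree)
  ids <- unique(assignments$taxid)
  genus_of <- stats::setNames(
    vapply(ids, function(id) rank_ancestor(tree, id, "genus"), 1L),
    ids
  )
  assignments$genus_taxid <- genus_of[as.character(assignments$taxid)]
  grouped <- dplyr::inner_join(
    assignments[!is.na(assignments$genus_taxid), ],
    profile[, c("genus_taxid", "sample_id")],
    by = c("genus_taxid", "sample_id")
  )
  if (nrow(grouped) == 0) {
    stop("no reads fall in the requested groups", call. = FALSE)
  }
  offs <- parse_offsets(grouped$ct_offsets)
  grouped |>
    dplyr::mutate(.offs = offs) |>
    dplyr::group_by(.data$genus_taxid, .data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      pos <- seq_len(max_pos)
      all_off <- unlist(d$.offs)
      tibble::tibble(
        pos = pos,
        k = vapply(pos, function(x) sum(all_off == x), 0L),
        n = vapply(pos, function(x) sum(d$read_length >= x), 0L)
      )
    }) |>
    dplyr::ungroup()
}

#' Read or write hit tables as TSV
#' @param hits A hit table.
#' @param path File path.
#' @return `read_hit_table()` returns a tibble; `write_hit_table()` returns
#'   `path` invisibly.
#' @export
write_hit_table <- function(hits, path) {
  .check_hit_table(hits)
  readr::write_tsv(hits, path, na = "")
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), sample_id = readr::col_character(),
    taxid = readr::col_integer(), identity = readr::col_double(),
    read_length = readr::col_integer(),
    ct_offsets = readr::col_character(), ga_offsets = readr::col_character()
  ))
  hits$ct_offsets[is.na(hits$ct_offsets)] <- ""
  hits$ga_offsets[is.na(hits$ga_offsets)] <- ""
  .check_hit_table(hits)
  hits
}
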