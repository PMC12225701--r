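#' Interpolate sample age from an age-depth table
#'
#' Piecewise-linear interpolation through a calibrated age-depth model's
#' point estimates (the age model itself is an input, not re-fitted here).
#'
#' @param age_depth Tibble with numeric columns `depth` (cm) and `age`
#'   (cal years BP), both strictly increasing.
#' @param depth Depths to evaluate, within the table's range.
#' @return Interpolated ages (years BP).
#' @export
interpolate_age <- function(age_depth, depth) {
  stopifnot(all(c("depth", "age") %in% names(age_depth)))
  if (nrow(age_depth) < 2 || any(diff(age_depth$depth) <= 0) ||
      any(diff(age_depth$age) <= 0)) {
    stop("age-depth table must be strictly increasing in depth and age ",
         "with at least two points", call. = FALSE)
  }
  if (any(depth < min(age_depth$depth) | depth > max(age_depth$depth))) {
    stop("depth outside the age-depth table range", call. = FALSE)
  }
  stats::approx(age_depth$depth, age_depth$age, xout = depth,
                method = "linear")$y
}

#' Combine both arms into a detection matrix
#'
#' One record per (taxon, sample, method) with positive evidence: the
#' number of positive PCR replicates for metabarcoding, the number of
#' mapped reads for metagenomics. Metagenomic records carry the age-damage
#' authentication status; metabarcoding records are `not_applicable`
#' (amplicons carry no positional damage readout here). Taxa detected by
#' both methods anywhere in the record are flagged `shared`.
#'
#' @param mb_detections Tibble with `sample_id`, `genus_taxid`,
#'   `n_positive` (metabarcoding, genus level).
#' @param mg_profile [genus_table()] output.
#' @param classifications [classify_ancient()] output (per genus, sample).
#' @param ages Tibble with `sample_id`, `age`.
#' @return A tibble: `genus_taxid`, `sample_id`, `age`, `method`,
#'   `evidence`, `damage_status`, `shared`.
#' @export
detection_matrix <- function(mb_detections, mg_profile, classifications,
                             ages) {
  mb <- mb_detections |>
    dplyr::filter(.data$n_positive > 0) |>
    dplyr::transmute(
      genus_taxid = .data$genus_taxid, sample_id = .data$sample_id,
      method = "metabarcoding", evidence = .data$n_positive,
      damage_status = "not_applicable"
    )
  mg <- mg_profile |>
    dplyr::left_join(
      classifications[, c("genus_taxid", "sample_id", "damage_status")],
      by = c("genus_taxid", "sample_id")
    ) |>
    dplyr::transmute(
      genus_taxid = .data$genus_taxid, sample_id = .data$sample_id,
      method = "metagenomics", evidence = .data$n_reads,
      damage_status = dplyr::coalesce(.data$damage_status, "unassessable")
    )
  shared_taxa <- intersect(unique(mb$genus_taxid), unique(mg$genus_taxid))
  dplyr::bind_rows(mb, mg) |>
    dplyr::left_join(ages[, c("sample_id", "age")], by = "sample_id") |>
    dplyr::mutate(shared = .data$genus_taxid %in% shared_taxa) |>
    dplyr::relocate("age", .after = "sample_id") |>
    dplyr::arrange(.data$method, .data$genus_taxid, .data$sample_id)
}

.audit_row <- function(stage, tbl) {
  tibble::tibble(stage = stage, rows = nrow(tbl),
                 reads = sum(tbl$count))
}

#' Run the full two-arm comparison pipeline on a simulated record
#'
#' Orchestrates simulate, emit, the metabarcoding filter cascade (orientation
#' merge, singleton removal, negative floor, length window, rarefaction and
#' CSS branches, LCA assignment, positive replicates), the metagenomic chain
#' (similarity band, per-read LCA, genus profile, damage counts, per-group
#' damage fits, plant-calibrated envelope, authentication), the detection
#' matrix, and the diversity comparison battery (richness regression,
#' Bray-Curtis/Jaccard, NMDS, procrustes, Mantel), with a per-stage audit
#' trail. Fully deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV, the envelope and test statistics as JSON, plus a manifest.
#' @param rarefy_depth Reads per surviving replicate (default 20000).
#' @param min_bp,max_bp Amplicon length window (defaults 75 and 150 bp).
#' @param min_sim,max_sim Metagenomic similarity band (defaults 0.95, 1.00).
#' @param min_reads_genus Minimum reads per (genus, sample) observation
#'   (default 100).
#' @param min_reads_damage,min_z Damage-calibration thresholds (defaults
#'   500 reads, z of 2).
#' @param mantel_perm,procrustes_perm Permutation counts (defaults 10000
#'   and 999).
#' @return A list of class `sedacomp_report`; see Details.
#' @details The report contains `record` (ground truth), `audit`, `mb`
#'   (filtered/rarefied/CSS tables, assignments, positive replicates,
#'   community), `mg` (genus profile, damage fits, envelope,
#'   classification), `detections`, `richness` (per-arm series, age trends,
#'   cross-arm regression) and `beta` (dissimilarities, ordinations,
#'   procrustes and Mantel results for the full and metazoan-subset
#'   communities).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         rarefy_depth = 20000L, min_bp = 75L, max_bp = 150L,
                         min_sim = 0.95, max_sim = 1.00,
                         min_reads_genus = 100L,
                         min_reads_damage = 500L, min_z = 2,
                         mantel_perm = 10000L, procrustes_perm = 999L) {
  record <- simulate_record(config)
  tree <- config$tree
  ages <- record$samples

  mb_raw <- emit_metabarcoding(record)
  hits_raw <- emit_metagenomics(record)

  audit <- list()
  merged <- merge_orientations(mb_raw$forward, mb_raw$reverse)
  audit$merged <- .audit_row("mb_merge_orientations", merged)
  nosingle <- remove_singletons(merged)
  audit$nosingle <- .audit_row("mb_remove_singletons", nosingle)
  floored <- negative_floor_filter(nosingle)
  audit$floored <- .audit_row("mb_negative_floor", floored)
  if (!any(merged$role != "sample")) {
    warning("no negative-control replicates: floor thresholds are all zero")
  }
  lenok <- length_filter(floored, min_bp, max_bp)
  audit$lenok <- .audit_row("mb_length_filter", lenok)
  rarefied <- rarefy(lenok, rarefy_depth, seed = config$seed + 303L)
  audit$rarefied <- .audit_row("mb_rarefy", rarefied)
  css <- css_normalize(lenok)

  assignments_asv <- assign_asvs(mb_raw$asv_hits, tree)
  posreps <- positive_replicates(rarefied)
  mb_comm <- community_table(posreps, "asv_id", "n_positive")

  # genus-level metabarcoding detections for the cross-method matrix
  asv_genus <- assignments_asv |>
    dplyr::mutate(genus_taxid = vapply(.data$taxid, function(id) {
      rank_ancestor(tree, id, "genus")
    }, 1L))
  mb_genus <- posreps |>
    dplyr::inner_join(asv_genus[, c("asv_id", "genus_taxid")], by = "asv_id") |>
    dplyr::filter(!is.na(.data$genus_taxid)) |>
    dplyr::group_by(.data$sample_id, .data$genus_taxid) |>
    dplyr::summarise(n_positive = max(.data$n_positive), .groups = "drop")

  # metagenomic chain
  hits <- filter_hits(hits_raw, min_sim, max_sim)
  audit$hits <- tibble::tibble(stage = "mg_similarity_band",
                               rows = nrow(hits), reads = NA_real_)
  assignments <- classify_reads(hits, tree)
  profile <- genus_table(assignments, tree, min_reads_genus)
  dmg <- damage_counts(assignments, profile, tree)
  fits <- fit_damage_groups(dmg, ages)
  envelope <- build_envelope(fits, tree, config$plant_clade,
                             config$plant_exclusions,
                             min_reads_damage, min_z)
  classified <- classify_ancient(fits, envelope, min_z)
  mg_comm <- community_table(profile, "genus_taxid", "n_reads")

  detections <- detection_matrix(mb_genus, profile, classified, ages)

  # --- diversity comparisons ---------------------------------------------
  rich_mb <- richness(mb_comm)
  rich_mg <- richness(mg_comm)
  shared_samples <- intersect(rich_mb$sample_id, rich_mg$sample_id)
  r1 <- rich_mb$richness[match(shared_samples, rich_mb$sample_id)]
  r2 <- rich_mg$richness[match(shared_samples, rich_mg$sample_id)]
  age_shared <- ages$age[match(shared_samples, ages$sample_id)]
  richness_cmp <- compare_richness(r1, r2)
  age_trends <- tibble::tibble(
    arm = c("metabarcoding", "metagenomics"),
    slope_per_kyr = c(
      unname(stats::coef(stats::lm(r1 ~ I(age_shared / 1000)))[2]),
      unname(stats::coef(stats::lm(r2 ~ I(age_shared / 1000)))[2])
    ),
    r = c(stats::cor(age_shared, r1), stats::cor(age_shared, r2))
  )

  is_mz_genus <- function(ids) {
    vapply(ids, function(id) {
      config$metazoa_clade %in% lineage(tree, id)$taxid
    }, TRUE)
  }
  subset_comm <- function(comm, keep_features) {
    keep <- intersect(names(comm), c("sample_id", keep_features))
    out <- comm[keep]
    m <- .community_matrix(out)
    out[rowSums(m) > 0, ]
  }
  mz_asvs <- asv_genus$asv_id[!is.na(asv_genus$genus_taxid) &
                                is_mz_genus(asv_genus$genus_taxid)]
  mz_genera <- unique(profile$genus_taxid[is_mz_genus(profile$genus_taxid)])

  beta_pair <- function(mb_c, mg_c, label) {
    samp <- intersect(mb_c$sample_id, mg_c$sample_id)
    if (length(samp) < 5) {
      return(list(label = label, n_samples = length(samp), mantel = NULL,
                  procrustes = NULL, ord_mb = NULL, ord_mg = NULL))
    }
    mb_c <- standardize_relfreq(mb_c[match(samp, mb_c$sample_id), ])
    mg_c <- standardize_relfreq(mg_c[match(samp, mg_c$sample_id), ])
    d_mb <- bray_curtis(mb_c)
    d_mg <- bray_curtis(mg_c)
    j_mb <- jaccard(mb_c)
    j_mg <- jaccard(mg_c)
    ord_mb <- ordinate(d_mb, method = "nmds", seed = config$seed + 11L)
    ord_mg <- ordinate(d_mg, method = "nmds", seed = config$seed + 12L)
    list(
      label = label, n_samples = length(samp),
      mantel = dplyr::bind_rows(
        dplyr::mutate(mantel_test(d_mb, d_mg, mantel_perm,
                                  seed = config$seed + 13L),
                      metric = "bray"),
        dplyr::mutate(mantel_test(j_mb, j_mg, mantel_perm,
                                  seed = config$seed + 14L),
                      metric = "jaccard")
      ),
      procrustes = procrustes_test(ord_mb, ord_mg, procrustes_perm,
                                   seed = config$seed + 15L),
      ord_mb = ord_mb, ord_mg = ord_mg
    )
  }

  beta_full <- beta_pair(mb_comm, mg_comm, "all_taxa")
  mb_mz <- subset_comm(mb_comm, mz_asvs)
  mg_mz <- subset_comm(mg_comm, as.character(mz_genera))
  beta_mz <- beta_pair(mb_mz, mg_mz, "metazoa")

  report <- structure(
    list(
      record = record,
      audit = dplyr::bind_rows(audit),
      mb = list(merged = merged, filtered = lenok, rarefied = rarefied,
                css = css, assignments = assignments_asv,
                positive_reps = posreps, community = mb_comm,
                genus_detections = mb_genus),
      mg = list(profile = profile, damage_counts = dmg, fits = fits,
                envelope = envelope, classification = classified,
                community = mg_comm),
      detections = detections,
      richness = list(mb = rich_mb, mg = rich_mg, ages = ages,
                      comparison = richness_cmp, age_trends = age_trends),
      beta = list(full = beta_full, metazoa = beta_mz),
      params = list(rarefy_depth = rarefy_depth, min_bp = min_bp,
                    max_bp = max_bp, min_sim = min_sim, max_sim = max_sim,
                    min_reads_genus = min_reads_genus,
                    min_reads_damage = min_reads_damage, min_z = min_z,
                    mantel_perm = mantel_perm,
                    procrustes_perm = procrustes_perm)
    ),
    class = "sedacomp_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.sedacomp_report <- function(x, ...) {
  cat("<sedacomp_report>\n")
  cat("  samples:", nrow(x$record$samples), " ASVs retained:",
      length(unique(x$mb$rarefied$asv_id)), " genera profiled:",
      length(unique(x$mg$profile$genus_taxid)), "\n")
  cat("  authenticated observations:",
      sum(x$mg$classification$damage_status == "ancient"), "\n")
  if (!is.null(x$beta$full$mantel)) {
    m <- x$beta$full$mantel[x$beta$full$mantel$metric == "bray", ]
    cat(sprintf("  full-community Mantel (Bray): r = %.3f, p = %.4g\n",
                m$r, m$p_value))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits every table as TSV, the envelope, test statistics and ground truth
#' as JSON, plus a manifest listing all files. Output is plain text and
#' byte-identical for identical configurations.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(report$audit, p("audit.tsv"))
  write_replicate_table(report$mb$rarefied, p("mb_rarefied.tsv"))
  readr::write_tsv(report$mb$css, p("mb_css.tsv"))
  readr::write_tsv(report$mb$assignments, p("mb_assignments.tsv"))
  readr::write_tsv(report$mb$positive_reps, p("mb_positive_reps.tsv"))
  readr::write_tsv(report$mg$profile, p("mg_genus_profile.tsv"))
  readr::write_tsv(report$mg$fits, p("mg_damage_fits.tsv"))
  readr::write_tsv(report$mg$classification, p("mg_classification.tsv"))
  readr::write_tsv(report$detections, p("detection_matrix.tsv"))
  readr::write_tsv(
    dplyr::left_join(report$richness$mb,
                     dplyr::rename(report$richness$mg,
                                   richness_mg = "richness"),
                     by = "sample_id"),
    p("richness.tsv")
  )
  if (!is.null(report$mg$envelope)) {
    jsonlite::write_json(report$mg$envelope$points, p("envelope.json"),
                         digits = NA)
  }
  stats_out <- list(
    richness_comparison = report$richness$comparison,
    richness_age_trends = report$richness$age_trends,
    mantel_full = report$beta$full$mantel,
    procrustes_full = report$beta$full$procrustes,
    mantel_metazoa = report$beta$metazoa$mantel,
    procrustes_metazoa = report$beta$metazoa$procrustes
  )
  jsonlite::write_json(stats_out, p("statistics.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  truth <- list(
    samples = report$record$samples,
    composition = report$record$composition,
    asvs = report$record$asvs[setdiff(names(report$record$asvs), "sequence")]
  )
  jsonlite::write_json(truth, p("ground_truth.json"), digits = NA)
  writeLines(paste0(">", report$record$asvs$asv_id, "\n",
                    report$record$asvs$sequence),
             p("asvs.fasta"))
  manifest <- tibble::tibble(file = sort(list.files(outdir)))
  readr::write_tsv(manifest, p("manifest.tsv"))
  invisible(outdir)
}
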