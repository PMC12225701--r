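#' Simulation configuration for a synthetic sedaDNA record
#'
#' Bundles every parameter of the taphonomic simulator: the sample ages, the
#' true community, age-dependent fragmentation and deamination, the amplicon
#' marker, replicate structure, and the metagenomic read model. The defaults
#' describe an 11-sample marine record spanning roughly 8000 calibrated years
#' BP (five samples younger than 2000 BP, six between 4000 and 8500 BP),
#' eight PCR replicates per sample, and a 90-130 bp eukaryote amplicon.
#'
#' @param seed Integer seed; the record and both emitted datasets are
#'   byte-identical functions of `seed` plus the other fields.
#' @param ages Calibrated ages (years BP), strictly increasing, one per sample.
#' @param tree A [taxonomy] containing every simulated taxon
#'   (default [example_taxonomy()]).
#' @param taxa Tibble with columns `taxid` (genus id in `tree`), `mean_abund`
#'   (mean relative abundance, normalised internally) and `source` (one of
#'   `marine_insitu`, `terrestrial_plant`, `modern_contaminant`).
#' @param lambda0 Mean DNA fragment length (bp) at age 0.
#' @param lambda_decay Exponential decay of mean fragment length per kyr.
#' @param a_max,k_age Saturating damage amplitude: the true position-1 excess
#'   C-to-T frequency at age `t` kyr is `a_max * (1 - exp(-k_age * t))` for
#'   in-situ and plant taxa and 0 for modern contaminants.
#' @param q Per-position decay of the damage signal along the read.
#' @param c Background (non-damage) C-to-T mismatch rate.
#' @param amplicon_min,amplicon_max Amplicon length bounds (bp, primer-free).
#' @param n_pcr_replicates PCR replicates per sample.
#' @param gamma_amp Amplification efficiency of the occupancy detection model:
#'   a replicate detects a taxon with probability
#'   `1 - exp(-gamma_amp * abundance * amplifiable_fraction)`.
#' @param replicate_reads_meanlog,replicate_reads_sdlog Log-normal parameters
#'   of the per-replicate sequencing depth.
#' @param n_negatives Named integer vector of negative-control replicates by
#'   role (`extraction_negative`, `pcr_negative`, `library_negative`).
#' @param contam_rate Mean contaminant reads per contaminant ASV per
#'   negative-control replicate (Poisson); 0 silences the negatives.
#' @param singleton_rate Probability that an empty experimental cell receives
#'   a single spurious read (exercises the singleton filter).
#' @param reverse_fraction Fraction of taxa whose ASV is also emitted in the
#'   reverse orientation (exercises orientation merging).
#' @param n_junk_asvs Number of off-target ASVs outside the length window.
#' @param mg_reads Shotgun reads sequenced per sample before capture losses.
#' @param capture_min,capture_max Fragment lengths (bp) recoverable by the
#'   short-fragment-optimised extraction/mapping chain; `capture_min` mirrors
#'   the 30 bp mapper minimum.
#' @param mg_inband_rate Fraction of metagenomic hits whose identity falls in
#'   the analysis band `[0.95, 1]`; the rest fall just below it.
#' @param mg_ambig_rate Fraction of reads carrying a second congeneric hit
#'   (exercises per-read LCA).
#' @param gradient_sd,noise_sd Spread of per-taxon age-gradient coefficients
#'   and per-cell log-abundance noise in the true community.
#' @param decouple_metazoa If `TRUE`, the metabarcoding arm sees an
#'   independently re-drawn metazoan composition, decoupling the metazoan
#'   subset between arms while all other taxa remain shared.
#' @param metazoa_clade,plant_clade,plant_exclusions Taxon ids of the
#'   metazoan clade, the reference plant clade, and clades excluded from
#'   plant-based damage calibration (the marine eelgrass genus by default).
#' @return A validated list of class `sedacomp_config`.
#' @export
sim_config <- function(seed = 1L,
                       ages = c(50, 450, 950, 1450, 1950,
                                4200, 5000, 5800, 6600, 7400, 8300),
                       tree = example_taxonomy(),
                       taxa = default_taxa(),
                       lambda0 = 130,
                       lambda_decay = 0.18,
                       a_max = 0.30,
                       k_age = 0.35,
                       q = 0.35,
                       c = 0.01,
                       amplicon_min = 90,
                       amplicon_max = 130,
                       n_pcr_replicates = 8L,
                       gamma_amp = 80,
                       replicate_reads_meanlog = log(6e4),
                       replicate_reads_sdlog = 0.4,
                       n_negatives = c(extraction_negative = 4L,
                                       pcr_negative = 2L,
                                       library_negative = 2L),
                       contam_rate = 30,
                       singleton_rate = 0.02,
                       reverse_fraction = 0.25,
                       n_junk_asvs = 2L,
                       mg_reads = 40000L,
                       capture_min = 30L,
                       capture_max = 70L,
                       mg_inband_rate = 0.85,
                       mg_ambig_rate = 0.15,
                       gradient_sd = 0.8,
                       noise_sd = 0.3,
                       decouple_metazoa = FALSE,
                       metazoa_clade = 10L,
                       plant_clade = 11L,
                       plant_exclusions = 340L) {
  cfg <- list(
    seed = as.integer(seed), ages = as.numeric(ages), tree = tree,
    taxa = tibble::as_tibble(taxa),
    lambda0 = lambda0, lambda_decay = lambda_decay,
    a_max = a_max, k_age = k_age, q = q, c = c,
    amplicon_min = as.integer(amplicon_min),
    amplicon_max = as.integer(amplicon_max),
    n_pcr_replicates = as.integer(n_pcr_replicates),
    gamma_amp = gamma_amp,
    replicate_reads_meanlog = replicate_reads_meanlog,
    replicate_reads_sdlog = replicate_reads_sdlog,
    n_negatives = n_negatives,
    contam_rate = contam_rate,
    singleton_rate = singleton_rate,
    reverse_fraction = reverse_fraction,
    n_junk_asvs = as.integer(n_junk_asvs),
    mg_reads = as.integer(mg_reads),
    capture_min = as.integer(capture_min),
    capture_max = as.integer(capture_max),
    mg_inband_rate = mg_inband_rate,
    mg_ambig_rate = mg_ambig_rate,
    gradient_sd = gradient_sd, noise_sd = noise_sd,
    decouple_metazoa = isTRUE(decouple_metazoa),
    metazoa_clade = as.integer(metazoa_clade),
    plant_clade = as.integer(plant_clade),
    plant_exclusions = as.integer(plant_exclusions)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sedacomp_config")
}

validate_sim_config <- function(cfg) {
  .assert_taxonomy(cfg$tree)
  if (length(cfg$ages) < 2 || any(diff(cfg$ages) <= 0)) {
    stop("ages must be strictly increasing with at least two samples",
         call. = FALSE)
  }
  rates <- c(cfg$q, cfg$c, cfg$a_max, cfg$singleton_rate,
             cfg$reverse_fraction, cfg$mg_inband_rate, cfg$mg_ambig_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$a_max + cfg$c > 1) stop("a_max + c must not exceed 1", call. = FALSE)
  if (cfg$lambda0 <= 0 || cfg$lambda_decay < 0) {
    stop("fragment length model requires lambda0 > 0 and decay >= 0",
         call. = FALSE)
  }
  req <- c("taxid", "mean_abund", "source")
  if (!all(req %in% names(cfg$taxa))) {
    stop("taxa table needs columns taxid, mean_abund, source", call. = FALSE)
  }
  bad_src <- setdiff(unique(cfg$taxa$source),
                     c("marine_insitu", "terrestrial_plant",
                       "modern_contaminant"))
  if (length(bad_src) > 0) {
    stop("unknown taxon source(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  .assert_known(cfg$tree, cfg$taxa$taxid)
  if (any(cfg$taxa$mean_abund <= 0)) {
    stop("mean_abund must be positive", call. = FALSE)
  }
  if (cfg$capture_min < 1 || cfg$capture_max <= cfg$capture_min) {
    stop("capture window must satisfy 1 <= capture_min < capture_max",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Example marine taxonomy for simulation
#'
#' A compact tree (root, Eukaryota; Metazoa, Viridiplantae, diatom and fungal
#' clades; genera with one or two species each) used by the default simulator
#' configuration. Contains the shared metazoan genera of interest (herring,
#' cod, a larvacean), terrestrial plant genera for damage calibration, the
#' marine eelgrass genus (excluded from calibration), a set of rarer marine
#' genera, and modern contaminant genera. Includes "no rank" intermediates so
#' rank queries must skip them.
#'
#' @return A [taxonomy] object.
#' @export
example_taxonomy <- function() {
  rows <- list(
    c(1, 1, "no rank", "root"),
    c(2, 1, "superkingdom", "Eukaryota"),
    c(10, 2, "kingdom", "Metazoa"),
    c(11, 2, "kingdom", "Viridiplantae"),
    c(12, 2, "no rank", "Stramenopiles"),
    c(13, 2, "kingdom", "Fungi"),
    c(14, 2, "no rank", "Alveolata"),
    c(20, 10, "phylum", "Chordata"),
    c(21, 20, "no rank", "Tunicata"),
    c(22, 10, "no rank", "Protostomia"),
    c(24, 12, "phylum", "Bacillariophyta"),
    c(25, 14, "phylum", "Dinoflagellata"),
    c(30, 11, "phylum", "Streptophyta")
  )
  genus <- function(id, parent, name, species) {
    out <- list(c(id, parent, "genus", name))
    for (i in seq_along(species)) {
      out[[i + 1]] <- c(id + i, id, "species", species[[i]])
    }
    out
  }
  g <- c(
    genus(100, 20, "Clupea", c("Clupea harengus", "Clupea sprattus")),
    genus(110, 20, "Gadus", c("Gadus morhua", "Gadus macrocephalus")),
    genus(120, 21, "Oikopleura", c("Oikopleura dioica", "Oikopleura labradoriensis")),
    genus(130, 20, "Homo", "Homo sapiens"),
    genus(200, 24, "Thalassiosira", c("Thalassiosira nordenskioeldii", "Thalassiosira gravida")),
    genus(210, 24, "Chaetoceros", c("Chaetoceros socialis", "Chaetoceros debilis")),
    genus(220, 24, "Skeletonema", c("Skeletonema costatum", "Skeletonema marinoi")),
    genus(300, 30, "Betula", c("Betula pendula", "Betula pubescens")),
    genus(310, 30, "Pinus", c("Pinus sylvestris", "Pinus mugo")),
    genus(320, 30, "Quercus", c("Quercus robur", "Quercus petraea")),
    genus(330, 30, "Alnus", c("Alnus glutinosa", "Alnus incana")),
    genus(340, 30, "Zostera", "Zostera marina"),
    genus(600, 13, "Penicillium", c("Penicillium chrysogenum", "Penicillium brevicompactum")),
    genus(610, 13, "Aspergillus", c("Aspergillus niger", "Aspergillus fumigatus"))
  )
  rare_protist <- c("Navicula", "Nitzschia", "Amphora", "Cocconeis",
                    "Fragilaria", "Cyclotella", "Melosira",
                    "Pseudonitzschia", "Leptocylindrus", "Rhizosolenia",
                    "Guinardia", "Ditylum", "Coscinodiscus", "Actinocyclus",
                    "Eucampia")
  for (i in seq_along(rare_protist)) {
    id <- 400L + 10L * (i - 1L)
    g <- c(g, genus(id, 24, rare_protist[i],
                    paste(rare_protist[i], c("species-a", "species-b"))))
  }
  moderate_mz <- c("Calanus", "Mytilus", "Carcinus", "Asterias", "Sagitta")
  for (i in seq_along(moderate_mz)) {
    id <- 550L + 10L * (i - 1L)
    g <- c(g, genus(id, 22, moderate_mz[i],
                    paste(moderate_mz[i], c("species-a", "species-b"))))
  }
  # rare tail: diatoms and dinoflagellates far below the metagenomic
  # genus-reporting depth but amplifiable, as most 18S ASVs are
  tail_diatom <- c("Minidiscus", "Attheya", "Licmophora", "Striatella",
                   "Grammatophora", "Diploneis", "Pleurosigma", "Surirella",
                   "Bacillaria", "Cylindrotheca", "Asterionellopsis",
                   "Odontella", "Lithodesmium", "Brockmanniella", "Papiliocellulus")
  tail_dino <- c("Alexandrium", "Gymnodinium", "Prorocentrum", "Ceratium",
                 "Dinophysis", "Protoperidinium", "Scrippsiella", "Gonyaulax",
                 "Heterocapsa", "Amphidinium", "Karenia", "Akashiwo",
                 "Polykrikos", "Noctiluca", "Oxyrrhis")
  for (i in seq_along(tail_diatom)) {
    id <- 700L + 10L * (i - 1L)
    g <- c(g, genus(id, 24, tail_diatom[i],
                    paste(tail_diatom[i], c("species-a", "species-b"))))
  }
  for (i in seq_along(tail_dino)) {
    id <- 850L + 10L * (i - 1L)
    g <- c(g, genus(id, 25, tail_dino[i],
                    paste(tail_dino[i], c("species-a", "species-b"))))
  }
  rows <- c(rows, g)
  nodes <- tibble::tibble(
    taxid = as.integer(vapply(rows, `[[`, "", 1L)),
    parent = as.integer(vapply(rows, `[[`, "", 2L)),
    rank = vapply(rows, `[[`, "", 3L),
    name = vapply(rows, `[[`, "", 4L)
  )
  taxonomy(nodes)
}

#' Default simulated community
#'
#' Genus-level mean relative abundances for [example_taxonomy()]: abundant
#' in-situ marine genera (three shared metazoans, three diatoms, eelgrass),
#' five moderately abundant metazoan genera, four terrestrial plant genera
#' (abundant enough to pass the 500-read damage-calibration threshold),
#' fifteen rarer diatom genera whose expected metagenomic read counts
#' straddle the 100-read genus reporting threshold, and three modern
#' contaminants.
#'
#' @return A tibble with columns `taxid`, `mean_abund`, `source`.
#' @export
default_taxa <- function() {
  anchors <- tibble::tibble(
    taxid = c(100L, 110L, 120L, 200L, 210L, 220L, 340L),
    mean_abund = c(0.060, 0.050, 0.050, 0.070, 0.060, 0.050, 0.040),
    source = "marine_insitu"
  )
  moderate_mz <- tibble::tibble(
    taxid = seq(550L, 590L, by = 10L),
    mean_abund = rep(0.020, 5),
    source = "marine_insitu"
  )
  plants <- tibble::tibble(
    taxid = c(300L, 310L, 320L, 330L),
    mean_abund = c(0.060, 0.060, 0.050, 0.050),
    source = "terrestrial_plant"
  )
  rare <- tibble::tibble(
    taxid = seq(400L, 540L, by = 10L),
    mean_abund = seq(0.004, 0.018, length.out = 15),
    source = "marine_insitu"
  )
  # rare amplifiable tail, below the genus-level metagenomic reporting depth
  rare_tail <- tibble::tibble(
    taxid = seq(700L, 990L, by = 10L),
    mean_abund = exp(seq(log(0.004), log(0.0008), length.out = 30)),
    source = "marine_insitu"
  )
  contam <- tibble::tibble(
    taxid = c(130L, 600L, 610L),
    mean_abund = c(0.015, 0.012, 0.012),
    source = "modern_contaminant"
  )
  dplyr::bind_rows(anchors, moderate_mz, plants, rare, rare_tail, contam)
}

#' Mean fragment length at a given age
#'
#' `lambda(age) = lambda0 * exp(-lambda_decay * age/1000)`: post-depositional
#' fragmentation shortens surviving fragments exponentially with age.
#'
#' @param age Age in calibrated years BP.
#' @param lambda0 Mean length at age 0 (bp).
#' @param lambda_decay Decay per kyr.
#' @return Mean fragment length in bp.
#' @export
fragment_mean_length <- function(age, lambda0 = 130, lambda_decay = 0.18) {
  lambda0 * exp(-lambda_decay * age / 1000)
}

#' True damage amplitude at a given age
#'
#' Saturating-exponential accumulation
#' `A(age) = a_max * (1 - exp(-k_age * age/1000))` for in-situ and plant
#' material; modern contaminants carry no damage at any age.
#'
#' @param age Age in years BP.
#' @param a_max,k_age Saturation amplitude and rate per kyr.
#' @param source Taxon source label; `modern_contaminant` returns 0.
#' @return Amplitude (excess position-1 C-to-T frequency).
#' @export
true_amplitude <- function(age, a_max = 0.30, k_age = 0.35,
                           source = "marine_insitu") {
  ifelse(source == "modern_contaminant", 0,
         a_max * (1 - exp(-k_age * age / 1000)))
}

#' Fraction of fragments long enough to amplify
#'
#' Under a geometric fragment-length distribution with mean `lambda`,
#' `P(L >= len) = (1 - 1/lambda)^(len - 1)`.
#'
#' @param len Required amplicon length (bp).
#' @param lambda Mean fragment length (bp); must exceed 1.
#' @return Probability in (0, 1].
#' @export
amplifiable_fraction <- function(len, lambda) {
  stopifnot(all(lambda > 1))
  (1 - 1 / lambda)^(len - 1)
}

#' Per-replicate detection probability
#'
#' Occupancy-style detection: `1 - exp(-gamma * abundance * amp_frac)`.
#' Reproduces replicate-level stochastic dropout without simulating PCR
#' cycles explicitly.
#'
#' @param abundance Relative abundance of the taxon.
#' @param amp_frac Amplifiable fraction (see [amplifiable_fraction()]).
#' @param gamma Amplification efficiency.
#' @return Detection probability per PCR replicate.
#' @export
detection_probability <- function(abundance, amp_frac, gamma = 80) {
  1 - exp(-gamma * abundance * amp_frac)
}

# geometric survival within the capture window [lo, hi]
.capture_fraction <- function(lambda, lo, hi) {
  p <- 1 / lambda
  (1 - p)^(lo - 1) - (1 - p)^hi
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

.random_seq <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate the ground truth of a sedaDNA record
#'
#' Draws the true per-sample community (with a smooth age gradient so that
#' community turnover tracks time), per-sample fragment-length and damage
#' parameters, and the ASV sequence inventory. The returned record is the
#' single source of truth consumed by [emit_metabarcoding()] and
#' [emit_metagenomics()]; identical seed and configuration yield identical
#' records.
#'
#' @param config A [sim_config()].
#' @return A list of class `sedacomp_record` with elements `samples`
#'   (sample_id, age, lambda, a_true), `composition` (per sample and taxon:
#'   relative abundance seen by each arm, source, true amplitude), `asvs`
#'   (ASV inventory with sequences, lengths, orientation and ambiguity
#'   flags), and the configuration.
#' @export
simulate_record <- function(config) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    n_s <- length(cfg$ages)
    sample_id <- sprintf("s%02d", seq_len(n_s))
    samples <- tibble::tibble(
      sample_id = sample_id,
      age = cfg$ages,
      lambda = fragment_mean_length(cfg$ages, cfg$lambda0, cfg$lambda_decay),
      a_true = true_amplitude(cfg$ages, cfg$a_max, cfg$k_age)
    )

    taxa <- cfg$taxa
    taxa$mean_abund <- taxa$mean_abund / sum(taxa$mean_abund)
    n_t <- nrow(taxa)

    # smooth turnover: log-abundance drifts linearly with scaled age
    grad <- stats::rnorm(n_t, 0, cfg$gradient_sd)
    grad[taxa$source == "modern_contaminant"] <- 0
    age_scaled <- cfg$ages / max(cfg$ages) - 0.5
    eps <- matrix(stats::rnorm(n_s * n_t, 0, cfg$noise_sd), n_s, n_t)
    logw <- outer(rep(1, n_s), log(taxa$mean_abund)) +
      outer(age_scaled, grad) + eps
    w <- exp(logw)
    rel <- w / rowSums(w)

    # per-(sample, taxon) fragment state seen by the metabarcoding arm;
    # modern contaminants always carry fresh, full-length DNA
    lambda_mb <- matrix(rep(samples$lambda, n_t), n_s, n_t)
    lambda_mb[, taxa$source == "modern_contaminant"] <- cfg$lambda0

    rel_mb <- rel
    if (cfg$decouple_metazoa) {
      # scramble the metazoan block for the metabarcoding arm only:
      # independent composition AND sample-permuted taphonomic state, so no
      # cross-arm structure survives within metazoa
      is_mz <- vapply(taxa$taxid, function(id) {
        cfg$metazoa_clade %in% lineage(cfg$tree, id)$taxid
      }, TRUE)
      grad2 <- stats::rnorm(n_t, 0, cfg$gradient_sd)
      eps2 <- matrix(stats::rnorm(n_s * n_t, 0, cfg$noise_sd), n_s, n_t)
      perm <- sample(n_s)
      logw2 <- outer(rep(1, n_s), log(taxa$mean_abund)) +
        outer(age_scaled[perm], grad2) + eps2
      w2 <- exp(logw2)
      w_mb <- w
      w_mb[, is_mz] <- w2[, is_mz]
      rel_mb <- w_mb / rowSums(w_mb)
      lambda_mb[, is_mz & taxa$source != "modern_contaminant"] <-
        lambda_mb[perm, is_mz & taxa$source != "modern_contaminant"]
    }

    s_idx <- rep(seq_len(n_s), each = n_t)
    t_idx <- rep(seq_len(n_t), times = n_s)
    composition <- tibble::tibble(
      sample_id = sample_id[s_idx],
      taxid = taxa$taxid[t_idx],
      source = taxa$source[t_idx],
      age = cfg$ages[s_idx],
      rel_mb = rel_mb[cbind(s_idx, t_idx)],
      rel_mg = rel[cbind(s_idx, t_idx)],
      lambda_mb = lambda_mb[cbind(s_idx, t_idx)]
    )
    composition$a_true <- true_amplitude(composition$age, cfg$a_max,
                                         cfg$k_age, composition$source)

    amp_len <- sample(cfg$amplicon_min:cfg$amplicon_max, n_t, replace = TRUE)
    reverse_oriented <- stats::runif(n_t) < cfg$reverse_fraction
    n_children <- vapply(taxa$taxid, function(id) {
      sum(cfg$tree$parent_of == id & cfg$tree$nodes$taxid != id)
    }, 1L)
    ambiguous <- n_children >= 2 & stats::runif(n_t) < 0.5
    asvs <- tibble::tibble(
      asv_id = sprintf("asv%03d", seq_len(n_t)),
      taxid = taxa$taxid,
      source = taxa$source,
      length = amp_len,
      sequence = .random_seq(n_t, amp_len),
      reverse_oriented = reverse_oriented,
      ambiguous = ambiguous
    )
    if (cfg$n_junk_asvs > 0) {
      junk_len <- rep(c(60L, 160L), length.out = cfg$n_junk_asvs)
      junk <- tibble::tibble(
        asv_id = sprintf("junk%02d", seq_len(cfg$n_junk_asvs)),
        taxid = NA_integer_,
        source = "off_target",
        length = junk_len,
        sequence = .random_seq(cfg$n_junk_asvs, junk_len),
        reverse_oriented = FALSE,
        ambiguous = FALSE
      )
      asvs <- dplyr::bind_rows(asvs, junk)
    }

    structure(
      list(samples = samples, composition = composition, asvs = asvs,
           config = cfg,
           seeds = list(mb = cfg$seed + 101L, mg = cfg$seed + 202L)),
      class = "sedacomp_record"
    )
  })
}

#' @export
print.sedacomp_record <- function(x, ...) {
  cat("<sedacomp_record> ", nrow(x$samples), " samples (",
      min(x$samples$age), "-", max(x$samples$age), " cal BP), ",
      sum(!is.na(x$asvs$taxid)), " taxa\n", sep = "")
  invisible(x)
}

#' Emit the metabarcoding arm of a simulated record
#'
#' Turns the true record into raw ASV-by-replicate count tables the way an
#' amplicon experiment would see them. For each taxon and sample the
#' amplifiable fraction is the geometric-tail probability that a surviving
#' fragment spans the amplicon; each PCR replicate then detects the taxon
#' with the occupancy probability of [detection_probability()]. Replicate
#' sequencing depth is log-normal and reads are shared multinomially among
#' detected ASVs (plus a small off-target floor, so even empty replicates
#' return reads). Negative-control replicates receive sparse contaminant
#' counts; a fraction of taxa is emitted in reverse orientation; spurious
#' singletons are injected at a configured rate.
#'
#' @param record A [simulate_record()] result.
#' @param config Optional [sim_config()]; defaults to the record's own.
#' @return A list with `forward` and `reverse` long replicate tables
#'   (columns `asv_id`, `sequence`, `replicate_id`, `sample_id`, `role`,
#'   `count`), `asv_hits` (per-ASV candidate taxonomy hits with identity and
#'   coverage), and `fasta` (ASV id and sequence).
#' @export
emit_metabarcoding <- function(record, config = record$config) {
  stopifnot(inherits(record, "sedacomp_record"))
  cfg <- config
  withr::with_seed(record$seeds$mb, {
    samples <- record$samples
    asvs <- record$asvs
    real <- asvs[!is.na(asvs$taxid), ]
    junk <- asvs[is.na(asvs$taxid), ]

    reps <- tidyr::expand_grid(
      sample_id = samples$sample_id,
      rep = seq_len(cfg$n_pcr_replicates)
    ) |>
      dplyr::mutate(
        replicate_id = sprintf("%s_r%d", .data$sample_id, .data$rep),
        role = "sample"
      )
    neg <- purrr::imap_dfr(as.list(cfg$n_negatives), function(n, role) {
      if (n == 0) return(NULL)
      tibble::tibble(
        sample_id = paste0("ctl_", sub("_negative", "", role)),
        rep = seq_len(n),
        replicate_id = sprintf("ctl_%s_r%d", sub("_negative", "", role),
                               seq_len(n)),
        role = role
      )
    })

    comp <- record$composition
    cells <- list()
    for (i in seq_len(nrow(reps))) {
      s <- reps$sample_id[i]
      rows <- comp[comp$sample_id == s, ]
      rows <- rows[match(real$taxid, rows$taxid), ]
      af <- amplifiable_fraction(real$length, rows$lambda_mb)
      p_det <- detection_probability(rows$rel_mb, af, cfg$gamma_amp)
      det <- stats::runif(nrow(real)) < p_det
      total <- round(stats::rlnorm(1, cfg$replicate_reads_meanlog,
                                   cfg$replicate_reads_sdlog))
      wts <- c(rows$rel_mb * af * det, rep(0.01, nrow(junk)))
      if (sum(wts) == 0) next  # nothing amplified in this replicate
      counts <- as.vector(stats::rmultinom(1, total, wts))
      ids <- c(real$asv_id, junk$asv_id)
      keep <- counts > 0
      if (!any(keep)) next
      cells[[i]] <- tibble::tibble(
        asv_id = ids[keep], replicate_id = reps$replicate_id[i],
        sample_id = s, role = "sample", count = counts[keep]
      )
    }
    tab <- dplyr::bind_rows(cells)

    # spurious singletons in empty experimental cells
    if (cfg$singleton_rate > 0) {
      grid <- tidyr::expand_grid(asv_id = real$asv_id,
                                 replicate_id = reps$replicate_id)
      grid <- dplyr::anti_join(grid, tab, by = c("asv_id", "replicate_id"))
      hit <- stats::runif(nrow(grid)) < cfg$singleton_rate
      if (any(hit)) {
        add <- grid[hit, ]
        add$sample_id <- reps$sample_id[match(add$replicate_id,
                                              reps$replicate_id)]
        add$role <- "sample"
        add$count <- 1
        tab <- dplyr::bind_rows(tab, add)
      }
    }

    # negative controls: sparse modern contaminant carry-over
    if (nrow(neg) > 0 && cfg$contam_rate > 0) {
      contam <- real[real$source == "modern_contaminant", ]
      if (nrow(contam) > 0) {
        negcells <- tidyr::expand_grid(
          asv_id = contam$asv_id, replicate_id = neg$replicate_id
        )
        negcells$count <- stats::rpois(nrow(negcells), cfg$contam_rate)
        negcells$sample_id <- neg$sample_id[match(negcells$replicate_id,
                                                  neg$replicate_id)]
        negcells$role <- neg$role[match(negcells$replicate_id,
                                        neg$replicate_id)]
        tab <- dplyr::bind_rows(tab, negcells[negcells$count > 0, ])
      }
    }

    tab$sequence <- asvs$sequence[match(tab$asv_id, asvs$asv_id)]
    tab <- tab[, c("asv_id", "sequence", "replicate_id", "sample_id",
                   "role", "count")]

    # split reverse-oriented taxa into a second table with revcomp sequences
    rev_ids <- asvs$asv_id[asvs$reverse_oriented]
    fwd <- tab
    rev <- tab[0, ]
    if (length(rev_ids) > 0) {
      in_rev <- tab$asv_id %in% rev_ids
      moved <- tab[in_rev, ]
      moved$rev_count <- stats::rbinom(nrow(moved), moved$count, 0.5)
      rev <- moved[moved$rev_count > 0, ]
      if (nrow(rev) > 0) {
        rev$count <- rev$rev_count
        rev$asv_id <- paste0(rev$asv_id, "_rc")
        rev$sequence <- .revcomp(rev$sequence)
      }
      rev$rev_count <- NULL
      fwd_counts <- tab
      fwd_counts$count[in_rev] <- moved$count - moved$rev_count
      fwd <- fwd_counts[fwd_counts$count > 0, ]
    }
    fwd <- dplyr::arrange(fwd, .data$asv_id, .data$replicate_id)
    rev <- dplyr::arrange(rev, .data$asv_id, .data$replicate_id)

    # per-ASV candidate hits for LCA assignment
    hits <- purrr::pmap_dfr(
      list(real$asv_id, real$taxid, real$ambiguous),
      function(aid, tid, amb) {
        kids <- cfg$tree$nodes$taxid[cfg$tree$parent_of == tid &
                                       cfg$tree$nodes$taxid != tid]
        if (length(kids) == 0) kids <- tid
        first <- tibble::tibble(asv_id = aid, taxid = kids[1],
                                identity = 1.0, coverage = 1.0)
        if (amb && length(kids) >= 2) {
          first <- dplyr::bind_rows(first, tibble::tibble(
            asv_id = aid, taxid = kids[2], identity = 0.997, coverage = 1.0
          ))
        }
        first
      }
    )

    list(
      forward = tibble::as_tibble(fwd),
      reverse = tibble::as_tibble(rev),
      asv_hits = hits,
      fasta = dplyr::bind_rows(
        tibble::tibble(asv_id = fwd$asv_id, sequence = fwd$sequence),
        tibble::tibble(asv_id = rev$asv_id, sequence = rev$sequence)
      ) |> dplyr::distinct()
    )
  })
}

#' Emit the metagenomic arm of a simulated record
#'
#' Generates a per-read hit table. Reads are multinomially assigned to taxa
#' by true relative abundance, thinned by the probability that a fragment
#' falls inside the recoverable length window (short-fragment-optimised
#' extraction loses long modern fragments; the mapper floor loses fragments
#' under `capture_min` bp). Each retained read receives a truncated-geometric
#' length, an identity (mostly inside the 0.95-1.00 analysis band), and
#' positional C-to-T / mirrored G-to-A mismatches drawn per position `x` with
#' probability `A_true (1-q)^(x-1) + c`. A configurable fraction of reads
#' carries a second congeneric hit to exercise per-read LCA.
#'
#' @param record A [simulate_record()] result.
#' @param config Optional [sim_config()]; defaults to the record's own.
#' @param max_sim_pos Deepest read position at which damage is simulated
#'   (beyond it the signal is indistinguishable from background).
#' @return A hit-table tibble with columns `read_id`, `sample_id`, `taxid`,
#'   `identity`, `read_length`, `ct_offsets`, `ga_offsets` (comma-separated
#'   1-based offsets, empty string when none).
#' @export
emit_metagenomics <- function(record, config = record$config,
                              max_sim_pos = 30L) {
  stopifnot(inherits(record, "sedacomp_record"))
  cfg <- config
  withr::with_seed(record$seeds$mg, {
    out <- vector("list", nrow(record$samples))
    lens <- cfg$capture_min:cfg$capture_max
    for (i in seq_len(nrow(record$samples))) {
      s <- record$samples$sample_id[i]
      lam <- record$samples$lambda[i]
      rows <- record$composition[record$composition$sample_id == s, ]
      lam_t <- ifelse(rows$source == "modern_contaminant", cfg$lambda0, lam)
      n_tax <- as.vector(stats::rmultinom(1, cfg$mg_reads, rows$rel_mg))
      f <- .capture_fraction(lam_t, cfg$capture_min, cfg$capture_max)
      n_keep <- stats::rbinom(length(n_tax), n_tax, f)
      if (sum(n_keep) == 0) next
      taxid <- rep(rows$taxid, n_keep)
      a_true <- rep(rows$a_true, n_keep)
      lam_read <- rep(lam_t, n_keep)
      n <- length(taxid)

      # truncated geometric lengths inside the capture window
      len <- integer(n)
      for (ul in unique(lam_read)) {
        idx <- which(lam_read == ul)
        p <- 1 / ul
        pr <- (1 - p)^(lens - 1)
        len[idx] <- sample(lens, length(idx), replace = TRUE, prob = pr)
      }

      inband <- stats::runif(n) < cfg$mg_inband_rate
      identity <- ifelse(inband, stats::runif(n, 0.955, 1),
                         stats::runif(n, 0.90, 0.9499))

      npos <- min(max_sim_pos, max(len))
      p_x <- outer(a_true, (1 - cfg$q)^(seq_len(npos) - 1)) + cfg$c
      hit_ct <- matrix(stats::runif(n * npos), n, npos) < p_x
      hit_ga <- matrix(stats::runif(n * npos), n, npos) < p_x
      mask <- outer(len, seq_len(npos), ">=")
      ct <- .offsets_to_string(hit_ct & mask)
      ga <- .offsets_to_string(hit_ga & mask)

      read_id <- sprintf("%s_read%06d", s, seq_len(n))
      # primary species-level hit; some reads gain a congeneric second hit
      kids <- lapply(rows$taxid, function(tid) {
        k <- cfg$tree$nodes$taxid[cfg$tree$parent_of == tid &
                                    cfg$tree$nodes$taxid != tid]
        if (length(k) == 0) tid else k
      })
      kid1 <- vapply(kids, `[[`, 1L, 1L)
      kid2 <- vapply(kids, function(k) if (length(k) >= 2) k[2] else NA_integer_, 1L)
      tax_idx <- rep(seq_len(nrow(rows)), n_keep)
      pick2 <- stats::runif(n) < 0.5
      primary <- ifelse(pick2 & !is.na(kid2[tax_idx]),
                        kid2[tax_idx], kid1[tax_idx])
      tab <- tibble::tibble(
        read_id = read_id, sample_id = s, taxid = as.integer(primary),
        identity = round(identity, 4), read_length = len,
        ct_offsets = ct, ga_offsets = ga
      )
      amb <- stats::runif(n) < cfg$mg_ambig_rate & !is.na(kid2[tax_idx])
      if (any(amb)) {
        second <- ifelse(primary[amb] == kid1[tax_idx][amb],
                         kid2[tax_idx][amb], kid1[tax_idx][amb])
        tab2 <- tab[amb, ]
        tab2$taxid <- as.integer(second)
        tab2$identity <- round(pmax(0.95, tab2$identity - 0.002), 4)
        tab <- dplyr::bind_rows(tab, tab2)
      }
      out[[i]] <- tab
    }
    dplyr::bind_rows(out) |>
      dplyr::arrange(.data$read_id, .data$taxid)
  })
}

# logical matrix of per-position mismatch hits -> comma strings of offsets
.offsets_to_string <- function(m) {
  strs <- rep("", nrow(m))
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    agg <- tapply(idx[, "col"], idx[, "row"],
                  function(v) paste(sort(v), collapse = ","))
    strs[as.integer(names(agg))] <- unname(agg)
  }
  strs
}

#' Parse comma-separated offset strings into integer vectors
#' @param x Character vector, e.g. `"1,3,7"`; empty strings give empty sets.
#' @return A list of integer vectors.
#' @export
parse_offsets <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ","),
         function(v) as.integer(v[v != ""]))
}
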