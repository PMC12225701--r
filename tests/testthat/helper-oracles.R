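# Independent oracles and fixture builders shared across the suite.
# These deliberately use different algorithms from the package internals.

# LCA by root-path intersection: intersect the root->node paths and take the
# last element common to all of them.
oracle_lca <- function(tree, ids) {
  paths <- lapply(ids, function(id) lineage(tree, id)$taxid)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# rank ancestor by brute-force lineage walk
oracle_rank_ancestor <- function(tree, id, rank) {
  lin <- lineage(tree, id)
  hit <- lin$taxid[lin$rank == rank]
  if (length(hit) == 0) NA_integer_ else hit[length(hit)]
}

# random rooted tree: node 1 is the root, each later node attaches to a
# uniformly chosen earlier node
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(seq_len(n - 1L) + 1L,
                           function(i) sample.int(i - 1L, 1L), 1L))
    ranks <- sample(c("no rank", "superkingdom", "kingdom", "phylum",
                      "class", "genus", "species"), n, replace = TRUE)
    ranks[1] <- "no rank"
    taxonomy(tibble::tibble(
      taxid = seq_len(n), parent = parent, rank = ranks,
      name = paste0("node", seq_len(n))
    ))
  })
}

# long replicate table from a wide count matrix (rows = ASVs, cols =
# replicates); zeros are kept implicit
long_table <- function(counts, roles, sample_ids = NULL, sequences = NULL) {
  asv_ids <- rownames(counts)
  rep_ids <- colnames(counts)
  if (is.null(sequences)) {
    sequences <- stats::setNames(
      vapply(seq_along(asv_ids),
             function(i) paste(rep("A", 100), collapse = ""), ""),
      asv_ids
    )
  }
  if (is.null(sample_ids)) {
    sample_ids <- stats::setNames(
      ifelse(roles == "sample", sub("_r[0-9]+$", "", rep_ids), "ctl"),
      rep_ids
    )
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble::tibble(
    asv_id = asv_ids[idx[, 1]],
    sequence = unname(sequences[asv_ids[idx[, 1]]]),
    replicate_id = rep_ids[idx[, 2]],
    sample_id = unname(sample_ids[rep_ids[idx[, 2]]]),
    role = unname(roles[rep_ids[idx[, 2]]]),
    count = counts[idx]
  )
}

# wide count matrix from a long replicate table (missing cells = 0)
wide_table <- function(tbl, asv_ids = NULL, rep_ids = NULL) {
  if (is.null(asv_ids)) asv_ids <- sort(unique(tbl$asv_id))
  if (is.null(rep_ids)) rep_ids <- sort(unique(tbl$replicate_id))
  m <- matrix(0, length(asv_ids), length(rep_ids),
              dimnames = list(asv_ids, rep_ids))
  m[cbind(match(tbl$asv_id, asv_ids), match(tbl$replicate_id, rep_ids))] <-
    tbl$count
  m
}

# cell-wise brute-force of the negative-floor rule on a wide matrix
oracle_negative_floor <- function(counts, neg_cols) {
  floors <- if (length(neg_cols) > 0) {
    apply(counts[, neg_cols, drop = FALSE], 1, max)
  } else {
    rep(0, nrow(counts))
  }
  out <- counts[, setdiff(colnames(counts), neg_cols), drop = FALSE]
  for (a in rownames(out)) {
    out[a, out[a, ] < floors[a]] <- 0
  }
  out
}

# exact one-sided Mantel p by full enumeration of all permutations (small n)
oracle_mantel_exact <- function(d1, d2) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  n <- nrow(m1)
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  perms <- .permutations(n)
  r_perm <- apply(perms, 1, function(p) {
    stats::cor(m1[ut], m2[p, p][ut])
  })
  list(r = r_obs, p = mean(r_perm >= r_obs - 1e-12))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# config for fast end-to-end runs in tests: lighter amplicon sequencing,
# metagenomic depth kept at its default so damage calibration stays viable
small_config <- function(seed, ...) {
  sim_config(
    seed = seed,
    replicate_reads_meanlog = log(3e4),
    ...
  )
}
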