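#' Build a taxonomy tree from a node table
#'
#' A taxonomy tree is the backbone for lowest-common-ancestor (LCA) read and
#' ASV assignment and for genus-level aggregation. It is stored as a validated
#' node table plus fast parent/rank/name lookups keyed by taxon id.
#'
#' @param nodes A data frame with columns `taxid`, `parent`, `rank`, `name`
#'   (`taxid` and `parent` integer-valued; the root is the single node with
#'   `parent == taxid`).
#' @return An object of class `taxonomy` wrapping the node tibble.
#' @details Validation enforces: exactly one root, no duplicate ids, every
#'   non-root parent present in the table, and no cycles. Unranked
#'   intermediate nodes (`rank = "no rank"`) are permitted; rank queries skip
#'   them.
#' @examples
#' tax <- taxonomy(data.frame(
#'   taxid = c(1L, 2L, 3L), parent = c(1L, 1L, 2L),
#'   rank = c("no rank", "genus", "species"),
#'   name = c("root", "GenusA", "a1")
#' ))
#' lca(tax, c(3L, 2L))
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  req <- c("taxid", "parent", "rank", "name")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    stop("taxonomy node table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)[req]
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  if (anyNA(nodes$taxid) || anyNA(nodes$parent)) {
    stop("non-integer taxid or parent in taxonomy table", call. = FALSE)
  }
  dup <- nodes$taxid[duplicated(nodes$taxid)]
  if (length(dup) > 0) {
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) != 1) {
    stop("taxonomy must have exactly one root (parent == taxid); found ",
         length(root), call. = FALSE)
  }
  orphan <- setdiff(nodes$parent, nodes$taxid)
  if (length(orphan) > 0) {
    stop("orphan node(s): parent id(s) ", paste(orphan, collapse = ", "),
         " absent from table", call. = FALSE)
  }

  parent_of <- stats::setNames(nodes$parent, nodes$taxid)
  # depth by iterative parent-following; a cycle never reaches the root
  depth <- .tax_depths(nodes$taxid, parent_of, root)

  structure(
    list(
      nodes = nodes,
      root = root,
      parent_of = parent_of,
      rank_of = stats::setNames(nodes$rank, nodes$taxid),
      name_of = stats::setNames(nodes$name, nodes$taxid),
      depth_of = depth
    ),
    class = "taxonomy"
  )
}

# depths from root (root = 0); errors on cycles
.tax_depths <- function(ids, parent_of, root) {
  n <- length(ids)
  depth <- stats::setNames(rep(NA_integer_, n), ids)
  depth[as.character(root)] <- 0L
  for (id in ids) {
    if (!is.na(depth[as.character(id)])) next
    path <- character(0)
    cur <- id
    while (is.na(depth[as.character(cur)])) {
      if (as.character(cur) %in% path) {
        stop("cycle detected in taxonomy involving taxid ", cur, call. = FALSE)
      }
      path <- c(path, as.character(cur))
      cur <- parent_of[[as.character(cur)]]
      if (length(path) > n) {
        stop("cycle detected in taxonomy involving taxid ", id, call. = FALSE)
      }
    }
    base <- depth[[as.character(cur)]]
    depth[rev(path)] <- base + seq_along(path)
  }
  depth
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      " (", x$name_of[[as.character(x$root)]], ")\n", sep = "")
  invisible(x)
}

.assert_taxonomy <- function(tree) {
  if (!inherits(tree, "taxonomy")) {
    stop("expected a taxonomy object; see taxonomy()", call. = FALSE)
  }
}

.assert_known <- function(tree, ids) {
  unknown <- setdiff(ids, tree$nodes$taxid)
  if (length(unknown) > 0) {
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

#' Load a taxonomy from file
#'
#' Reads either a 4-column tab-separated table with header
#' `taxid  parent  rank  name`, or the NCBI taxonomy dump dialect
#' (`nodes.dmp` with fields separated by `\\t|\\t`, names supplied through a
#' companion `names.dmp` restricted to scientific names).
#'
#' @param path Path to the TSV node table or to `nodes.dmp`.
#' @param names_path Optional path to `names.dmp` (NCBI dialect only).
#' @return A [taxonomy] object.
#' @export
load_taxonomy <- function(path, names_path = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("\t\\|", first)) {
    nodes_raw <- readLines(path)
    fields <- strsplit(sub("\t\\|$", "", nodes_raw), "\t\\|\t")
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad) > 0) {
      stop("malformed nodes.dmp line(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    nodes <- tibble::tibble(
      taxid = as.integer(vapply(fields, `[[`, "", 1L)),
      parent = as.integer(vapply(fields, `[[`, "", 2L)),
      rank = vapply(fields, `[[`, "", 3L),
      name = NA_character_
    )
    if (!is.null(names_path)) {
      nm_raw <- readLines(names_path)
      nm_fields <- strsplit(sub("\t\\|$", "", nm_raw), "\t\\|\t")
      nm <- tibble::tibble(
        taxid = as.integer(vapply(nm_fields, `[[`, "", 1L)),
        name = vapply(nm_fields, `[[`, "", 2L),
        class = vapply(nm_fields, function(f) f[[length(f)]], "")
      )
      nm <- nm[nm$class == "scientific name", c("taxid", "name")]
      nodes$name <- nm$name[match(nodes$taxid, nm$taxid)]
    }
    nodes$name[is.na(nodes$name)] <- paste0("taxid_", nodes$taxid[is.na(nodes$name)])
  } else {
    nodes <- readr::read_tsv(path, col_types = readr::cols(
      taxid = readr::col_integer(), parent = readr::col_integer(),
      rank = readr::col_character(), name = readr::col_character()
    ))
    prob <- readr::problems(nodes)
    if (nrow(prob) > 0) {
      stop("taxonomy TSV parse error at line(s) ",
           paste(unique(prob$row), collapse = ", "), call. = FALSE)
    }
  }
  taxonomy(nodes)
}

#' Lineage of a taxon
#'
#' Ordered path of taxon ids from the root down to `id`.
#'
#' @param tree A [taxonomy].
#' @param id A single taxon id.
#' @return A tibble with columns `taxid`, `rank`, `name`, ordered root first.
#' @export
lineage <- function(tree, id) {
  .assert_taxonomy(tree)
  .assert_known(tree, id)
  path <- integer(0)
  cur <- as.integer(id)
  repeat {
    path <- c(cur, path)
    if (cur == tree$root) break
    cur <- tree$parent_of[[as.character(cur)]]
  }
  tibble::tibble(
    taxid = path,
    rank = unname(tree$rank_of[as.character(path)]),
    name = unname(tree$name_of[as.character(path)])
  )
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node ancestral to (or equal to) every input id. Sets spanning
#' the root return the root, matching the conservative semantics of LCA-based
#' read classifiers.
#'
#' @param tree A [taxonomy].
#' @param ids Non-empty vector of taxon ids.
#' @return A single taxon id.
#' @details Implemented by depth-lifting: the deeper of two nodes is walked up
#'   to the depth of the shallower, then both are walked up in lockstep until
#'   they meet; the pairwise LCA is folded over the input set.
#' @export
lca <- function(tree, ids) {
  .assert_taxonomy(tree)
  ids <- unique(as.integer(ids))
  if (length(ids) == 0) stop("lca() needs at least one taxon id", call. = FALSE)
  .assert_known(tree, ids)
  Reduce(function(a, b) .lca2(tree, a, b), ids)
}

.lca2 <- function(tree, a, b) {
  da <- tree$depth_of[[as.character(a)]]
  db <- tree$depth_of[[as.character(b)]]
  while (da > db) { a <- tree$parent_of[[as.character(a)]]; da <- da - 1L }
  while (db > da) { b <- tree$parent_of[[as.character(b)]]; db <- db - 1L }
  while (a != b) {
    a <- tree$parent_of[[as.character(a)]]
    b <- tree$parent_of[[as.character(b)]]
  }
  a
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage towards the root until a node of the requested rank is
#' found; unranked ("no rank") intermediates are skipped. A node of the
#' requested rank returns itself.
#'
#' @param tree A [taxonomy].
#' @param id A single taxon id.
#' @param rank Rank label, e.g. `"genus"`.
#' @return The taxon id of the ancestor at `rank`, or `NA` if the lineage has
#'   no node of that rank.
#' @export
rank_ancestor <- function(tree, id, rank) {
  .assert_taxonomy(tree)
  .assert_known(tree, id)
  cur <- as.integer(id)
  repeat {
    if (identical(tree$rank_of[[as.character(cur)]], rank)) return(cur)
    if (cur == tree$root) return(NA_integer_)
    cur <- tree$parent_of[[as.character(cur)]]
  }
}

#' Does a taxon belong to the reference plant clade?
#'
#' True iff `id` descends from (or is) the designated plant clade
#' (Viridiplantae in the default simulated taxonomy) and descends from none
#' of the excluded clades. The exclusion list is how marine plants such as
#' eelgrass (*Zostera*) are kept out of the terrestrial-plant damage
#' calibration.
#'
#' @param tree A [taxonomy].
#' @param id A single taxon id.
#' @param plant_clade Taxon id of the plant clade root.
#' @param exclusions Integer vector of excluded clade ids (default none).
#' @return Logical.
#' @export
is_reference_plant <- function(tree, id, plant_clade, exclusions = integer(0)) {
  .assert_taxonomy(tree)
  .assert_known(tree, c(id, plant_clade, exclusions))
  anc <- lineage(tree, id)$taxid
  (plant_clade %in% anc) && !any(exclusions %in% anc)
}
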