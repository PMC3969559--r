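## Bootstrap support statistics for the branching position of a LECA clade:
## NBS (node bootstrap support of the tripartition at the base of the
## eukaryotic stem), SGS (sister-group stability), taxon monophyly support,
## the near-universal cluster filter, and SGS threshold calibration.

.check_same_leaves <- function(ref_labels, trees, what = "bootstrap tree") {
  for (i in seq_along(trees))
    if (!setequal(trees[[i]]$tip.label, ref_labels))
      stop(what, " ", i, " does not share the reference leaf set")
  invisible(TRUE)
}

#' Node bootstrap support (NBS) at the base of a clade
#'
#' The NBS of a LECA clade is the percentage of bootstrap replicate trees
#' containing the tripartition at the node where the clade's stem meets the
#' rest of the ML tree -- equivalently, in which the three bipartitions
#' adjacent to that node co-occur. Replicates in which the clade is not a
#' clan (eukaryotes paraphyletic) necessarily lack the tripartition and
#' contribute zero.
#'
#' @param ml_tree The ML `phylo`; `clade_leaves` must be one of its clans.
#' @param bootstrap_trees Replicate trees sharing the ML leaf set.
#' @param clade_leaves Leaf labels of the clade.
#' @return Percentage in `[0, 100]`.
#' @export
nbs <- function(ml_tree, bootstrap_trees, clade_leaves) {
  if (length(bootstrap_trees) < 1L) stop("no bootstrap trees")
  .check_same_leaves(ml_tree$tip.label, bootstrap_trees)
  tri <- tripartition_at_base(ml_tree, clade_leaves)
  hits <- vapply(bootstrap_trees, has_tripartition, logical(1), tri = tri)
  100 * mean(hits)
}

#' Jaccard similarity of two leaf sets
#' @param a,b Character vectors.
#' @return `|a` \eqn{\cap} `b| / |a` \eqn{\cup} `b|`.
#' @export
jaccard_similarity <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Sister-group stability (SGS) of a clade across bootstrap replicates
#'
#' For each replicate tree the sister group of the clade is extracted (the
#' smaller of the two prokaryotic subtrees flanking the node at the base of
#' the clade); the SGS is the mean pairwise similarity of these sister sets
#' over all unordered replicate pairs:
#' \deqn{SGS = \frac{2}{N(N-1)} \sum_{i<j} s(G_i, G_j)}
#' with `s` the Jaccard index by default. Whenever the clade is paraphyletic
#' (or its attachment multifurcating) in replicate *i* or *j*, the pair
#' contributes 0. The score runs from 0 (complete disjunction of sister
#' groups across replicates) to 1 (absolute stability).
#'
#' @inheritParams nbs
#' @param similarity Set-similarity function taking two character vectors
#'   (default [jaccard_similarity()]); pluggable so alternative readings can
#'   be swapped in without touching callers.
#' @return Fraction in `[0, 1]` with attribute `sisters` (the per-replicate
#'   sister sets; `NULL` where undefined).
#' @export
sgs <- function(bootstrap_trees, clade_leaves, similarity = jaccard_similarity) {
  N <- length(bootstrap_trees)
  if (N < 2L) stop("SGS needs at least 2 bootstrap trees")
  .check_same_leaves(bootstrap_trees[[1L]]$tip.label, bootstrap_trees[-1L])
  sisters <- lapply(bootstrap_trees, function(tr) {
    if (!is_clan(tr, clade_leaves)) return(NULL)
    g <- sister_group(tr, clade_leaves)
    if (isTRUE(attr(g, "unresolved"))) NULL else as.character(g)
  })
  total <- 0
  for (i in seq_len(N - 1L)) {
    gi <- sisters[[i]]
    if (is.null(gi)) next
    for (j in seq.int(i + 1L, N)) {
      gj <- sisters[[j]]
      if (!is.null(gj)) total <- total + similarity(gi, gj)
    }
  }
  structure(2 * total / (N * (N - 1L)), sisters = sisters)
}

#' Bootstrap support for the monophyly of a taxon
#'
#' Percentage of replicate trees in which the given leaves form a clan.
#'
#' @inheritParams nbs
#' @param taxon_leaves Non-empty character vector of leaf labels.
#' @return Percentage in `[0, 100]`.
#' @export
monophyly_support <- function(bootstrap_trees, taxon_leaves) {
  if (length(taxon_leaves) == 0L) stop("empty taxon set")
  if (length(bootstrap_trees) < 1L) stop("no bootstrap trees")
  100 * mean(vapply(bootstrap_trees, is_clan, logical(1),
                    leafset = taxon_leaves))
}

#' Near-universal cluster filter
#'
#' A gene family is near-universal when it contains representatives for at
#' least a given fraction (default 90%) of the reference species of both
#' Archaea and Bacteria. Only such families are informative about the
#' domain-level relationship of Eukarya to Archaea.
#'
#' @param cluster_species Either a character vector of species ids present in
#'   the family (domains looked up in `tax`), or a named list with
#'   components `Archaea` and `Bacteria`.
#' @param tax A [taxonomy_map()]; supplies the reference species totals per
#'   domain unless `totals` is given.
#' @param fraction Required coverage fraction, in `(0, 1]`.
#' @param totals Optional named vector `c(Archaea = , Bacteria = )` of
#'   reference species counts.
#' @return Logical scalar.
#' @export
near_universal_filter <- function(cluster_species, tax, fraction = 0.9,
                                  totals = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(totals)) {
    sp <- unique(tax[, c("species_id", "domain")])
    totals <- c(Archaea = sum(sp$domain == "Archaea"),
                Bacteria = sum(sp$domain == "Bacteria"))
  }
  if (!is.list(cluster_species)) {
    sp <- unique(tax[, c("species_id", "domain")])
    d <- sp$domain[match(cluster_species, sp$species_id)]
    cluster_species <- list(Archaea = cluster_species[d %in% "Archaea"],
                            Bacteria = cluster_species[d %in% "Bacteria"])
  }
  for (d in c("Archaea", "Bacteria")) {
    need <- ceiling(fraction * totals[[d]])
    if (length(unique(cluster_species[[d]])) < need) return(FALSE)
  }
  TRUE
}

#' Calibrate an SGS decision threshold on a reference gene set
#'
#' Given reference LECA clades whose true origin is known (e.g. genes
#' encoded in a mitochondrial genome, which must be of alphaproteobacterial
#' origin), finds the smallest SGS value `t` such that every reference clade
#' with SGS above `t` was classified to the expected group -- i.e. the
#' highest SGS among misclassified clades, or 0 when none is misclassified.
#' If no clade is correctly classified above that point the threshold is
#' unusable and flagged as such.
#'
#' @param reference A data.frame with columns `clade_id`, `sgs` (percent)
#'   and `group` (the assigned group).
#' @param expected_group The group every reference clade should be traced to.
#' @return An object of class `sgs_calibration`: list with `threshold`
#'   (SGS percent), `usable` (logical) and `table` (the reference table,
#'   sorted by decreasing SGS, with a `correct` column).
#' @export
calibrate_sgs_threshold <- function(reference, expected_group) {
  reference <- as.data.frame(reference, stringsAsFactors = FALSE)
  if (!all(c("clade_id", "sgs", "group") %in% names(reference)))
    stop("reference needs columns clade_id, sgs, group")
  if (nrow(reference) < 1L) stop("empty reference set")
  reference$correct <- reference$group == expected_group
  reference <- reference[order(-reference$sgs, reference$clade_id), ]
  rownames(reference) <- NULL
  wrong <- reference$sgs[!reference$correct]
  threshold <- if (length(wrong)) max(wrong) else 0
  usable <- any(reference$correct & reference$sgs > threshold)
  if (!usable) threshold <- max(reference$sgs)
  structure(list(threshold = threshold, usable = usable, table = reference,
                 expected_group = expected_group),
            class = "sgs_calibration")
}

#' @export
print.sgs_calibration <- function(x, ...) {
  cat("SGS calibration against expected group", x$expected_group, "\n")
  cat("  threshold =", x$threshold,
      if (x$usable) "(usable)" else "(UNUSABLE: no correct call above it)",
      "\n")
  print(x$table)
  invisible(x)
}

#' Full support report for one LECA clade
#'
#' Computes NBS, SGS and the ML-tree sister group in one pass.
#'
#' @inheritParams nbs
#' @return List of class `clade_support` with `nbs` (percent), `sgs`
#'   (fraction), `sgs_percent`, `g_ml` (ML sister leaf set), `n_replicates`
#'   and `sisters` (per-replicate sister sets).
#' @export
clade_support <- function(ml_tree, bootstrap_trees, clade_leaves) {
  s <- sgs(bootstrap_trees, clade_leaves)
  structure(list(
    nbs = nbs(ml_tree, bootstrap_trees, clade_leaves),
    sgs = as.numeric(s),
    sgs_percent = 100 * as.numeric(s),
    g_ml = as.character(sister_group(ml_tree, clade_leaves)),
    n_replicates = length(bootstrap_trees),
    sisters = attr(s, "sisters")), class = "clade_support")
}

#' @export
print.clade_support <- function(x, ...) {
  cat(sprintf("Clade support over %d replicates: NBS = %.1f%%, SGS = %.1f%%\n",
              x$n_replicates, x$nbs, x$sgs_percent))
  cat("  ML sister group:", paste(x$g_ml, collapse = ","), "\n")
  invisible(x)
}
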