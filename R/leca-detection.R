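## LECA-clade detection: maximal eukaryotic clans of a gene-family tree, an
## automated stand-in for manual removal of isolated prokaryotic "intruder"
## sequences, and the ancestrality rules deciding which eukaryotic clades
## trace back to the last eukaryotic common ancestor.

#' Maximal eukaryotic clans of a gene-family tree
#'
#' Returns every maximal clan of the (unrooted) tree whose leaves are all
#' eukaryotic according to the taxonomy. The clans are pairwise disjoint and
#' jointly cover all eukaryotic leaves; a tree with no eukaryotes yields an
#' empty list.
#'
#' @param tree A `phylo` object.
#' @param tax A [taxonomy_map()] covering all tree leaves.
#' @return List of sorted character vectors (one per clan).
#' @export
extract_euk_clades <- function(tree, tax) {
  labs <- tree$tip.label
  dom <- tax_domain(tax, labs)
  euks <- labs[dom == "Eukarya"]
  if (length(euks) == 0L) return(list())
  if (length(euks) == length(labs)) return(list(sort(labs)))
  if (length(labs) == 2L) return(list(euks))

  ## root at a prokaryotic tip: maximal eukaryote-pure rooted clades are then
  ## exactly the maximal eukaryotic clans of the unrooted tree
  prok <- labs[dom != "Eukarya"][1L]
  rt <- ape::root(.as_unrooted(tree), outgroup = prok, resolve.root = TRUE)
  labs2 <- rt$tip.label
  eukv <- tax_domain(tax, labs2) == "Eukarya"
  M <- clan_matrix(rt)
  pure <- rowSums(M[, !eukv, drop = FALSE]) == 0L
  nt <- length(labs2)
  parent <- integer(nt + rt$Nnode)
  parent[rt$edge[, 2L]] <- rt$edge[, 1L]
  root <- nt + 1L
  maximal <- which(pure & seq_along(pure) != root & !pure[pmax(parent, 1L)])
  lapply(maximal, function(v) sort(labs2[M[v, ]]))
}

#' Flag isolated prokaryotic intruders among eukaryotes
#'
#' Recent eukaryote-to-prokaryote transfers can leave one or two prokaryotic
#' sequences nested inside an otherwise eukaryotic region of the tree, making
#' the eukaryotes look paraphyletic. This heuristic flags every maximal
#' prokaryote-only clan of at most `max_intruder_size` leaves whose removal
#' would merge two or more eukaryotic clans jointly spanning at least
#' `min_supergroups` eukaryotic supergroups. To avoid the unrooted-tree
#' degeneracy in which the eukaryotes become a "clan" merely because only
#' one prokaryotic block remains (the complement of any single clan is a
#' clan), the before/after comparison is made in the rooted sense, with the
#' root held at a reference prokaryote outside the candidate clan. Flagged
#' leaves are only reported; pruning is the caller's decision (see
#' [run_pipeline()]'s `prune_intruders`).
#'
#' @inheritParams extract_euk_clades
#' @param max_intruder_size Largest prokaryotic clan considered an intruder
#'   (default 2).
#' @param min_supergroups Minimum number of distinct supergroups the merged
#'   eukaryotic clans must span (default 2).
#' @return Sorted character vector of flagged prokaryotic leaf labels
#'   (possibly empty).
#' @export
flag_intruders <- function(tree, tax, max_intruder_size = 2,
                           min_supergroups = 2) {
  if (max_intruder_size < 1) stop("max_intruder_size must be >= 1")
  labs <- tree$tip.label
  dom <- tax_domain(tax, labs)
  euks <- labs[dom == "Eukarya"]
  proks <- labs[dom != "Eukarya"]
  if (length(euks) == 0L || length(proks) == 0L) return(character(0))

  ## maximal prokaryote-only clans, via rooting at a eukaryotic tip
  if (length(labs) <= 3L) {
    prok_clans <- as.list(proks)
  } else {
    rt <- ape::root(.as_unrooted(tree), outgroup = euks[1L],
                    resolve.root = TRUE)
    labs2 <- rt$tip.label
    eukv <- tax_domain(tax, labs2) == "Eukarya"
    M <- clan_matrix(rt)
    pure <- rowSums(M[, eukv, drop = FALSE]) == 0L
    nt <- length(labs2)
    parent <- integer(nt + rt$Nnode)
    parent[rt$edge[, 2L]] <- rt$edge[, 1L]
    root <- nt + 1L
    maximal <- which(pure & seq_along(pure) != root & !pure[pmax(parent, 1L)])
    prok_clans <- lapply(maximal, function(v) sort(labs2[M[v, ]]))
  }

  ## maximal eukaryote-pure rooted clades, with the root held at `ref`
  euk_clades_rooted <- function(tr, ref) {
    if (ape::Ntip(tr) == 2L)
      return(as.list(setdiff(tr$tip.label, ref)))
    rt <- ape::root(.as_unrooted(tr), outgroup = ref, resolve.root = TRUE)
    labs2 <- rt$tip.label
    eukv <- tax_domain(tax, labs2) == "Eukarya"
    M <- clan_matrix(rt)
    pure <- rowSums(M[, !eukv, drop = FALSE]) == 0L
    nt <- length(labs2)
    parent <- integer(nt + rt$Nnode)
    parent[rt$edge[, 2L]] <- rt$edge[, 1L]
    maximal <- which(pure & seq_along(pure) != nt + 1L &
                       !pure[pmax(parent, 1L)])
    lapply(maximal, function(v) sort(labs2[M[v, ]]))
  }

  flagged <- character(0)
  for (P in prok_clans) {
    if (length(P) > max_intruder_size) next
    if (length(labs) - length(P) < 2L) next
    ref <- setdiff(proks, P)
    if (!length(ref)) next      # no prokaryote left to witness the merge
    ref <- sort(ref)[1L]
    old <- euk_clades_rooted(tree, ref)
    newt <- ape::drop.tip(.as_unrooted(tree), P)
    for (nc in euk_clades_rooted(newt, ref)) {
      merged <- Filter(function(oc) all(oc %in% nc), old)
      if (length(merged) < 2L) next
      sg <- unique(tax_supergroup(tax, unlist(merged)))
      if (length(sg) >= min_supergroups) {
        flagged <- c(flagged, P)
        break
      }
    }
  }
  sort(unique(flagged))
}

#' Which LECA ancestrality rules does a eukaryotic clade satisfy?
#'
#' A eukaryotic clade is inferred to trace back to LECA if it contains
#' sequences from at least: (R1) two Unikont species and two Plantae, (R2)
#' two Unikonts and two Chromalveolates, or (R3) two Plantae, two
#' Chromalveolates and one kinetoplastid. Species, not sequences, are
#' counted, so within-species paralogs do not inflate the counts. An empty
#' result means the clade is not LECA-traceable; note that a Unikont-only
#' clade (e.g. an opisthokont-specific gene family) never passes.
#'
#' @param leaves Character vector of eukaryotic leaf labels (non-eukaryotic
#'   labels are an error).
#' @param tax A [taxonomy_map()].
#' @return Character vector, a subset of `c("R1", "R2", "R3")`.
#' @export
passes_leca_criteria <- function(leaves, tax) {
  if (length(leaves) == 0L) stop("empty leaf set")
  dom <- tax_domain(tax, leaves)
  if (any(dom != "Eukarya"))
    stop("non-eukaryotic leaf in LECA-criteria check: ",
         paste(leaves[dom != "Eukarya"], collapse = ", "))
  sp <- tax_species(tax, leaves)
  sg <- tax_supergroup(tax, leaves)
  keep <- !duplicated(sp)
  cnt <- table(factor(sg[keep], levels = euk_supergroups()))
  rules <- character(0)
  if (cnt[["Unikonts"]] >= 2 && cnt[["Plantae"]] >= 2) rules <- c(rules, "R1")
  if (cnt[["Unikonts"]] >= 2 && cnt[["Chromalveolates"]] >= 2)
    rules <- c(rules, "R2")
  if (cnt[["Plantae"]] >= 2 && cnt[["Chromalveolates"]] >= 2 &&
      cnt[["Kinetoplastids"]] >= 1) rules <- c(rules, "R3")
  rules
}

#' Detect LECA clades in a gene-family tree
#'
#' Convenience wrapper: optionally prunes flagged prokaryotic intruders, then
#' extracts maximal eukaryotic clans and keeps those satisfying at least one
#' LECA ancestrality rule. Several LECA clades may coexist in one family
#' (ancient paralogy); each is an independent analysis unit.
#'
#' @inheritParams flag_intruders
#' @param prune_intruders If TRUE (default), leaves flagged by
#'   [flag_intruders()] are pruned before clan extraction.
#' @return A list with one element per LECA clade, each a list with
#'   `leaves` and `rules`; attributes `intruders` (flagged labels),
#'   `n_euk_clans` (count before the ancestrality filter) and `tree` (the
#'   possibly pruned tree actually analysed).
#' @export
detect_leca_clades <- function(tree, tax, max_intruder_size = 2,
                               min_supergroups = 2, prune_intruders = TRUE) {
  intr <- flag_intruders(tree, tax, max_intruder_size, min_supergroups)
  used <- tree
  if (prune_intruders && length(intr))
    used <- ape::drop.tip(.as_unrooted(tree), intr)
  clans <- extract_euk_clades(used, tax)
  out <- list()
  for (cl in clans) {
    rules <- passes_leca_criteria(cl, tax)
    if (length(rules))
      out[[length(out) + 1L]] <- list(leaves = cl, rules = rules)
  }
  attr(out, "intruders") <- intr
  attr(out, "n_euk_clans") <- length(clans)
  attr(out, "tree") <- used
  out
}
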