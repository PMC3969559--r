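## Taxonomy-aware "configuration" classification of a LECA clade's origin.
## The label depends not only on the identity of the sister group but on the
## taxonomic representativeness of the clans enclosing the eukaryotes, under
## a per-group system of minimum species counts.

.default_group_table <- function() {
  x <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
group domain sampled rule
Acidobacteria Bacteria 3 3
Actinobacteria Bacteria 15 HALF
Alphaproteobacteria Bacteria 10 HALF
Aquificae Bacteria 4 3
Bacilli Bacteria 9 HALF
Bacteroidetes Bacteria 15 HALF
Betaproteobacteria Bacteria 4 3
Chlamydiae Bacteria 3 3
Chlorobi Bacteria 5 4
Chloroflexi Bacteria 5 4
Clostridia Bacteria 9 HALF
Crenarchaeota Archaea 11 HALF
Cyanobacteria Bacteria 15 HALF
Deinococcus-Thermus Bacteria 2 NEVER
Deltaproteobacteria Bacteria 8 HALF
Dictyoglomi Bacteria 1 NEVER
Elusimicrobia Bacteria 2 NEVER
Epsilonproteobacteria Bacteria 5 3
Euryarchaeota Archaea 25 HALF
Fusobacteria Bacteria 1 NEVER
Gammaproteobacteria Bacteria 7 HALF
Gemmatimonadetes Bacteria 1 NEVER
Korarchaeota Archaea 1 NEVER
Mollicutes Bacteria 4 3
Nitrospirae Bacteria 1 NEVER
Planctomycetes Bacteria 3 3
Spirochaetes Bacteria 4 3
Thaumarchaeota Archaea 2 NEVER
Thermotogae Bacteria 4 3
UnclProteobacteria Bacteria 1 NEVER
Verrucomicrobia Bacteria 3 3
")
  x
}

.resolve_rule <- function(rule, sampled) {
  if (rule == "NEVER") return(NA_integer_)
  if (rule == "HALF") return(as.integer(ceiling(sampled / 2)))
  as.integer(rule)
}

#' Per-group species-representation thresholds
#'
#' The configuration system requires that the clan enclosing a LECA clade
#' represent a minimum number of distinct species of the assigned group. The
#' default table gives, per prokaryotic group, the number of species in the
#' reference genome sampling and the threshold rule: an integer, `HALF`
#' (at least half the sampled species, rounded up -- e.g. 8 of 15 for
#' Actinobacteria), or `NEVER` (the group is too sparsely sampled for a
#' group-level call ever to be made).
#'
#' @param overrides Optional data.frame with columns `group`, `sampled`,
#'   `rule` (and optionally `domain`) replacing or extending default rows.
#' @param domain_min Minimum distinct species for a domain-level
#'   (bacteria-/archaea-related) call (default 10).
#' @param three_domain_min Minimum species per prokaryotic domain for a
#'   three-domain call (default 10).
#' @return A data.frame of class `group_thresholds` with columns `group`,
#'   `domain`, `sampled`, `rule`, `min_required` (NA for `NEVER`), and
#'   attributes `domain_min` and `three_domain_min`.
#' @export
group_thresholds <- function(overrides = NULL, domain_min = 10,
                             three_domain_min = 10) {
  x <- .default_group_table()
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
    if (!all(c("group", "sampled", "rule") %in% names(overrides)))
      stop("overrides need columns group, sampled, rule")
    if (is.null(overrides$domain)) {
      i <- match(overrides$group, x$group)
      if (anyNA(i))
        stop("override for unknown group without a domain column: ",
             paste(overrides$group[is.na(i)], collapse = ", "))
      overrides$domain <- x$domain[i]
    }
    x <- x[!(x$group %in% overrides$group), ]
    x <- rbind(x, overrides[, c("group", "domain", "sampled", "rule")])
  }
  x$rule <- toupper(as.character(x$rule))
  x$min_required <- mapply(.resolve_rule, x$rule, x$sampled)
  x <- x[order(x$group), ]
  rownames(x) <- NULL
  attr(x, "domain_min") <- domain_min
  attr(x, "three_domain_min") <- three_domain_min
  class(x) <- c("group_thresholds", "data.frame")
  x
}

#' @rdname group_thresholds
#' @param path TSV file with columns `group`, `domain`, `sampled`, `rule`.
#' @export
read_group_thresholds <- function(path, domain_min = 10,
                                  three_domain_min = 10) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  group_thresholds(overrides = x, domain_min = domain_min,
                   three_domain_min = three_domain_min)
}

configuration_kinds <- function() {
  c("GROUP_RELATED", "BACTERIAL_DOMAIN_RELATED", "ARCHAEAL_DOMAIN_RELATED",
    "THREE_DOMAIN", "UNCLEAR", "PARAPHYLETIC")
}

.make_label <- function(kind, group = NA_character_, clan = NULL,
                        species_count = NA_integer_, note = NULL) {
  structure(list(kind = kind, group = group, clan = clan,
                 species_count = species_count, note = note),
            class = "configuration_label")
}

#' Short string form of a configuration label
#'
#' `"group:<name>"`, `"domain:Bacteria"`, `"domain:Archaea"`,
#' `"three_domain"`, `"unclear"` or `"paraphyletic"`.
#'
#' @param label A `configuration_label` (or a character already in string
#'   form, returned unchanged).
#' @return Character scalar.
#' @export
format_configuration <- function(label) {
  if (is.character(label)) return(label)
  switch(label$kind,
         GROUP_RELATED = paste0("group:", label$group),
         BACTERIAL_DOMAIN_RELATED = "domain:Bacteria",
         ARCHAEAL_DOMAIN_RELATED = "domain:Archaea",
         THREE_DOMAIN = "three_domain",
         UNCLEAR = "unclear",
         PARAPHYLETIC = "paraphyletic")
}

#' @export
print.configuration_label <- function(x, ...) {
  cat("Configuration:", format_configuration(x))
  if (!is.na(x$species_count))
    cat(" (", x$species_count, " species in evidence clan)", sep = "")
  cat("\n")
  invisible(x)
}

## All clans of the tree containing the clade, as logical tip vectors over
## tree$tip.label (includes the full leaf set).
.enclosing_sides <- function(tree, memb) {
  n <- length(tree$tip.label)
  M <- clan_matrix(tree)
  root <- n + 1L
  sides <- list(rep(TRUE, n))
  seen <- character(1)
  seen[1] <- paste(which(rep(TRUE, n)), collapse = ",")
  for (v in seq_len(nrow(M))) {
    if (v == root) next
    side <- if (all(M[v, ] | !memb) && any(M[v, ] & memb)) M[v, ]
            else if (!any(M[v, ] & memb)) !M[v, ]
            else next
    key <- paste(which(side), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sides[[length(sides) + 1L]] <- side
  }
  sides
}

#' Classify the origin configuration of a LECA clade in one tree
#'
#' Assigns one of six labels. If the clade's representatives are not a clan
#' of the tree, the tree is `PARAPHYLETIC`. Otherwise the clade is
#' *group-related* if it branches inside a clan whose prokaryotic members all
#' belong to one group and represent at least that group's threshold of
#' distinct species ([group_thresholds()]); *bacterial-* (or *archaeal-*)
#' *domain-related* if it branches inside a clan of purely bacterial
#' (archaeal) sequences representing at least `domain_min` species but no
#' group-level call is possible; `THREE_DOMAIN` if Eukarya, Bacteria and
#' Archaea are each clans with at least `three_domain_min` species per
#' prokaryotic domain; and `UNCLEAR` otherwise. "Branches inside a clan of X
#' sequences" is read existentially: some clan containing the clade has all
#' its prokaryotic members in X and enough species. If two taxa at the same
#' level are simultaneously eligible (the clade sits exactly between two
#' pure blocks), no call is made at that level and classification falls
#' through to the next.
#'
#' @param tree A `phylo` containing the clade plus prokaryotic sequences.
#' @param clade_leaves Leaf labels of the clade's representative sequences.
#' @param tax A [taxonomy_map()] covering all tree leaves.
#' @param thr A [group_thresholds()] table.
#' @return A `configuration_label`: list with `kind`, `group`, `clan`
#'   (evidence clan leaf set), `species_count`.
#' @export
classify_configuration <- function(tree, clade_leaves, tax,
                                   thr = group_thresholds()) {
  tree <- .as_unrooted(tree)
  labs <- tree$tip.label
  dom <- tax_domain(tax, labs)       # errors naming any missing leaf
  grp <- tax_group(tax, labs)
  spc <- tax_species(tax, labs)
  if (!any(dom != "Eukarya")) stop("tree contains no prokaryotic leaves")
  clade_leaves <- .check_leafset(tree, clade_leaves, "clade")
  if (!is_clan(tree, clade_leaves)) return(.make_label("PARAPHYLETIC"))

  memb <- labs %in% clade_leaves
  sides <- .enclosing_sides(tree, memb)
  prok <- dom != "Eukarya"

  ## per side: the unique prokaryotic group (or domain) if pure, and its
  ## distinct-species count
  best_group <- list()   # group -> c(count, size); max count, then min size
  best_domain <- list()
  for (side in sides) {
    p <- side & prok
    if (!any(p)) next
    gs <- unique(grp[p])
    if (length(gs) == 1L) {
      cnt <- length(unique(spc[p]))
      cur <- best_group[[gs]]
      if (is.null(cur) || cnt > cur$count ||
          (cnt == cur$count && sum(side) < cur$size))
        best_group[[gs]] <- list(count = cnt, size = sum(side), side = side)
    }
    ds <- unique(dom[p])
    if (length(ds) == 1L) {
      cnt <- length(unique(spc[p]))
      cur <- best_domain[[ds]]
      if (is.null(cur) || cnt > cur$count ||
          (cnt == cur$count && sum(side) < cur$size))
        best_domain[[ds]] <- list(count = cnt, size = sum(side), side = side)
    }
  }

  elig <- character(0)
  for (g in names(best_group)) {
    i <- match(g, thr$group)
    if (is.na(i)) next                       # unknown group: never eligible
    need <- thr$min_required[i]
    if (!is.na(need) && best_group[[g]]$count >= need) elig <- c(elig, g)
  }
  if (length(elig) == 1L) {
    ev <- best_group[[elig]]
    return(.make_label("GROUP_RELATED", group = elig,
                       clan = sort(labs[ev$side]),
                       species_count = ev$count))
  }
  note <- if (length(elig) > 1L)
    paste("ambiguous group-level eligibility:", paste(sort(elig), collapse = ", "))

  dmin <- attr(thr, "domain_min")
  delig <- character(0)
  for (d in intersect(names(best_domain), c("Bacteria", "Archaea")))
    if (best_domain[[d]]$count >= dmin) delig <- c(delig, d)
  if (length(delig) == 1L) {
    ev <- best_domain[[delig]]
    kind <- if (delig == "Bacteria") "BACTERIAL_DOMAIN_RELATED"
            else "ARCHAEAL_DOMAIN_RELATED"
    return(.make_label(kind, clan = sort(labs[ev$side]),
                       species_count = ev$count, note = note))
  }
  if (length(delig) > 1L)
    note <- paste(c(note, "both domains eligible"), collapse = "; ")

  tdm <- attr(thr, "three_domain_min")
  sets <- split(labs, dom)
  counts <- vapply(c("Archaea", "Bacteria"), function(d)
    length(unique(spc[dom == d])), integer(1))
  if (all(c("Archaea", "Bacteria", "Eukarya") %in% names(sets)) &&
      counts[["Archaea"]] >= tdm && counts[["Bacteria"]] >= tdm &&
      all(vapply(sets, function(s) is_clan(tree, s), logical(1))))
    return(.make_label("THREE_DOMAIN", species_count = sum(counts),
                       note = note))

  .make_label("UNCLEAR", note = note)
}

#' Naive sister-clade-identity classification
#'
#' The simple criterion the configuration system is designed to improve on:
#' the origin of a LECA clade is read off the taxonomic identity of its
#' sister group alone -- the sister's group if taxonomically uniform, else
#' its domain if uniform, else `"mixed"`. A single horizontally transferred
#' sequence sitting next to the eukaryotes is enough to mislead this
#' criterion into a confident group-level call.
#'
#' @inheritParams classify_configuration
#' @return Character scalar: a group name, a domain name, or `"mixed"`.
#' @export
classify_naive <- function(tree, clade_leaves, tax) {
  clade_leaves <- .check_leafset(tree, clade_leaves, "clade")
  if (!is_clan(tree, clade_leaves))
    stop("clade is paraphyletic; naive classification undefined")
  sis <- sister_group(tree, clade_leaves)
  gs <- unique(tax_group(tax, sis))
  if (length(gs) == 1L && !isTRUE(attr(sis, "unresolved"))) return(gs)
  ds <- unique(tax_domain(tax, sis))
  if (length(ds) == 1L) return(ds)
  "mixed"
}

## precedence for modal-label ties: group-related first (alphabetical within),
## then three-domain, then domain-related, then unclear, then paraphyletic
.label_order <- function(labels) {
  rank <- function(l) {
    if (startsWith(l, "group:")) 1
    else if (l == "three_domain") 2
    else if (startsWith(l, "domain:")) 3
    else if (l == "unclear") 4
    else 5
  }
  order(vapply(labels, rank, numeric(1)), labels)
}

#' Configuration profile of a LECA clade across bootstrap replicates
#'
#' Classifies every bootstrap tree and tabulates label frequencies (which sum
#' to one, `paraphyletic` included). The modal label is the most frequent
#' one; frequency ties are broken by specificity (group-related over
#' three-domain over domain-related over unclear over paraphyletic, then
#' alphabetically). Per-group association fractions (the fraction of
#' replicates assigned to each group) are reported alongside.
#'
#' @param bootstrap_trees A `multiPhylo` (or list of `phylo`) of replicate
#'   trees sharing the ML tree's leaf set.
#' @inheritParams classify_configuration
#' @return An object of class `configuration_profile`: list with
#'   `frequencies` (named numeric), `modal` (label string), `group_fractions`
#'   (named numeric) and `labels` (per-replicate label strings).
#' @export
bootstrap_configuration_profile <- function(bootstrap_trees, clade_leaves,
                                            tax, thr = group_thresholds()) {
  if (length(bootstrap_trees) < 1L) stop("need at least one bootstrap tree")
  cache <- new.env(parent = emptyenv())
  labels <- vapply(bootstrap_trees, function(tr) {
    key <- ape::write.tree(tr)
    if (!is.null(cache[[key]])) return(cache[[key]])
    lab <- format_configuration(
      classify_configuration(tr, clade_leaves, tax, thr))
    cache[[key]] <- lab
    lab
  }, character(1))
  freq <- table(labels) / length(labels)
  freq <- stats::setNames(as.numeric(freq), names(freq))
  freq <- freq[.label_order(names(freq))]
  modal <- names(freq)[which.max(freq)]   # freq already in precedence order
  is_grp <- startsWith(names(freq), "group:")
  gf <- stats::setNames(freq[is_grp], sub("^group:", "", names(freq)[is_grp]))
  structure(list(frequencies = freq, modal = modal,
                 group_fractions = gf, labels = unname(labels)),
            class = "configuration_profile")
}

#' @export
print.configuration_profile <- function(x, ...) {
  cat("Bootstrap configuration profile (", length(x$labels),
      " replicates); modal = ", x$modal, "\n", sep = "")
  for (l in names(x$frequencies))
    cat(sprintf("  %-28s %.2f\n", l, x$frequencies[[l]]))
  invisible(x)
}
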