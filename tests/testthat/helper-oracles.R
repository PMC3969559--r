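# Independent oracles used to validate the package's unrooted-tree
# combinatorics. Clan enumeration here goes through phangorn's split
# machinery (a separate implementation from the package's incidence-matrix
# code); sister/tripartition extraction is re-derived set-theoretically from
# the enumerated clans.

# all sides of all bipartitions, as sorted label vectors (non-empty, proper)
oracle_sides <- function(tree) {
  sp <- phangorn::as.splits(tree)
  labs <- attr(sp, "labels")
  sides <- lapply(sp, function(i) sort(labs[i]))
  sides <- c(sides, lapply(sides, function(s) sort(setdiff(labs, s))))
  sides <- Filter(function(s) length(s) > 0 && length(s) < length(labs),
                  sides)
  unique(sides)
}

oracle_is_clan <- function(tree, S) {
  S <- sort(S)
  n <- length(tree$tip.label)
  if (length(S) == 1L || length(S) == n) return(TRUE)
  any(vapply(oracle_sides(tree), identical, logical(1), y = S))
}

# the subtrees adjacent to the attachment node of clan C: the minimal clans
# X disjoint from C such that X union C is again a clan (or everything)
oracle_parts_at_base <- function(tree, C) {
  labs <- sort(tree$tip.label)
  C <- sort(C)
  sides <- oracle_sides(tree)
  all_clans <- unique(c(lapply(labs, identity), sides))
  is_cl <- function(S) {
    S <- sort(S)
    length(S) == 1L || length(S) == length(labs) ||
      any(vapply(sides, identical, logical(1), y = S))
  }
  cand <- Filter(function(X) length(intersect(X, C)) == 0L &&
                   is_cl(union(X, C)), all_clans)
  minimal <- Filter(function(X) {
    !any(vapply(cand, function(Y)
      length(Y) < length(X) && all(Y %in% X), logical(1)))
  }, cand)
  unique(minimal)
}

oracle_sister <- function(tree, C) {
  parts <- oracle_parts_at_base(tree, C)
  if (length(parts) == 1L) {
    p <- sort(parts[[1L]])
    # a single multi-leaf candidate (the bare complement) means no adjacent
    # subtree pairs with C into a clan: the attachment is multifurcating
    if (length(p) == 1L) return(structure(p, unresolved = FALSE))
    return(structure(p, unresolved = TRUE))
  }
  if (length(parts) > 2L)
    return(structure(sort(unique(unlist(parts))), unresolved = TRUE))
  a <- parts[[1L]]; b <- parts[[2L]]
  key <- function(s) paste(s, collapse = "\r")
  if (length(a) < length(b)) return(structure(a, unresolved = FALSE))
  if (length(b) < length(a)) return(structure(b, unresolved = FALSE))
  if (key(a) < key(b)) structure(a, unresolved = FALSE)
  else structure(b, unresolved = FALSE)
}

# SGS by explicit double loop, with sister sets taken from the oracle
oracle_sgs <- function(trees, clade) {
  sisters <- lapply(trees, function(tr) {
    if (!oracle_is_clan(tr, clade)) return(NULL)
    g <- oracle_sister(tr, clade)
    if (isTRUE(attr(g, "unresolved"))) NULL else as.character(g)
  })
  N <- length(trees)
  tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i >= j) next
    gi <- sisters[[i]]; gj <- sisters[[j]]
    if (is.null(gi) || is.null(gj)) next
    tot <- tot + length(intersect(gi, gj)) / length(union(gi, gj))
  }
  2 * tot / (N * (N - 1))
}

# NBS by explicit counting against the oracle clan test
oracle_nbs <- function(ml, trees, clade) {
  parts <- oracle_parts_at_base(ml, clade)
  stopifnot(length(parts) == 2L)
  tri <- list(sort(clade), parts[[1L]], parts[[2L]])
  hits <- vapply(trees, function(tr)
    all(vapply(tri, oracle_is_clan, logical(1), tree = tr)), logical(1))
  100 * mean(hits)
}

# least-squares root position by per-edge grid search
oracle_ls_root <- function(tree, step = 1e-4) {
  n <- ape::Ntip(tree)
  D <- ape::dist.nodes(tree)
  best <- list(score = Inf, edge = NA, x = NA)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    L <- tree$edge.length[k]
    tips_v <- unlist(phangorn::Descendants(tree, v, "tips"))
    on_v <- seq_len(n) %in% tips_v
    for (x in seq(0, L, by = step)) {
      d <- ifelse(on_v, D[v, seq_len(n)] + (L - x), D[u, seq_len(n)] + x)
      sc <- sum((d - mean(d))^2)
      if (sc < best$score) best <- list(score = sc, edge = k, x = x)
    }
  }
  best
}

# brute-force configuration classifier: enumerates every clan of the tree
# (via the oracle) and applies the labelling rules directly
oracle_classify <- function(tree, clade, tax, thr = group_thresholds()) {
  if (!oracle_is_clan(tree, clade)) return("paraphyletic")
  labs <- tree$tip.label
  dom <- tax_domain(tax, labs)
  grp <- tax_group(tax, labs)
  spc <- tax_species(tax, labs)
  clade <- sort(clade)
  all_clans <- unique(c(lapply(sort(labs), identity), oracle_sides(tree),
                        list(sort(labs))))
  enclosing <- Filter(function(S) all(clade %in% S), all_clans)
  count_if_pure <- function(S, level) {
    i <- match(S, labs)
    p <- i[dom[i] != "Eukarya"]
    if (!length(p)) return(NULL)
    tags <- if (level == "group") grp[p] else dom[p]
    if (length(unique(tags)) != 1L) return(NULL)
    list(tag = tags[1L], count = length(unique(spc[p])))
  }
  elig <- character(0)
  for (S in enclosing) {
    r <- count_if_pure(S, "group")
    if (is.null(r)) next
    i <- match(r$tag, thr$group)
    if (!is.na(i) && !is.na(thr$min_required[i]) &&
        r$count >= thr$min_required[i]) elig <- c(elig, r$tag)
  }
  elig <- unique(elig)
  if (length(elig) == 1L) return(paste0("group:", elig))
  delig <- character(0)
  for (S in enclosing) {
    r <- count_if_pure(S, "domain")
    if (!is.null(r) && r$count >= attr(thr, "domain_min"))
      delig <- c(delig, r$tag)
  }
  delig <- unique(delig)
  if (length(delig) == 1L)
    return(paste0("domain:", delig))
  counts <- vapply(c("Archaea", "Bacteria"), function(d)
    length(unique(spc[dom == d])), integer(1))
  sets <- split(labs, dom)
  if (all(c("Archaea", "Bacteria", "Eukarya") %in% names(sets)) &&
      all(counts >= attr(thr, "three_domain_min")) &&
      all(vapply(sets, oracle_is_clan, logical(1), tree = tree)))
    return("three_domain")
  "unclear"
}
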