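## Unrooted-tree combinatorics: bipartitions, clans, tripartitions, sister
## groups. Trees are ape "phylo" objects; bootstrap supports ride along as
## node labels. All set-valued results are sorted character vectors of leaf
## labels.

.as_unrooted <- function(tree) {
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2) ape::unroot(tree) else tree
}

## node x tip incidence matrix: row v is TRUE at the tips below node v (in the
## stored, arbitrarily rooted representation). One postorder sweep.
clan_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  M <- matrix(FALSE, nt + tree$Nnode, nt)
  M[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  edge <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    M[edge[k, 1L], ] <- M[edge[k, 1L], ] | M[edge[k, 2L], ]
  M
}

## index of a non-root node whose descendant set equals `target` (logical over
## tips), or 0L if none
.match_side <- function(M, target, root) {
  k <- sum(target)
  cand <- which(rowSums(M) == k)
  cand <- cand[cand != root]
  for (v in cand) if (all(M[v, ] == target)) return(v)
  0L
}

## TRUE if sorted label vector a precedes b lexicographically
.lex_less <- function(a, b) {
  m <- min(length(a), length(b))
  for (i in seq_len(m)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

.check_leafset <- function(tree, leafset, what = "leaf set") {
  if (length(leafset) == 0L) stop(what, " is empty")
  bad <- setdiff(leafset, tree$tip.label)
  if (length(bad))
    stop(what, " contains labels absent from the tree: ",
         paste(bad, collapse = ", "))
  sort(unique(leafset))
}

#' Test whether a leaf set is a clan of an unrooted tree
#'
#' A clan is one side of a bipartition of an unrooted tree -- the unrooted
#' analogue of a clade, and the sense in which a set of sequences is
#' "monophyletic" on an unrooted gene tree. Single leaves and the full leaf
#' set are trivially clans.
#'
#' @param tree A `phylo` object (rooted trees are treated as unrooted).
#' @param leafset Non-empty character vector of tip labels.
#' @return Logical scalar.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' is_clan(tr, c("A", "B"))  # TRUE
#' is_clan(tr, c("A", "C"))  # FALSE
#' @export
is_clan <- function(tree, leafset) {
  leafset <- .check_leafset(tree, leafset)
  n <- length(tree$tip.label)
  k <- length(leafset)
  if (k == 1L || k == n) return(TRUE)
  tree <- .as_unrooted(tree)
  memb <- tree$tip.label %in% leafset
  M <- clan_matrix(tree)
  root <- length(tree$tip.label) + 1L
  .match_side(M, memb, root) > 0L || .match_side(M, !memb, root) > 0L
}

## parts of the tree around the attachment node of a clan: a list of sorted
## label vectors, one per subtree adjacent to the attachment node other than
## the clan itself. attr "attachment_is_leaf" marks the degenerate
## all-but-one-leaf case.
.parts_at_base <- function(tree, clan) {
  tree <- .as_unrooted(tree)
  labs <- tree$tip.label
  n <- length(labs)
  if (length(clan) == n) stop("clan covers all leaves; it has no stem")
  memb <- labs %in% clan
  M <- clan_matrix(tree)
  root <- n + 1L
  part_of <- function(v) sort(labs[M[v, ]])

  v <- .match_side(M, memb, root)
  if (v > 0L) { # clan is the descendant set of v; attachment is v's parent
    u <- tree$edge[tree$edge[, 2L] == v, 1L]
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    parts <- lapply(setdiff(kids, v), part_of)
    if (u != root) parts <- c(parts, list(sort(labs[!M[u, ]])))
  } else {      # clan is the complement of the descendant set of v
    v <- .match_side(M, !memb, root)
    if (v == 0L) stop("leaf set is not a clan of the tree")
    if (v <= n) { # attachment node is the single remaining leaf
      parts <- list(labs[v])
      attr(parts, "attachment_is_leaf") <- TRUE
      return(parts)
    }
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    parts <- lapply(kids, part_of)
  }
  attr(parts, "attachment_is_leaf") <- FALSE
  parts
}

#' Sister group of a clan on an unrooted tree
#'
#' The sister group of a eukaryotic clan is defined as the smaller (by leaf
#' count) of the two subtrees adjacent to the clan's stem edge. Ties are
#' broken towards the set whose sorted label tuple is lexicographically
#' smaller, for determinism. If the attachment node is multifurcating the
#' sister is unresolved: the union of all adjacent subtrees is returned with
#' attribute `unresolved = TRUE` (downstream, such replicates contribute a
#' similarity of 0 to the SGS score).
#'
#' @inheritParams is_clan
#' @param clan Character vector of tip labels forming a clan (checked).
#' @return Sorted character vector of tip labels, with logical attribute
#'   `unresolved`.
#' @export
sister_group <- function(tree, clan) {
  clan <- .check_leafset(tree, clan, "clan")
  parts <- .parts_at_base(tree, clan)
  if (isTRUE(attr(parts, "attachment_is_leaf")) || length(parts) == 1L)
    return(structure(parts[[1L]], unresolved = FALSE))
  if (length(parts) > 2L)
    return(structure(sort(unique(unlist(parts))), unresolved = TRUE))
  a <- parts[[1L]]; b <- parts[[2L]]
  smaller <- if (length(a) != length(b)) {
    if (length(a) < length(b)) a else b
  } else if (.lex_less(a, b)) a else b
  structure(smaller, unresolved = FALSE)
}

#' Tripartition at the base of a clan
#'
#' The internal node where a clan's stem meets the rest of the tree splits
#' the leaves into three parts: the clan, its sister group, and the
#' remainder. This tripartition (equivalently, the co-occurrence of its three
#' induced bipartitions) is the object whose bootstrap frequency defines the
#' NBS statistic.
#'
#' @inheritParams sister_group
#' @return An object of class `tripartition`: a list of three sorted,
#'   disjoint label vectors covering all leaves (order is not meaningful).
#' @export
tripartition_at_base <- function(tree, clan) {
  clan <- .check_leafset(tree, clan, "clan")
  parts <- .parts_at_base(tree, clan)
  if (isTRUE(attr(parts, "attachment_is_leaf")))
    stop("attachment node is a leaf; no tripartition at the base of this clan")
  if (length(parts) != 2L)
    stop("attachment node is multifurcating; tripartition undefined")
  out <- list(clan, parts[[1L]], parts[[2L]])
  out <- out[order(vapply(out, function(p) p[1L], character(1)))]
  class(out) <- "tripartition"
  out
}

#' Does a tree contain a given tripartition?
#'
#' TRUE iff the three bipartitions induced by the tripartition's parts all
#' occur in `tree` (they then necessarily meet at one internal node).
#'
#' @param tree A `phylo` object.
#' @param tri A [tripartition_at_base()] result.
#' @return Logical scalar.
#' @export
has_tripartition <- function(tree, tri) {
  stopifnot(inherits(tri, "tripartition"))
  all(vapply(tri, function(p) is_clan(tree, p), logical(1)))
}

#' Enumerate the non-trivial bipartitions of a tree
#'
#' @param tree A `phylo` object.
#' @return A list of bipartitions, each a list with sorted components
#'   `side_a` and `side_b` (`side_a` holds the alphabetically first label).
#' @export
tree_bipartitions <- function(tree) {
  tree <- .as_unrooted(tree)
  labs <- tree$tip.label
  n <- length(labs)
  M <- clan_matrix(tree)
  root <- n + 1L
  internal <- setdiff(seq_len(n + tree$Nnode), c(seq_len(n), root))
  out <- list()
  seen <- character(0)
  for (v in internal) {
    k <- sum(M[v, ])
    if (k <= 1L || k >= n - 1L) next
    a <- sort(labs[M[v, ]]); b <- sort(labs[!M[v, ]])
    if (b[1L] < a[1L]) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(side_a = a, side_b = b)
  }
  out
}

## ---- Newick I/O -------------------------------------------------------

## Secondary support dialect: "):0.12[87]" (support in a bracket comment after
## the branch length) is rewritten to the node-label dialect ")87:0.12"
## before parsing.
.lift_bracket_supports <- function(text) {
  if (!grepl("[", text, fixed = TRUE)) return(text)
  gsub("\\)\\s*:\\s*([0-9eE.+-]+)\\s*\\[([0-9.]+)\\]", ")\\2:\\1", text)
}

.parse_one_newick <- function(text, where) {
  tr <- tryCatch(
    ape::read.tree(text = .lift_bracket_supports(text)),
    error = function(e) stop("cannot parse Newick at ", where, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("cannot parse Newick at ", where, call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s) at ", where, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tr$edge.length)) {
    warning("tree at ", where, " has no branch lengths; using 1.0 throughout",
            call. = FALSE)
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length at ", where, call. = FALSE)
  tr
}

#' Read gene trees from Newick files
#'
#' `read_gene_tree()` reads a single-tree file; `read_gene_trees()` reads a
#' file with one Newick tree per line (e.g. a bootstrap replicate file).
#' Internal node labels are interpreted as integer bootstrap supports on the
#' 0--100 scale; the alternative dialect placing supports in bracket comments
#' after branch lengths (`):0.12[87]`) is also accepted. Duplicate leaf
#' labels are a hard error. Trees without branch lengths get unit lengths
#' with a warning (supports and topology queries do not depend on them).
#'
#' @param path Path to a Newick file.
#' @param expect_supports If TRUE, warn when internal-node supports are
#'   absent.
#' @return A `phylo` object, or a `multiPhylo` list for
#'   `read_gene_trees()`.
#' @export
read_gene_tree <- function(path, expect_supports = FALSE) {
  lines <- .newick_lines(path)
  if (length(lines) > 1L)
    stop("file ", path, " contains ", length(lines),
         " trees; use read_gene_trees()")
  tr <- .parse_one_newick(lines[[1L]], paste0(path, " line ", names(lines)[1L]))
  if (expect_supports && !.has_supports(tr))
    warning("no internal-node supports found in ", path, call. = FALSE)
  tr
}

#' @rdname read_gene_tree
#' @export
read_gene_trees <- function(path, expect_supports = FALSE) {
  lines <- .newick_lines(path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines))
    out[[i]] <- .parse_one_newick(lines[[i]],
                                  paste0(path, " line ", names(lines)[i]))
  if (expect_supports && !all(vapply(out, .has_supports, logical(1))))
    warning("some trees in ", path, " lack internal-node supports",
            call. = FALSE)
  class(out) <- "multiPhylo"
  out
}

.newick_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)))
  if (!length(keep)) stop("no Newick trees found in ", path)
  stats::setNames(as.list(trimws(raw[keep])), keep)
}

.has_supports <- function(tr) {
  !is.null(tr$node.label) && any(nzchar(tr$node.label))
}

#' Numeric supports on internal nodes
#'
#' @param tree A `phylo` with node labels carrying supports.
#' @return Numeric vector of length `tree$Nnode` (NA where absent).
#' @export
edge_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Write a gene tree (or list of trees) in Newick format
#'
#' Node labels (bootstrap supports) and branch lengths are preserved.
#'
#' @param tree A `phylo` or `multiPhylo`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
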