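## Gene-family simulator. Generates a three-domain species tree from a
## configurable species design, derives gene trees under an origin scenario
## (endosymbiotic transfer from a donor group, vertical archaeal descent,
## three-domain LUCA inheritance, or a transfer-scrambled mix) with per
## species gene loss and prokaryote-to-prokaryote transfers, and emulates
## bootstrap ensembles by topological perturbation with controllable
## stability of the eukaryote attachment point. Everything is deterministic
## under the configuration seed.

#' Default species design for simulations
#'
#' The prokaryotic rows reproduce the reference genome sampling behind the
#' default [group_thresholds()] table (39 archaeal and 144 bacterial
#' species across 31 groups); the eukaryote panel spans the four supergroups
#' used by the LECA ancestrality rules (6 Unikonts, 5 Plantae, 5
#' Chromalveolates, 2 Kinetoplastids) plus one other eukaryote, 19 species
#' in all.
#'
#' @return Data.frame with columns `group`, `domain`, `n_species`.
#' @export
default_species_design <- function() {
  thr <- .default_group_table()
  prok <- data.frame(group = thr$group, domain = thr$domain,
                     n_species = thr$sampled, stringsAsFactors = FALSE)
  euk <- data.frame(
    group = c("Unikonts", "Plantae", "Chromalveolates", "Kinetoplastids",
              "OtherEukaryote"),
    domain = "Eukarya",
    n_species = c(6L, 5L, 5L, 2L, 1L), stringsAsFactors = FALSE)
  rbind(prok, euk)
}

#' Simulation configuration
#'
#' Collects every knob of the generator. `scenario` fixes the true origin of
#' the eukaryotic gene copy; `loss_prob` thins species independently
#' (producing the patchy taxonomic distributions typical of real families);
#' `hgt_rate` is the expected number of prokaryote-to-prokaryote transfers
#' per family; `q_instability` is the per-replicate probability that the
#' emulated bootstrap detaches the eukaryote clan and re-attaches it
#' elsewhere (with edge choice decaying geometrically in topological
#' distance, base `kernel_decay`), and `r_nni` the probability of one
#' random NNI perturbation per replicate.
#'
#' @param seed Integer; fully determines all generator output.
#' @param species_design Data.frame as [default_species_design()].
#' @param scenario One of `"EGT"`, `"VERTICAL_ARCHAEAL"`,
#'   `"LUCA_THREE_DOMAIN"`, `"UNCLEAR_MIX"`.
#' @param donor_group Donor group for the `EGT` scenario.
#' @param loss_prob Per-species gene-loss probability, in `[0, 1]`.
#' @param hgt_rate Expected transfers per family (Poisson mean).
#' @param n_replicates Bootstrap ensemble size (default 100).
#' @param q_instability Probability a replicate perturbs the eukaryote
#'   attachment.
#' @param r_nni Probability a replicate NNI-perturbs one random internal
#'   edge.
#' @param kernel_decay Geometric decay of the re-attachment kernel with
#'   topological distance from the true edge, in `(0, 1]`.
#' @param branch_rate Rate of the exponential branch-length distribution.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              species_design = default_species_design(),
                              scenario = c("EGT", "VERTICAL_ARCHAEAL",
                                           "LUCA_THREE_DOMAIN", "UNCLEAR_MIX"),
                              donor_group = "Alphaproteobacteria",
                              loss_prob = 0.1, hgt_rate = 0,
                              n_replicates = 100L, q_instability = 0.05,
                              r_nni = 0.05, kernel_decay = 0.5,
                              branch_rate = 1) {
  scenario <- match.arg(scenario)
  for (p in c(loss_prob, q_instability, r_nni))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (kernel_decay <= 0 || kernel_decay > 1)
    stop("kernel_decay must lie in (0, 1]")
  if (sum(species_design$n_species) < 4L || nrow(species_design) < 2L)
    stop("degenerate species design: need >= 2 groups and >= 4 species")
  if (scenario == "EGT" && !(donor_group %in% species_design$group))
    stop("EGT donor group absent from the species design: ", donor_group)
  structure(list(seed = as.integer(seed), species_design = species_design,
                 scenario = scenario, donor_group = donor_group,
                 loss_prob = loss_prob, hgt_rate = hgt_rate,
                 n_replicates = as.integer(n_replicates),
                 q_instability = q_instability, r_nni = r_nni,
                 kernel_decay = kernel_decay, branch_rate = branch_rate),
            class = "simulation_config")
}

.subtree_newick <- function(tree) sub(";$", "", ape::write.tree(tree))

.random_join <- function(nwks, rate) {
  while (length(nwks) > 1L) {
    i <- sample.int(length(nwks), 2L)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", nwks[i[1L]], stats::rexp(1, rate),
                      nwks[i[2L]], stats::rexp(1, rate))
    nwks <- c(nwks[-i], merged)
  }
  nwks
}

#' Simulate a species tree from a species design
#'
#' Groups and domains are monophyletic by construction; topology within and
#' among groups is random, branch lengths are exponential. The domain
#' backbone is `(Bacteria, (Archaea, Eukarya))`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Seed (default `cfg$seed`); pass `NULL` to draw from the
#'   current RNG stream.
#' @return List of class `species_tree_sim` with `tree` (rooted `phylo`)
#'   and `species` (data.frame `species_id`, `group`, `domain`,
#'   `supergroup`).
#' @export
simulate_species_tree <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  des <- cfg$species_design
  rate <- cfg$branch_rate
  species <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    n <- des$n_species[i]
    data.frame(
      species_id = sprintf("%s_s%02d", gsub("[^A-Za-z0-9]", "", des$group[i]),
                           seq_len(n)),
      group = des$group[i], domain = des$domain[i],
      supergroup = if (des$domain[i] == "Eukarya") des$group[i]
                   else NA_character_,
      stringsAsFactors = FALSE)
  }))

  group_nwk <- vapply(seq_len(nrow(des)), function(i) {
    ids <- species$species_id[species$group == des$group[i]]
    if (length(ids) == 1L)
      return(sprintf("%s:%.6f", ids, stats::rexp(1, rate)))
    sub <- ape::rtree(length(ids), br = function(k) stats::rexp(k, rate))
    sub$tip.label <- ids[as.integer(sub("^t", "", sub$tip.label))]
    .subtree_newick(sub)
  }, character(1))

  dom_nwk <- vapply(c("Bacteria", "Archaea", "Eukarya"), function(d) {
    .random_join(group_nwk[des$domain == d], rate)
  }, character(1))
  txt <- sprintf("(%s:%.6f,(%s:%.6f,%s:%.6f):%.6f);",
                 dom_nwk[["Bacteria"]], stats::rexp(1, rate),
                 dom_nwk[["Archaea"]], stats::rexp(1, rate),
                 dom_nwk[["Eukarya"]], stats::rexp(1, rate),
                 stats::rexp(1, rate))
  structure(list(tree = ape::read.tree(text = txt), species = species),
            class = "species_tree_sim")
}

## ---- tree surgery ----------------------------------------------------

.detach_clan <- function(tree, leaves) {
  list(sub = ape::keep.tip(tree, leaves),
       rest = ape::drop.tip(.as_unrooted(tree), leaves))
}

## edges of `tree` whose child-side leaves all belong to `member_leaves`
## (the taxon's internal and pendant edges, plus its stem edge); tree is
## rerooted at a non-member tip so the subtree never contains the root
.edges_in_taxon <- function(tree, member_leaves) {
  out_tip <- setdiff(tree$tip.label, member_leaves)
  if (!length(out_tip)) stop("taxon spans the whole tree")
  rt <- ape::root(.as_unrooted(tree), outgroup = out_tip[1L],
                  resolve.root = TRUE)
  M <- clan_matrix(rt)
  memb <- rt$tip.label %in% member_leaves
  ks <- which(vapply(seq_len(nrow(rt$edge)), function(k) {
    desc <- M[rt$edge[k, 2L], ]
    all(!desc | memb)
  }, logical(1)))
  list(tree = rt, edges = ks)
}

.attach_sub <- function(tree, sub, k, stem, position = NULL) {
  child <- tree$edge[k, 2L]
  L <- tree$edge.length[k]
  pos <- if (is.null(position)) stats::runif(1, 0.1, 0.9) * L
         else min(max(position, 0), L)
  sub$root.edge <- stem
  ape::bind.tree(tree, sub, where = child, position = pos)
}

## stem edge (index) of a clan: edge whose child-side leaf set equals the clan,
## after rerooting at a non-member tip; returns list(tree, k)
.stem_edge <- function(tree, clan_leaves) {
  out_tip <- setdiff(tree$tip.label, clan_leaves)
  rt <- ape::root(.as_unrooted(tree), outgroup = out_tip[1L],
                  resolve.root = TRUE)
  M <- clan_matrix(rt)
  memb <- rt$tip.label %in% clan_leaves
  for (k in seq_len(nrow(rt$edge)))
    if (all(M[rt$edge[k, 2L], ] == memb)) return(list(tree = rt, k = k))
  stop("leaf set is not a clan; no stem edge")
}

## move a single leaf onto the edge subtending `target`: either another leaf
## label or a clan (attach on its stem edge)
.move_leaf <- function(tree, leaf, target, rate) {
  rest <- ape::drop.tip(.as_unrooted(tree), leaf)
  if (length(target) == 1L && target %in% rest$tip.label &&
      length(target) == 1L) {
    child <- which(rest$tip.label == target)
    L <- rest$edge.length[rest$edge[, 2L] == child]
    rt <- rest
  } else {
    se <- .stem_edge(rest, target)
    rt <- se$tree
    child <- rt$edge[se$k, 2L]
    L <- rt$edge.length[se$k]
  }
  phytools::bind.tip(rt, leaf, edge.length = stats::rexp(1, rate),
                     where = child, position = stats::runif(1, 0.1, 0.9) * L)
}

## ---- gene-family simulation ------------------------------------------

.viable_losses <- function(sp, cfg) {
  for (i in seq_len(100L)) {
    lost <- sp$species_id[stats::runif(nrow(sp)) < cfg$loss_prob]
    kd <- sp[!(sp$species_id %in% lost), ]
    ok <- nrow(kd) >= 4L && sum(kd$domain == "Eukarya") >= 1L &&
      sum(kd$domain != "Eukarya") >= 2L
    if (cfg$scenario == "EGT")
      ok <- ok && sum(kd$group == cfg$donor_group) >= 1L
    if (cfg$scenario %in% c("VERTICAL_ARCHAEAL", "LUCA_THREE_DOMAIN",
                            "UNCLEAR_MIX"))
      ok <- ok && sum(kd$domain == "Archaea") >= 1L &&
        sum(kd$domain == "Bacteria") >= 1L
    if (ok) return(lost)
  }
  stop("could not draw a viable loss pattern in 100 tries; lower loss_prob")
}

#' Simulate one gene family (ML tree plus truth log)
#'
#' The gene tree follows the species tree except that (i) each species loses
#' the gene independently with probability `loss_prob`, (ii) the eukaryote
#' clan is re-attached according to the origin scenario (inside the donor
#' group's clan under `EGT`; inside or adjacent to the archaeal clan under
#' `VERTICAL_ARCHAEAL`; left in place, all three domains monophyletic,
#' under `LUCA_THREE_DOMAIN`; behind a ladder of alternately archaeal and
#' bacterial transferred sequences under `UNCLEAR_MIX`), and (iii)
#' `Poisson(hgt_rate)` transfer events each move one recipient sequence next
#' to a random donor-group sequence. Every loss and transfer is logged.
#'
#' @param species_sim A [simulate_species_tree()] result.
#' @param cfg A [simulation_config()].
#' @param family_id Identifier used in reports and file names.
#' @param seed Seed; `NULL` (default) draws from the current RNG stream.
#' @return List of class `simulated_family`: `ml_tree`, `taxonomy`
#'   ([taxonomy_map()] of the family's sequences), `truth` (scenario, donor
#'   group, event log), `family_id`, and `replicates` (`NULL` until
#'   [emulate_bootstrap()] fills it).
#' @export
simulate_gene_tree <- function(species_sim, cfg, family_id = "fam001",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- species_sim$species
  events <- list()

  lost <- .viable_losses(sp, cfg)
  gene <- if (length(lost)) ape::drop.tip(species_sim$tree, lost)
          else species_sim$tree
  for (l in lost)
    events[[length(events) + 1L]] <- c(type = "loss", subject = l, detail = "")

  ## one sequence per surviving species
  kept <- gene$tip.label
  gene$tip.label <- paste0(kept, "_1")
  ki <- match(kept, sp$species_id)
  taxonomy <- taxonomy_map(data.frame(
    sequence_id = gene$tip.label, species_id = kept,
    group = sp$group[ki], domain = sp$domain[ki],
    supergroup = sp$supergroup[ki], stringsAsFactors = FALSE))
  euk_seqs <- taxonomy$sequence_id[taxonomy$domain == "Eukarya"]
  prok_tax <- taxonomy[taxonomy$domain != "Eukarya", ]

  if (cfg$scenario == "EGT") {
    det <- .detach_clan(gene, euk_seqs)
    donors <- prok_tax$sequence_id[prok_tax$group == cfg$donor_group]
    et <- .edges_in_taxon(det$rest, donors)
    k <- et$edges[sample.int(length(et$edges), 1L)]
    gene <- .attach_sub(et$tree, det$sub, k,
                        stem = stats::rexp(1, cfg$branch_rate))
    events[[length(events) + 1L]] <-
      c(type = "egt", subject = cfg$donor_group,
        detail = paste0("edge", k))
  } else if (cfg$scenario == "VERTICAL_ARCHAEAL") {
    det <- .detach_clan(gene, euk_seqs)
    arch <- prok_tax$sequence_id[prok_tax$domain == "Archaea"]
    et <- .edges_in_taxon(det$rest, arch)
    k <- et$edges[sample.int(length(et$edges), 1L)]
    gene <- .attach_sub(et$tree, det$sub, k,
                        stem = stats::rexp(1, cfg$branch_rate))
    events[[length(events) + 1L]] <-
      c(type = "vertical_archaeal", subject = "Archaea",
        detail = paste0("edge", k))
  } else if (cfg$scenario == "UNCLEAR_MIX") {
    m <- 4L + stats::rpois(1, 2)
    doms <- rep(c("Bacteria", "Archaea"), length.out = m)
    for (j in seq_len(m)) {
      pool <- prok_tax$sequence_id[prok_tax$domain == doms[j]]
      pool <- intersect(pool, gene$tip.label)
      mover <- pool[sample.int(length(pool), 1L)]
      gene <- .move_leaf(gene, mover, target = euk_seqs,
                         rate = cfg$branch_rate)
      events[[length(events) + 1L]] <-
        c(type = "mix_transfer", subject = mover, detail = "euk_stem")
    }
  } ## LUCA_THREE_DOMAIN: species-tree position kept, domains monophyletic

  n_hgt <- stats::rpois(1, cfg$hgt_rate)
  for (j in seq_len(n_hgt)) {
    present <- intersect(prok_tax$sequence_id, gene$tip.label)
    pg <- prok_tax$group[match(present, prok_tax$sequence_id)]
    if (length(unique(pg)) < 2L) break
    donor <- present[sample.int(length(present), 1L)]
    others <- present[pg != pg[match(donor, present)]]
    recipient <- others[sample.int(length(others), 1L)]
    ## the recipient's sequence re-branches next to the donor's
    gene <- .move_leaf(gene, recipient, target = donor,
                       rate = cfg$branch_rate)
    events[[length(events) + 1L]] <-
      c(type = "hgt", subject = recipient, detail = paste0("near:", donor))
  }

  ev <- if (length(events))
    as.data.frame(do.call(rbind, events), stringsAsFactors = FALSE)
  else data.frame(type = character(), subject = character(),
                  detail = character(), stringsAsFactors = FALSE)

  structure(list(
    ml_tree = gene, taxonomy = taxonomy,
    truth = list(scenario = cfg$scenario,
                 donor_group = if (cfg$scenario == "EGT") cfg$donor_group
                               else NA_character_,
                 events = ev),
    family_id = family_id, replicates = NULL),
    class = "simulated_family")
}

#' Construct a recent-HGT sister confound case
#'
#' Builds the classic trap for the naive sister-clade criterion: one
#' sequence of `recipient_group` is first transferred away from its group
#' (into the `context_group` region), then the eukaryote clan is attached
#' directly onto that isolated sequence's branch. The eukaryotes' sister is
#' a single `recipient_group` sequence, but their true surroundings are
#' mixed Bacteria: the naive criterion names `recipient_group`, while the
#' configuration classifier can only support a bacterial-domain-level call.
#'
#' @inheritParams simulate_gene_tree
#' @param recipient_group Group of the single misleading sister sequence.
#' @param context_group Group inside which that sequence is marooned.
#' @return A `simulated_family`.
#' @export
simulate_hgt_confound <- function(species_sim, cfg,
                                  recipient_group = "Deltaproteobacteria",
                                  context_group = "Actinobacteria",
                                  family_id = "confound", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene <- species_sim$tree
  sp <- species_sim$species
  gene$tip.label <- paste0(gene$tip.label, "_1")
  taxonomy <- taxonomy_map(data.frame(
    sequence_id = paste0(sp$species_id, "_1"), species_id = sp$species_id,
    group = sp$group, domain = sp$domain, supergroup = sp$supergroup,
    stringsAsFactors = FALSE))
  euk_seqs <- taxonomy$sequence_id[taxonomy$domain == "Eukarya"]

  rec_pool <- taxonomy$sequence_id[taxonomy$group == recipient_group]
  ctx_pool <- taxonomy$sequence_id[taxonomy$group == context_group]
  if (!length(rec_pool) || !length(ctx_pool))
    stop("recipient or context group absent from the species design")
  mover <- rec_pool[sample.int(length(rec_pool), 1L)]
  ctx <- ctx_pool[sample.int(length(ctx_pool), 1L)]
  gene <- .move_leaf(gene, mover, target = ctx, rate = cfg$branch_rate)

  det <- .detach_clan(gene, euk_seqs)
  child <- which(det$rest$tip.label == mover)
  k <- which(det$rest$edge[, 2L] == child)
  gene <- .attach_sub(det$rest, det$sub, k,
                      stem = stats::rexp(1, cfg$branch_rate))
  structure(list(
    ml_tree = gene, taxonomy = taxonomy,
    truth = list(scenario = "HGT_SISTER_CONFOUND",
                 donor_group = recipient_group,
                 events = data.frame(type = "hgt", subject = mover,
                                     detail = paste0("near:", ctx),
                                     stringsAsFactors = FALSE)),
    family_id = family_id, replicates = NULL),
    class = "simulated_family")
}

#' Emulate a bootstrap ensemble by topological perturbation
#'
#' Each replicate starts as a copy of the family's ML tree. With probability
#' `q_instability` the eukaryote clan is detached and re-attached to an edge
#' drawn from a kernel decaying geometrically with topological distance from
#' the true attachment edge (the true edge itself is excluded, so a
#' perturbed replicate never reproduces the original tripartition). With
#' probability `r_nni` one random internal edge is additionally
#' NNI-perturbed. With both probabilities zero all replicates equal the ML
#' tree, giving NBS = 100 and SGS = 1 downstream.
#'
#' @param family A `simulated_family`.
#' @param cfg A [simulation_config()] (`n_replicates`, `q_instability`,
#'   `r_nni`, `kernel_decay`).
#' @param seed Seed; `NULL` (default) draws from the current RNG stream.
#' @return A `multiPhylo` of `cfg$n_replicates` trees on the ML leaf set.
#' @export
emulate_bootstrap <- function(family, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$n_replicates
  if (N < 2L) stop("need at least 2 replicates")
  ml <- family$ml_tree
  q <- cfg$q_instability; r <- cfg$r_nni

  if (q > 0) {
    euks <- family$taxonomy$sequence_id[family$taxonomy$domain == "Eukarya"]
    euks <- intersect(euks, ml$tip.label)
    if (!is_clan(ml, euks))
      stop("eukaryote leaves are not a clan of the ML tree; ",
           "cannot perturb their attachment")
    se <- .stem_edge(ml, euks)
    stem_len <- se$tree$edge.length[se$k]
    det <- .detach_clan(ml, euks)
    sis <- as.character(sister_group(ml, euks))
    rest_rt <- ape::root(.as_unrooted(det$rest),
                         outgroup = det$rest$tip.label[1L],
                         resolve.root = TRUE)
    M <- clan_matrix(rest_rt)
    memb_s <- rest_rt$tip.label %in% sis
    k_orig <- NA_integer_
    for (k in seq_len(nrow(rest_rt$edge))) {
      d <- M[rest_rt$edge[k, 2L], ]
      if (all(d == memb_s) || all(d == !memb_s)) { k_orig <- k; break }
    }
    unit <- rest_rt
    unit$edge.length <- rep(1, nrow(unit$edge))
    D <- ape::dist.nodes(unit)
    cands <- setdiff(which(rest_rt$edge.length > 0),
                     if (is.na(k_orig)) integer(0) else k_orig)
    dd <- if (is.na(k_orig)) rep(0, length(cands))
          else D[rest_rt$edge[k_orig, 2L], rest_rt$edge[cands, 2L]]
    w <- cfg$kernel_decay^dd
    w <- w / sum(w)
  }

  out <- vector("list", N)
  for (i in seq_len(N)) {
    t <- ml
    if (q > 0 && stats::runif(1) < q) {
      k <- cands[sample.int(length(cands), 1L, prob = w)]
      t <- .attach_sub(rest_rt, det$sub, k, stem = stem_len,
                       position = rest_rt$edge.length[k] / 2)
    }
    if (r > 0 && stats::runif(1) < r) t <- phangorn::rNNI(t, 1L)
    out[[i]] <- t
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate a dataset of gene families
#'
#' Draws one species tree and `n_families` gene families with bootstrap
#' ensembles, all from `cfg$seed`. Optionally writes the exact input formats
#' the pipeline reads.
#'
#' @param cfg A [simulation_config()].
#' @param n_families Number of families.
#' @param dir If non-NULL, files are written there: per family
#'   `<id>.ml.nwk` and `<id>.boot.nwk`, plus `taxonomy.tsv` and
#'   `truth.tsv`.
#' @return List of class `simulated_dataset` with `species`, `families`,
#'   `taxonomy` (merged), `config`.
#' @export
simulate_dataset <- function(cfg, n_families = 1L, dir = NULL) {
  set.seed(cfg$seed)
  spsim <- simulate_species_tree(cfg, seed = NULL)
  fams <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- simulate_gene_tree(spsim, cfg,
                              family_id = sprintf("fam%03d", f), seed = NULL)
    fam$replicates <- emulate_bootstrap(fam, cfg, seed = NULL)
    fams[[f]] <- fam
  }
  tax_all <- unique(do.call(rbind, lapply(fams, function(f)
    as.data.frame(f$taxonomy))))
  obj <- structure(list(species = spsim, families = fams,
                        taxonomy = taxonomy_map(tax_all), config = cfg),
                   class = "simulated_dataset")
  if (!is.null(dir)) write_dataset(obj, dir)
  obj
}

#' @rdname simulate_dataset
#' @param dataset A `simulated_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fam in dataset$families) {
    write_gene_tree(fam$ml_tree,
                    file.path(dir, paste0(fam$family_id, ".ml.nwk")))
    if (!is.null(fam$replicates))
      write_gene_tree(fam$replicates,
                      file.path(dir, paste0(fam$family_id, ".boot.nwk")))
  }
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  truth <- do.call(rbind, lapply(dataset$families, function(fam) {
    ev <- fam$truth$events
    if (nrow(ev) == 0L)
      ev <- data.frame(type = "none", subject = "", detail = "",
                       stringsAsFactors = FALSE)
    cbind(family_id = fam$family_id, scenario = fam$truth$scenario,
          donor_group = fam$truth$donor_group, ev)
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}
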