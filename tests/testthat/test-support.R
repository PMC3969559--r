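# small trees with a two-leaf eukaryote clan whose sister set is chosen at
# will; remaining prokaryotes pad the other side
sister_tree <- function(sister, others) {
  blob <- function(x) if (length(x) == 1) x else
    paste0("(", x[1], ",", blob(x[-1]), ")")
  ape::read.tree(text = sprintf("((E1,E2),(%s,%s));",
                                blob(sister), blob(others)))
}

test_that("NBS counts tripartition occurrences across replicates", {
  ml <- ape::read.tree(text = "((E1,E2),(P1,(P2,P3)));")
  expect_equal(nbs(ml, rep(c(ml), 7), c("E1", "E2")), 100)

  moved <- ape::read.tree(text = "((E1,E2),(P2,(P1,P3)));")
  expect_equal(nbs(ml, c(ml, moved, c(ml), moved), c("E1", "E2")), 50)

  para <- ape::read.tree(text = "((E1,(P1,E2)),(P2,P3));")
  expect_equal(nbs(ml, rep(c(para), 4), c("E1", "E2")), 0)

  expect_error(nbs(ml, list(ape::read.tree(text = "((E1,E2),(P1,P4));")),
                   c("E1", "E2")), "leaf set")
  expect_error(nbs(para, rep(c(ml), 2), c("E1", "E2")), "not a clan")
})

test_that("SGS spans its limits and matches hand-enumerated pairs", {
  others <- c("x", "y")
  t_ab <- sister_tree(c("a", "b"), c("c", others))
  t_ac <- sister_tree(c("a", "c"), c("b", others))
  t_b <- sister_tree("b", c("a", "c", others))
  t_c <- sister_tree("c", c("a", "b", others))
  t_a <- sister_tree("a", c("b", "c", others))

  # absolute stability
  expect_equal(as.numeric(sgs(rep(c(t_ab), 5), c("E1", "E2"))), 1)
  # complete disjunction of sister sets
  expect_equal(as.numeric(sgs(c(t_a, t_b, t_c), c("E1", "E2"))), 0)
  # N = 3 with sisters {a,b}, {a,b}, {a,c}: mean of (1, 1/3, 1/3)
  expect_equal(as.numeric(sgs(c(t_ab, t_ab, t_ac), c("E1", "E2"))), 5 / 9)

  # paraphyletic replicates contribute zero similarity
  para <- ape::read.tree(text = "((E1,(a,E2)),(b,(c,(x,y))));")
  expect_equal(as.numeric(sgs(c(t_ab, t_ab, para), c("E1", "E2"))), 1 / 3)

  expect_error(sgs(list(t_ab), c("E1", "E2")), "at least 2")

  # pluggable similarity: overlap coefficient instead of Jaccard
  overlap <- function(a, b) length(intersect(a, b)) / min(length(a), length(b))
  expect_equal(as.numeric(sgs(c(t_ab, t_ab, t_ac), c("E1", "E2"),
                              similarity = overlap)), 2 / 3)
})

test_that("SGS and NBS agree with brute-force implementations on ensembles", {
  set.seed(2024)
  cfg <- simulation_config(seed = 2024, species_design = small_design(),
                           scenario = "EGT", loss_prob = 0.1,
                           n_replicates = 12, q_instability = 0.4,
                           r_nni = 0.2)
  sp <- simulate_species_tree(cfg)
  for (rep in 1:3) {
    fam <- simulate_gene_tree(sp, cfg)
    reps <- emulate_bootstrap(fam, cfg)
    euks <- intersect(fam$taxonomy$sequence_id[
      fam$taxonomy$domain == "Eukarya"], fam$ml_tree$tip.label)
    expect_equal(as.numeric(sgs(reps, euks)), oracle_sgs(reps, euks),
                 tolerance = 1e-12)
    expect_equal(nbs(fam$ml_tree, reps, euks),
                 oracle_nbs(fam$ml_tree, reps, euks))
    # replicates sharing the ML tripartition have identical sister sets, so
    # those pairs alone bound the SGS sum from below
    N <- length(reps)
    k <- round(nbs(fam$ml_tree, reps, euks) / 100 * N)
    expect_gte(as.numeric(sgs(reps, euks)) + 1e-12,
               k * (k - 1) / (N * (N - 1)))
  }
})

test_that("monophyly support is the replicate fraction where the taxon is a clan", {
  ml <- ape::read.tree(text = "((E1,E2),(P1,(P2,P3)));")
  broken <- ape::read.tree(text = "((E1,(P1,E2)),(P2,P3));")
  expect_equal(monophyly_support(c(rep(c(ml), 19), broken), c("E1", "E2")),
               95)
  expect_equal(monophyly_support(rep(c(broken), 4), "P1"), 100) # single leaf
  expect_equal(monophyly_support(rep(c(broken), 4), ml$tip.label), 100)
  expect_error(monophyly_support(rep(c(ml), 3), character(0)), "empty")
})

test_that("near-universal filter applies the ceiling coverage rule", {
  tax <- prefix_tax(c("E1", "A1", "R1"))
  totals <- c(Archaea = 39, Bacteria = 144)
  cs <- list(Archaea = sprintf("a%02d", 1:36),
             Bacteria = sprintf("b%03d", 1:130))
  expect_true(near_universal_filter(cs, tax, fraction = 0.9,
                                    totals = totals))  # ceil(35.1) = 36
  cs$Archaea <- cs$Archaea[1:35]
  expect_false(near_universal_filter(cs, tax, fraction = 0.9,
                                     totals = totals))
  full <- list(Archaea = sprintf("a%02d", 1:39),
               Bacteria = sprintf("b%03d", 1:144))
  expect_true(near_universal_filter(full, tax, fraction = 1,
                                    totals = totals))
  expect_error(near_universal_filter(full, tax, fraction = 0,
                                     totals = totals), "fraction")
})

test_that("SGS calibration finds the highest misclassified reference", {
  ref <- data.frame(clade_id = paste0("c", 1:5),
                    sgs = c(90, 70, 50, 45, 30),
                    group = c("Alphaproteobacteria", "Alphaproteobacteria",
                              "Alphaproteobacteria", "Gammaproteobacteria",
                              "unclear"))
  cal <- calibrate_sgs_threshold(ref, "Alphaproteobacteria")
  expect_equal(cal$threshold, 45)
  expect_true(cal$usable)
  expect_identical(cal$table$clade_id, paste0("c", 1:5)) # sorted by SGS

  all_good <- calibrate_sgs_threshold(
    data.frame(clade_id = "x", sgs = 80, group = "Alphaproteobacteria"),
    "Alphaproteobacteria")
  expect_equal(all_good$threshold, 0)

  none <- calibrate_sgs_threshold(
    data.frame(clade_id = c("x", "y"), sgs = c(80, 60),
               group = "Gammaproteobacteria"), "Alphaproteobacteria")
  expect_false(none$usable)
  expect_equal(none$threshold, 80)
})

test_that("clade_support bundles NBS, SGS and the ML sister group", {
  ml <- ape::read.tree(text = "((E1,E2),(P1,(P2,P3)));")
  cs <- clade_support(ml, rep(c(ml), 6), c("E1", "E2"))
  expect_equal(cs$nbs, 100)
  expect_equal(cs$sgs, 1)
  expect_identical(cs$g_ml, "P1")
  expect_length(cs$sisters, 6)
})
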