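test_that("eukaryotic clan extraction finds maximal pure clans", {
  tax <- prefix_tax(c("E1", "E2", "E3", "G1", "G2"))
  tr <- ape::read.tree(text = "((E1,E2),(G1,(E3,G2)));")
  clans <- extract_euk_clades(tr, tax)
  expect_setequal(vapply(clans, paste, character(1), collapse = ","),
                  c("E1,E2", "E3"))

  all_euk <- ape::read.tree(text = "((E1,E2),(E3,F1));")
  clans2 <- extract_euk_clades(all_euk, prefix_tax(c("E1", "E2", "E3", "F1")))
  expect_length(clans2, 1)
  expect_setequal(clans2[[1]], c("E1", "E2", "E3", "F1"))

  scattered <- ape::read.tree(text = "((E1,G1),(E2,(G2,E3)));")
  clans3 <- extract_euk_clades(scattered, tax)
  expect_setequal(vapply(clans3, paste, character(1), collapse = ","),
                  c("E1", "E2", "E3"))

  no_euk <- ape::read.tree(text = "((G1,G2),(A1,A2));")
  expect_length(extract_euk_clades(no_euk, prefix_tax(c("G1", "G2", "A1",
                                                        "A2"))), 0)
})

test_that("extracted clans partition the eukaryotic leaves (oracle check)", {
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    tr <- random_tree(n, multifurcate = rep %% 3 == 0)
    # random eukaryote/prokaryote assignment via label prefixes
    prefixes <- sample(c("E", "F", "G", "R"), n, replace = TRUE)
    tr$tip.label <- paste0(prefixes, seq_len(n))
    tax <- prefix_tax(tr$tip.label)
    euks <- tr$tip.label[startsWith(tr$tip.label, "E") |
                           startsWith(tr$tip.label, "F")]
    clans <- extract_euk_clades(tr, tax)
    expect_setequal(unlist(clans), euks)
    expect_equal(sum(lengths(clans)), length(euks)) # pairwise disjoint
    # each clan is a maximal all-eukaryote clan per the oracle
    for (cl in clans) {
      expect_true(oracle_is_clan(tr, cl))
      bigger <- Filter(function(S) length(S) > length(cl) &&
                         all(cl %in% S) && all(S %in% euks),
                       oracle_sides(tr))
      expect_length(bigger, 0)
    }
  }
})

test_that("intruder flagging follows the size and supergroup-merge rules", {
  # E1 (Unikont) and F2 (Plantae) separated by one bacterium; the archaeal
  # outgroup is larger than the intruder bound so it is never a candidate
  tax <- prefix_tax(c("E1", "G9", "F2", "E3", "E4", "Y1", "Y2", "Y3"))
  tr <- ape::read.tree(text = "(((E1,(G9,F2)),(E3,E4)),(Y1,(Y2,Y3)));")
  expect_identical(flag_intruders(tr, tax), "G9")

  # no prokaryote nested among eukaryotes
  clean <- ape::read.tree(text = "(((E1,F2),(E3,E4)),(G9,(Y1,(Y2,Y3))));")
  expect_length(flag_intruders(clean, tax), 0)

  # prokaryotic clan above the size bound is left alone
  tax3 <- prefix_tax(c("E1", "F2", "G1", "G2", "G3", "E3", "E4",
                       "Y1", "Y2", "Y3", "Y4"))
  tr3 <- ape::read.tree(
    text = "(((E1,((G1,(G2,G3)),F2)),(E3,E4)),((Y1,Y2),(Y3,Y4)));")
  expect_length(flag_intruders(tr3, tax3, max_intruder_size = 2), 0)
  expect_identical(flag_intruders(tr3, tax3, max_intruder_size = 3),
                   c("G1", "G2", "G3"))

  # a small prokaryotic clan separating eukaryote groups is also an
  # intruder, whatever its domain
  taxy <- prefix_tax(c("E1", "G9", "F2", "E3", "E4", "Y1", "Y2"))
  try_ <- ape::read.tree(text = "(((E1,(G9,F2)),(E3,E4)),(Y1,Y2));")
  expect_identical(flag_intruders(try_, taxy), c("G9", "Y1", "Y2"))

  # merging clans of a single supergroup does not trigger the flag
  tax4 <- prefix_tax(c("E1", "G9", "E2", "E3", "E4", "Y1", "Y2", "Y3"))
  tr4 <- ape::read.tree(text = "(((E1,(G9,E2)),(E3,E4)),(Y1,(Y2,Y3)));")
  expect_length(flag_intruders(tr4, tax4), 0)
})

test_that("pruning flagged intruders only merges eukaryotic clans", {
  # deterministic case first, so the property is always exercised
  tax0 <- prefix_tax(c("E1", "G9", "F2", "E3", "E4", "Y1", "Y2"))
  tr0 <- ape::read.tree(text = "(((E1,(G9,F2)),(E3,E4)),(Y1,Y2));")
  before0 <- extract_euk_clades(tr0, tax0)
  after0 <- extract_euk_clades(
    ape::drop.tip(ape::unroot(tr0), flag_intruders(tr0, tax0)), tax0)
  expect_lt(length(after0), length(before0))
  for (cl in before0)
    expect_true(any(vapply(after0, function(a) all(cl %in% a), logical(1))))

  set.seed(77)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    tr <- random_tree(n)
    tr$tip.label <- paste0(sample(c("E", "F", "G", "R"), n, replace = TRUE),
                           seq_len(n))
    tax <- prefix_tax(tr$tip.label)
    if (!length(extract_euk_clades(tr, tax))) next
    flagged <- flag_intruders(tr, tax)
    if (!length(flagged) || length(tr$tip.label) - length(flagged) < 3) next
    before <- extract_euk_clades(tr, tax)
    after <- extract_euk_clades(ape::drop.tip(ape::unroot(tr), flagged), tax)
    expect_lte(length(after), length(before))
    for (cl in before) # clans only merge, never split
      expect_true(any(vapply(after, function(a) all(cl %in% a), logical(1))))
  }
})

test_that("LECA ancestrality rules count species per supergroup", {
  mk <- function(n_uni, n_pla, n_chr = 0, n_kin = 0, uni_species = n_uni) {
    seqs <- c(sprintf("u%d", seq_len(n_uni)), sprintf("p%d", seq_len(n_pla)),
              sprintf("c%d", seq_len(n_chr)), sprintf("k%d", seq_len(n_kin)))
    sg <- rep(c("Unikonts", "Plantae", "Chromalveolates", "Kinetoplastids"),
              c(n_uni, n_pla, n_chr, n_kin))
    species <- c(sprintf("Us%d", pmin(seq_len(n_uni), uni_species)),
                 sprintf("Ps%d", seq_len(n_pla)),
                 sprintf("Cs%d", seq_len(n_chr)),
                 sprintf("Ks%d", seq_len(n_kin)))
    tax <- taxonomy_map(data.frame(
      sequence_id = seqs, species_id = species, group = sg,
      domain = "Eukarya", supergroup = sg, stringsAsFactors = FALSE))
    passes_leca_criteria(seqs, tax)
  }
  expect_identical(mk(2, 2), "R1")
  expect_identical(mk(2, 0, n_chr = 2), "R2")
  expect_identical(mk(0, 2, n_chr = 2), character(0))    # R3 needs kinetoplastid
  expect_identical(mk(0, 2, n_chr = 2, n_kin = 1), "R3")
  # three Unikont sequences from a single species do not count as two
  expect_identical(mk(3, 2, uni_species = 1), character(0))
  # Unikont-only clades never pass
  expect_identical(mk(5, 0), character(0))
  expect_setequal(mk(2, 2, n_chr = 2, n_kin = 1), c("R1", "R2", "R3"))

  tax <- prefix_tax(c("E1", "G1"))
  expect_error(passes_leca_criteria(c("E1", "G1"), tax), "non-eukaryotic")
})
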