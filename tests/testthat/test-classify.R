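test_that("threshold table resolves HALF and NEVER rules", {
  thr <- group_thresholds()
  g <- function(x, col) thr[[col]][thr$group == x]
  expect_equal(g("Actinobacteria", "min_required"), 8L) # half of 15, ceiling
  expect_equal(g("Alphaproteobacteria", "min_required"), 5L)
  expect_equal(g("Euryarchaeota", "min_required"), 13L)
  expect_equal(g("Aquificae", "min_required"), 3L)
  expect_true(is.na(g("Thaumarchaeota", "min_required"))) # NEVER
  expect_true(is.na(g("Fusobacteria", "min_required")))
  expect_equal(sum(thr$sampled[thr$domain == "Archaea"]), 39)
  expect_equal(sum(thr$sampled[thr$domain == "Bacteria"]), 144)

  o <- group_thresholds(overrides = data.frame(
    group = "Alphaproteobacteria", sampled = 6, rule = "3"), domain_min = 7)
  expect_equal(o$min_required[o$group == "Alphaproteobacteria"], 3L)
  expect_equal(attr(o, "domain_min"), 7)
})

# toy taxonomy with enough bacterial species for the domain rule
mixed_tax <- function() {
  prefix_tax(c("E1", "F1",
               paste0("A", 1:6), paste0("G", 1:4), paste0("C", 1:3),
               "D1", paste0("R", 1:3)))
}

test_that("configuration labels reproduce the archetypal cases", {
  tax <- mixed_tax()
  thr <- group_thresholds()

  # eukaryote clan nested inside a clan of 6 alphaproteobacterial species
  # (threshold 5): group-related
  alpha_nested <- ape::read.tree(text = paste0(
    "((G1,(G2,(G3,(G4,(C1,(C2,C3)))))),",
    "((A1,(A2,A3)),((A4,(A5,A6)),(E1,F1))),(R1,(R2,R3)));"))
  lab <- classify_configuration(alpha_nested, c("E1", "F1"), tax, thr)
  expect_identical(lab$kind, "GROUP_RELATED")
  expect_identical(lab$group, "Alphaproteobacteria")
  expect_equal(lab$species_count, 6)

  # sister is one isolated deltaproteobacterium inside a mixed bacterial
  # clan of >= 10 species: bacterial-domain-related, not Deltaproteobacteria
  delta_sister <- ape::read.tree(text = paste0(
    "(((A1,(A2,(A3,(A4,(A5,A6))))),((G1,(G2,(G3,G4))),",
    "((C1,(C2,C3)),(D1,(E1,F1))))),(R1,(R2,R3)));"))
  lab2 <- classify_configuration(delta_sister, c("E1", "F1"), tax, thr)
  expect_identical(lab2$kind, "BACTERIAL_DOMAIN_RELATED")
  expect_identical(classify_naive(delta_sister, c("E1", "F1"), tax),
                   "Deltaproteobacteria")

  # archaeal and bacterial sequences interleaved around the attachment
  tangled <- ape::read.tree(text = paste0(
    "((((E1,F1),(R1,G1)),(R2,C1)),((G2,(R3,G3)),(A1,(C2,C3))));"))
  lab3 <- classify_configuration(tangled, c("E1", "F1"), tax, thr)
  expect_identical(lab3$kind, "UNCLEAR")

  # paraphyletic representatives
  para <- ape::read.tree(text = "((E1,(G1,F1)),(A1,(R1,R2)));")
  expect_identical(classify_configuration(para, c("E1", "F1"), tax,
                                          thr)$kind, "PARAPHYLETIC")
  expect_error(classify_naive(para, c("E1", "F1"), tax), "paraphyletic")
})

test_that("three-domain calls need all domains monophyletic and sampled", {
  # 12 bacterial and 11 archaeal species, three clean domain clans
  labs <- c("E1", "F1", paste0("A", 1:6), paste0("G", 1:6),
            paste0("R", 1:6), paste0("Y", 1:5))
  tax <- prefix_tax(labs)
  nest <- function(x) if (length(x) == 1) x else
    paste0("(", x[1], ",", nest(x[-1]), ")")
  txt <- sprintf("((E1,F1),(%s,%s));",
                 nest(c(paste0("A", 1:6), paste0("G", 1:6))),
                 nest(c(paste0("R", 1:6), paste0("Y", 1:5))))
  tr <- ape::read.tree(text = txt)
  lab <- classify_configuration(tr, c("E1", "F1"), tax)
  expect_identical(lab$kind, "THREE_DOMAIN")

  # with only 9 archaeal species the three-domain call degrades
  tax9 <- prefix_tax(setdiff(labs, c("Y4", "Y5")))
  tr9 <- ape::drop.tip(tr, c("Y4", "Y5"))
  lab9 <- classify_configuration(tr9, c("E1", "F1"), tax9)
  expect_false(identical(lab9$kind, "THREE_DOMAIN"))
})

test_that("classification agrees with the brute-force clan-enumeration classifier", {
  set.seed(99)
  prefixes <- c("E", "F", "A", "G", "C", "D", "R", "Y")
  for (rep in 1:12) {
    n <- sample(8:14, 1)
    tr <- random_tree(n, multifurcate = rep %% 4 == 0)
    pre <- c("E", "F", sample(prefixes, n - 2, replace = TRUE))
    tr$tip.label <- paste0(pre, seq_len(n))
    tax <- prefix_tax(tr$tip.label)
    euks <- tr$tip.label[pre %in% c("E", "F")]
    # thresholds scaled to toy trees so every label kind is reachable
    thr <- group_thresholds(domain_min = 3, three_domain_min = 2,
                            overrides = data.frame(
                              group = c("Alphaproteobacteria",
                                        "Gammaproteobacteria",
                                        "Cyanobacteria", "Crenarchaeota"),
                              sampled = 4, rule = "2"))
    got <- format_configuration(classify_configuration(tr, euks, tax, thr))
    want <- oracle_classify(tr, euks, tax, thr)
    expect_identical(got, want)
  }
})

test_that("naive classification reads the sister group at its lowest uniform rank", {
  tax <- mixed_tax()
  tr <- ape::read.tree(text = "(((E1,F1),(A1,A2)),((G1,C1),(R1,R2)));")
  expect_identical(classify_naive(tr, c("E1", "F1"), tax),
                   "Alphaproteobacteria")
  tr2 <- ape::read.tree(text = "(((E1,F1),(G1,C1)),((A1,A2),(R1,R2)));")
  expect_identical(classify_naive(tr2, c("E1", "F1"), tax), "Bacteria")
  tr3 <- ape::read.tree(text = "((E1,F1),(G1,R1),((A1,A2),(R2,R3)));")
  expect_identical(classify_naive(tr3, c("E1", "F1"), tax), "mixed")
})

test_that("bootstrap profiles tabulate, sum to one, and break ties by specificity", {
  tax <- mixed_tax()
  thr <- group_thresholds()
  alpha_nested <- ape::read.tree(text = paste0(
    "((G1,(G2,(G3,(G4,(C1,(C2,C3)))))),",
    "((A1,(A2,A3)),((A4,(A5,A6)),(E1,F1))),(R1,(R2,R3)));"))
  delta_sister <- ape::read.tree(text = paste0(
    "(((A1,(A2,(A3,(A4,(A5,A6))))),((G1,(G2,(G3,G4))),",
    "((C1,(C2,C3)),(D1,(E1,F1))))),(R1,(R2,R3)));"))
  para <- ape::read.tree(text = paste0(
    "((E1,(G1,F1)),((A1,(A2,(A3,(A4,(A5,A6))))),",
    "((G2,(G3,G4)),((C1,(C2,C3)),(D1,(R1,(R2,R3)))))));"))

  # uniform ensemble
  prof1 <- bootstrap_configuration_profile(rep(c(alpha_nested), 10),
                                           c("E1", "F1"), tax, thr)
  expect_equal(unname(prof1$frequencies), 1)
  expect_identical(prof1$modal, "group:Alphaproteobacteria")

  # 60/40 majority
  prof2 <- bootstrap_configuration_profile(
    c(rep(c(delta_sister), 6), rep(c(para), 4)), c("E1", "F1"), tax, thr)
  expect_equal(sum(prof2$frequencies), 1)
  expect_equal(unname(prof2$frequencies["domain:Bacteria"]), 0.6)
  expect_identical(prof2$modal, "domain:Bacteria")

  # 50/50 tie between a group label and a domain label: the group wins
  prof3 <- bootstrap_configuration_profile(
    c(rep(c(alpha_nested), 5), rep(c(delta_sister), 5)),
    c("E1", "F1"), tax, thr)
  expect_identical(prof3$modal, "group:Alphaproteobacteria")
  expect_equal(unname(prof3$group_fractions["Alphaproteobacteria"]), 0.5)
})
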