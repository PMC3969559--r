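# Small fixtures shared across tests: toy taxonomies and a reduced species
# design that keeps simulated trees small while leaving the default
# Alphaproteobacteria threshold attainable.

toy_tax <- function(seqs, species, group, domain, supergroup = NA) {
  taxonomy_map(data.frame(
    sequence_id = seqs, species_id = species, group = group,
    domain = domain,
    supergroup = ifelse(domain == "Eukarya", supergroup, NA),
    stringsAsFactors = FALSE))
}

# two eukaryotes (one Unikont, one Plantae) plus labelled prokaryotes;
# prokaryote labels encode group: A* Alphaproteobacteria, G* Gamma-,
# D* Delta-, C* Cyanobacteria, R* Crenarchaeota (Archaea), Y* Euryarchaeota
prefix_tax <- function(labels) {
  info <- lapply(labels, function(l) {
    p <- substr(l, 1, 1)
    switch(p,
      E = c("Unikonts", "Eukarya", "Unikonts"),
      F = c("Plantae", "Eukarya", "Plantae"),
      A = c("Alphaproteobacteria", "Bacteria", NA),
      G = c("Gammaproteobacteria", "Bacteria", NA),
      D = c("Deltaproteobacteria", "Bacteria", NA),
      C = c("Cyanobacteria", "Bacteria", NA),
      R = c("Crenarchaeota", "Archaea", NA),
      Y = c("Euryarchaeota", "Archaea", NA),
      stop("unknown label prefix: ", l))
  })
  taxonomy_map(data.frame(
    sequence_id = labels,
    species_id = paste0("sp_", labels),
    group = vapply(info, `[`, character(1), 1),
    domain = vapply(info, `[`, character(1), 2),
    supergroup = vapply(info, `[`, character(1), 3),
    stringsAsFactors = FALSE))
}

small_design <- function() {
  rbind(
    data.frame(group = c("Alphaproteobacteria", "Gammaproteobacteria",
                         "Actinobacteria", "Deltaproteobacteria"),
               domain = "Bacteria", n_species = c(10L, 7L, 15L, 8L),
               stringsAsFactors = FALSE),
    data.frame(group = "Crenarchaeota", domain = "Archaea", n_species = 11L,
               stringsAsFactors = FALSE),
    data.frame(group = c("Unikonts", "Plantae", "Chromalveolates",
                         "Kinetoplastids"),
               domain = "Eukarya", n_species = c(4L, 3L, 3L, 1L),
               stringsAsFactors = FALSE))
}

random_tree <- function(n, multifurcate = FALSE) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::rexp(k))
  if (multifurcate && ape::Ntip(tr) > 4) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.25))
  }
  tr
}
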