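## Pipeline orchestration: detection -> representative sampling ->
## configuration classification -> support statistics over a collection of
## gene families, producing one report row per retained LECA clade plus
## structured logs for families that yield none.

.kind_of_label <- function(label) {
  ifelse(startsWith(label, "group:"), "GROUP_RELATED",
  ifelse(label == "domain:Bacteria", "BACTERIAL_DOMAIN_RELATED",
  ifelse(label == "domain:Archaea", "ARCHAEAL_DOMAIN_RELATED",
  ifelse(label == "three_domain", "THREE_DOMAIN",
  ifelse(label == "unclear", "UNCLEAR", "PARAPHYLETIC")))))
}

#' Read a directory of gene families
#'
#' Families are file pairs `<id>.ml.nwk` (single Newick ML tree) and
#' `<id>.boot.nwk` (one replicate tree per line). A family without a
#' replicate file is kept with a warning; its support statistics will be
#' blank.
#'
#' @param dir Directory path.
#' @return List of `simulated_family`-shaped lists (without taxonomy).
#' @export
read_family_dir <- function(dir) {
  mls <- sort(list.files(dir, pattern = "\\.ml\\.nwk$", full.names = TRUE))
  fams <- list()
  for (p in mls) {
    id <- sub("\\.ml\\.nwk$", "", basename(p))
    bp <- file.path(dir, paste0(id, ".boot.nwk"))
    reps <- NULL
    if (file.exists(bp)) reps <- read_gene_trees(bp)
    else warning("family ", id, " has no replicate file; ML-only analysis",
                 call. = FALSE)
    fams[[length(fams) + 1L]] <-
      list(family_id = id, ml_tree = read_gene_tree(p), replicates = reps,
           truth = NULL)
  }
  fams
}

#' Run the full LECA-origin pipeline
#'
#' For every family: flags (and optionally prunes) prokaryotic intruders,
#' extracts eukaryotic clans, keeps those satisfying a LECA ancestrality
#' rule, samples k representatives per clade, restricts the ML tree and the
#' bootstrap replicates to the representatives plus all prokaryotic leaves,
#' and then (i) discards clades whose representative-set monophyly support
#' is not strictly above `retention` percent, (ii) classifies the ML and
#' every bootstrap tree into configurations, and (iii) computes NBS, SGS,
#' the ML sister group, per-domain monophyly supports and the near-universal
#' flag. Rows are sorted by configuration class and decreasing NBS.
#'
#' @param families A `simulated_dataset`, a list of `simulated_family`
#'   objects, or a directory path (see [read_family_dir()]).
#' @param taxonomy A [taxonomy_map()] or TSV path covering every leaf
#'   (taken from the dataset when `families` is a `simulated_dataset`).
#' @param thresholds A [group_thresholds()] table.
#' @param k Representatives per clade (default 10).
#' @param retention Monophyly-support retention threshold in percent;
#'   clades at or below it are discarded as ambiguous (default 50, strict
#'   `>`).
#' @param prune_intruders Prune flagged prokaryotic intruders before clan
#'   extraction (default TRUE).
#' @param max_intruder_size Passed to [flag_intruders()].
#' @param near_universal_fraction Coverage fraction for the near-universal
#'   flag (default 0.9).
#' @return An object of class `leca_scan`: list with `clades` (one row per
#'   retained LECA clade), `summary` (counts per configuration), `logs`
#'   (`no_leca`, `ambiguous`, `intruders`) and `config`.
#' @export
run_pipeline <- function(families, taxonomy = NULL,
                         thresholds = group_thresholds(), k = 10,
                         retention = 50, prune_intruders = TRUE,
                         max_intruder_size = 2,
                         near_universal_fraction = 0.9) {
  if (inherits(families, "simulated_dataset")) {
    if (is.null(taxonomy)) taxonomy <- families$taxonomy
    families <- families$families
  } else if (is.character(families) && length(families) == 1L) {
    families <- read_family_dir(families)
  }
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (!inherits(taxonomy, "taxonomy_map")) stop("need a taxonomy_map")

  sp <- unique(as.data.frame(taxonomy)[, c("species_id", "domain")])
  totals <- c(Archaea = sum(sp$domain == "Archaea"),
              Bacteria = sum(sp$domain == "Bacteria"))

  rows <- list()
  logs <- list(no_leca = character(0), ambiguous = character(0),
               intruders = list())
  for (fam in families) {
    id <- fam$family_id
    det <- detect_leca_clades(fam$ml_tree, taxonomy,
                              max_intruder_size = max_intruder_size,
                              prune_intruders = prune_intruders)
    if (length(attr(det, "intruders")))
      logs$intruders[[id]] <- attr(det, "intruders")
    if (length(det) == 0L) {
      logs$no_leca <- c(logs$no_leca, id)
      next
    }
    used <- attr(det, "tree")
    fam_species <- unique(tax_species(taxonomy, fam$ml_tree$tip.label))
    nu <- near_universal_filter(fam_species, taxonomy,
                                fraction = near_universal_fraction,
                                totals = totals)
    prok_leaves <- used$tip.label[tax_domain(taxonomy, used$tip.label) !=
                                    "Eukarya"]
    hgt_flag <- !is.null(fam$truth) &&
      any(fam$truth$events$type %in% c("hgt", "mix_transfer"))

    for (ci in seq_along(det)) {
      clade <- det[[ci]]
      reps <- sample_representatives(used, clade$leaves, k = k)
      keep_set <- c(reps, prok_leaves)
      ml_r <- ape::keep.tip(.as_unrooted(used), keep_set)
      clade_id <- paste0(id, ".", ci)

      if (is.null(fam$replicates)) {
        lab <- format_configuration(
          classify_configuration(ml_r, reps, taxonomy, thresholds))
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = id, clade_id = clade_id, n_leaves = length(clade$leaves),
          rules = paste(clade$rules, collapse = "+"),
          representatives = paste(reps, collapse = ","),
          ml_config = lab, modal_config = NA_character_,
          config_freqs = NA_character_, mono_support = NA_real_,
          nbs = NA_real_, sgs_percent = NA_real_, g_ml = NA_character_,
          near_universal = nu, arch_mono = NA_real_, bact_mono = NA_real_,
          hgt_flag = hgt_flag, stringsAsFactors = FALSE)
        next
      }

      boot_r <- lapply(fam$replicates, function(tr)
        ape::keep.tip(.as_unrooted(tr), keep_set))
      class(boot_r) <- "multiPhylo"

      mono <- monophyly_support(boot_r, reps)
      if (mono <= retention) {
        logs$ambiguous <- c(logs$ambiguous, clade_id)
        next
      }

      ml_label <- format_configuration(
        classify_configuration(ml_r, reps, taxonomy, thresholds))
      prof <- bootstrap_configuration_profile(boot_r, reps, taxonomy,
                                              thresholds)
      nbs_v <- tryCatch(nbs(ml_r, boot_r, reps), error = function(e) NA_real_)
      sgs_v <- as.numeric(sgs(boot_r, reps))
      g_ml <- tryCatch(paste(sister_group(ml_r, reps), collapse = ","),
                       error = function(e) NA_character_)
      arch <- ml_r$tip.label[tax_domain(taxonomy, ml_r$tip.label) == "Archaea"]
      bact <- ml_r$tip.label[tax_domain(taxonomy, ml_r$tip.label) ==
                               "Bacteria"]
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = id, clade_id = clade_id, n_leaves = length(clade$leaves),
        rules = paste(clade$rules, collapse = "+"),
        representatives = paste(reps, collapse = ","),
        ml_config = ml_label, modal_config = prof$modal,
        config_freqs = paste(sprintf("%s=%.2f", names(prof$frequencies),
                                     prof$frequencies), collapse = ";"),
        mono_support = mono, nbs = nbs_v, sgs_percent = 100 * sgs_v,
        g_ml = g_ml, near_universal = nu,
        arch_mono = if (length(arch)) monophyly_support(boot_r, arch)
                    else NA_real_,
        bact_mono = if (length(bact)) monophyly_support(boot_r, bact)
                    else NA_real_,
        hgt_flag = hgt_flag, stringsAsFactors = FALSE)
    }
  }

  clades <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), clade_id = character(),
               ml_config = character(), stringsAsFactors = FALSE)
  if (nrow(clades)) {
    kind <- factor(.kind_of_label(clades$ml_config),
                   levels = configuration_kinds())
    o <- order(kind, -ifelse(is.na(clades$nbs), -1, clades$nbs),
               clades$clade_id)
    clades <- clades[o, ]
    rownames(clades) <- NULL
  }
  summary_tab <- if (nrow(clades)) table(clades$ml_config) else table(character())
  structure(list(clades = clades, summary = summary_tab, logs = logs,
                 config = list(k = k, retention = retention,
                               thresholds = thresholds,
                               near_universal_fraction =
                                 near_universal_fraction,
                               totals = totals)),
            class = "leca_scan")
}

#' @export
print.leca_scan <- function(x, ...) {
  cat("LECA origin scan:", nrow(x$clades), "retained clade(s);",
      length(x$logs$no_leca), "family(ies) without LECA clade;",
      length(x$logs$ambiguous), "ambiguous clade(s) discarded\n")
  if (nrow(x$clades)) {
    cat("ML configurations:\n")
    print(x$summary)
  }
  invisible(x)
}

#' @export
summary.leca_scan <- function(object, ...) {
  x <- object
  cat("LECA origin scan\n")
  cat("  retained clades:   ", nrow(x$clades), "\n")
  cat("  no-LECA families:  ", length(x$logs$no_leca), "\n")
  cat("  ambiguous discards:", length(x$logs$ambiguous), "\n")
  cat("  intruder prunings: ", length(x$logs$intruders), "\n")
  if (nrow(x$clades)) {
    cat("\nML configuration counts:\n")
    print(x$summary)
    if (!all(is.na(x$clades$modal_config))) {
      cat("\nModal bootstrap configuration counts:\n")
      print(table(x$clades$modal_config))
    }
    cat("\nSupport: median NBS =",
        stats::median(x$clades$nbs, na.rm = TRUE),
        "; median SGS =", stats::median(x$clades$sgs_percent, na.rm = TRUE),
        "%\n")
  }
  invisible(x)
}

#' @export
plot.leca_scan <- function(x, ...) {
  if (!nrow(x$clades)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  d <- x$clades
  kind <- factor(.kind_of_label(d$ml_config), levels = configuration_kinds())
  cols <- c(GROUP_RELATED = "#1b9e77", BACTERIAL_DOMAIN_RELATED = "#7570b3",
            ARCHAEAL_DOMAIN_RELATED = "#d95f02", THREE_DOMAIN = "#e7298a",
            UNCLEAR = "grey60", PARAPHYLETIC = "grey30")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(d$nbs, col = cols[as.character(kind)], border = NA,
                    ylab = "NBS (%)", xlab = "LECA clades", main = "NBS",
                    ylim = c(0, 100))
  graphics::barplot(d$sgs_percent, col = cols[as.character(kind)],
                    border = NA, ylab = "SGS (%)", xlab = "LECA clades",
                    main = "SGS", ylim = c(0, 100))
  invisible(x)
}

#' Domain-monophyly summary over near-universal families
#'
#' Restricts the report to near-universal, non-bacteria-related clades
#' without transfer flags and summarises the bootstrap supports for the
#' monophyly of Archaea and of Bacteria: the per-clade values, their means,
#' and decile histogram counts.
#'
#' @param scan A [run_pipeline()] result.
#' @return List with `table`, `mean_arch`, `mean_bact`, `hist_breaks`,
#'   `hist_arch`, `hist_bact` (empty table when no row qualifies).
#' @export
summarize_universal <- function(scan) {
  d <- scan$clades
  thr <- scan$config$thresholds
  if (nrow(d)) {
    kind <- .kind_of_label(d$ml_config)
    grp <- sub("^group:", "", d$ml_config)
    grp_dom <- thr$domain[match(grp, thr$group)]
    bact_related <- kind == "BACTERIAL_DOMAIN_RELATED" |
      (kind == "GROUP_RELATED" & grp_dom %in% "Bacteria")
    d <- d[d$near_universal & !bact_related & !d$hgt_flag &
             !is.na(d$arch_mono) & !is.na(d$bact_mono), ]
  }
  if (!nrow(d)) {
    message("no near-universal, non-bacteria-related clades in the report")
    return(list(table = d, mean_arch = NA_real_, mean_bact = NA_real_,
                hist_breaks = seq(0, 100, 10),
                hist_arch = integer(10), hist_bact = integer(10)))
  }
  br <- seq(0, 100, 10)
  list(table = d[, c("family_id", "clade_id", "ml_config", "arch_mono",
                     "bact_mono")],
       mean_arch = mean(d$arch_mono), mean_bact = mean(d$bact_mono),
       hist_breaks = br,
       hist_arch = graphics::hist(d$arch_mono, breaks = br,
                                  plot = FALSE)$counts,
       hist_bact = graphics::hist(d$bact_mono, breaks = br,
                                  plot = FALSE)$counts)
}

#' Write the pipeline report as TSV files
#'
#' Writes `clades.tsv` (one row per retained LECA clade), `summary.tsv`
#' (configuration counts) and `logs.tsv`.
#'
#' @param scan A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_leca_report <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(scan$clades, file.path(dir, "clades.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  s <- as.data.frame(scan$summary, stringsAsFactors = FALSE)
  names(s) <- c("ml_config", "count")[seq_len(ncol(s))]
  utils::write.table(s, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mk <- function(event, ids) {
    if (!length(ids)) return(NULL)
    data.frame(event = event, id = as.character(ids),
               stringsAsFactors = FALSE)
  }
  logs <- rbind(mk("no_leca", scan$logs$no_leca),
                mk("ambiguous", scan$logs$ambiguous),
                mk("intruders_flagged", names(scan$logs$intruders)))
  if (is.null(logs))
    logs <- data.frame(event = character(), id = character(),
                       stringsAsFactors = FALSE)
  utils::write.table(logs, file.path(dir, "logs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
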