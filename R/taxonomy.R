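#' Taxonomy tables
#'
#' A taxonomy map links every sequence identifier occurring in a gene tree to
#' its species, taxonomic group (phylum, or class for Proteobacteria and
#' Firmicutes), domain of life, and -- for eukaryotes -- supergroup. All
#' tree-reading in the pipeline goes through this lens: clan purity, species
#' counting and the LECA ancestrality rules are all defined on these columns.
#'
#' @param x A data.frame with columns `sequence_id`, `species_id`, `group`,
#'   `domain` and `supergroup`. `domain` must be one of `"Bacteria"`,
#'   `"Archaea"`, `"Eukarya"`; `supergroup` must be one of [euk_supergroups()]
#'   for eukaryotes and `NA` for prokaryotes.
#'
#' @return An object of class `taxonomy_map` (a validated data.frame).
#' @examples
#' tax <- taxonomy_map(data.frame(
#'   sequence_id = c("hs1", "ec1"),
#'   species_id  = c("Hsap", "Ecoli"),
#'   group       = c("Unikonts", "Gammaproteobacteria"),
#'   domain      = c("Eukarya", "Bacteria"),
#'   supergroup  = c("Unikonts", NA)))
#' tax_domain(tax, "ec1")
#' @export
taxonomy_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("sequence_id", "species_id", "group", "domain", "supergroup")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[, needed]
  for (col in needed) x[[col]] <- as.character(x[[col]])
  x$supergroup[x$supergroup %in% c("NA", "")] <- NA_character_

  dup <- x$sequence_id[duplicated(x$sequence_id)]
  if (length(dup))
    stop("duplicated sequence_id in taxonomy: ", paste(unique(dup), collapse = ", "))
  bad_dom <- setdiff(unique(x$domain), c("Bacteria", "Archaea", "Eukarya"))
  if (length(bad_dom))
    stop("unknown domain: ", paste(bad_dom, collapse = ", "))

  is_euk <- x$domain == "Eukarya"
  if (any(is_euk & is.na(x$supergroup)))
    stop("eukaryotic records must carry a supergroup: ",
         paste(x$sequence_id[is_euk & is.na(x$supergroup)], collapse = ", "))
  if (any(!is_euk & !is.na(x$supergroup)))
    stop("prokaryotic records must have supergroup NA: ",
         paste(x$sequence_id[!is_euk & !is.na(x$supergroup)], collapse = ", "))
  bad_sg <- setdiff(unique(x$supergroup[is_euk]), euk_supergroups())
  if (length(bad_sg))
    stop("unknown eukaryotic supergroup: ", paste(bad_sg, collapse = ", "))

  # every species maps to exactly one group and domain
  sp <- unique(x[, c("species_id", "group", "domain")])
  dup_sp <- sp$species_id[duplicated(sp$species_id)]
  if (length(dup_sp))
    stop("species mapped to more than one group/domain: ",
         paste(unique(dup_sp), collapse = ", "))

  rownames(x) <- NULL
  class(x) <- c("taxonomy_map", "data.frame")
  x
}

#' @describeIn taxonomy_map Recognised eukaryotic supergroup labels.
#' @export
euk_supergroups <- function() {
  c("Unikonts", "Plantae", "Chromalveolates", "Kinetoplastids", "OtherEukaryote")
}

#' Read a taxonomy table from a tab-separated file
#'
#' The file must have a header with columns `sequence_id`, `species_id`,
#' `group`, `domain`, `supergroup` (supergroup `NA` for prokaryotes).
#'
#' @param path Path to a UTF-8, tab-separated file.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  taxonomy_map(x)
}

#' Write a taxonomy table as TSV
#' @param tax A [taxonomy_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## Vectorised lookups; error loudly on any label missing from the map, since a
## silent NA would corrupt species counts downstream.
tax_field <- function(tax, labels, field) {
  i <- match(labels, tax$sequence_id)
  if (anyNA(i))
    stop("sequence(s) absent from taxonomy: ",
         paste(labels[is.na(i)], collapse = ", "))
  tax[[field]][i]
}

#' Taxonomy lookups for tree leaves
#'
#' Vectorised accessors mapping sequence ids to taxonomy columns. All error
#' if any label is missing from the map.
#'
#' @param tax A [taxonomy_map()].
#' @param labels Character vector of sequence ids.
#' @return Character vector, parallel to `labels`.
#' @export
tax_domain <- function(tax, labels) tax_field(tax, labels, "domain")

#' @rdname tax_domain
#' @export
tax_group <- function(tax, labels) tax_field(tax, labels, "group")

#' @rdname tax_domain
#' @export
tax_species <- function(tax, labels) tax_field(tax, labels, "species_id")

#' @rdname tax_domain
#' @export
tax_supergroup <- function(tax, labels) tax_field(tax, labels, "supergroup")

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("Taxonomy map:", nrow(x), "sequences,",
      length(unique(x$species_id)), "species\n")
  tb <- table(x$domain[!duplicated(x$species_id)])
  cat("  species per domain:",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
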