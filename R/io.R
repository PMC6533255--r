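# Reading, validating and writing the species-by-trait table and the
# phylogenies used for imputation.

#' The ten diet category column names
#'
#' Internal column names for the ten-category diet composition
#' (percent use per category), following the EltonTraits granularity:
#' invertebrates, endothermic vertebrates, ectothermic vertebrates,
#' fish, vertebrates of unknown type, scavenged carrion, fruit, nectar,
#' seed, and other plant material.
#'
#' @return character vector of length 10.
#' @export
diet_categories <- function() {
  c("diet_inv", "diet_vend", "diet_vect", "diet_vfish", "diet_vunk",
    "diet_scav", "diet_fruit", "diet_nect", "diet_seed", "diet_planto")
}

iucn_codes <- function() c("CR", "EN", "VU", "NT", "LC", "DD")

core_traits <- function() {
  c("body_mass", "litter_clutch_size", "habitat_breadth",
    "generation_length")
}

# Column dictionary: maps external header spellings (EltonTraits /
# figshare conventions) onto the internal schema so real exports load
# unmodified. Internal names map to themselves.
column_dictionary <- function() {
  ext <- c(
    species_id         = "Scientific",
    taxon_class        = "Class",
    body_mass          = "BodyMass.Value",
    litter_clutch_size = "Litter.Clutch.size",
    habitat_breadth    = "Habitat.breadth",
    generation_length  = "GenerationLength.years",
    iucn_category      = "IUCN.Status",
    diet_inv           = "Diet.Inv",
    diet_vend          = "Diet.Vend",
    diet_vect          = "Diet.Vect",
    diet_vfish         = "Diet.Vfish",
    diet_vunk          = "Diet.Vunk",
    diet_scav          = "Diet.Scav",
    diet_fruit         = "Diet.Fruit",
    diet_nect          = "Diet.Nect",
    diet_seed          = "Diet.Seed",
    diet_planto        = "Diet.PlantO"
  )
  c(setNames(names(ext), ext), setNames(names(ext), names(ext)))
}

trait_table_columns <- function() {
  c("species_id", "taxon_class", "body_mass", "litter_clutch_size",
    "habitat_breadth", "generation_length", diet_categories(),
    "iucn_category")
}

#' Construct and validate a trait table
#'
#' Checks a data frame against the trait-table schema: unique species
#' ids, taxon class in `{mammal, bird}`, positive body mass and
#' generation length, litter/clutch size at least 1, integer habitat
#' breadth at least 1, diet rows that are either all missing or
#' non-negative and summing to 100 (within 0.5), and known IUCN
#' category codes. Missing values are `NA`.
#'
#' @param df data frame with the columns of [trait_table_columns()].
#' @return `df` with class `trait_table`, invisibly validated.
#' @export
trait_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(trait_table_columns(), names(df))
  if (length(missing_cols))
    stop("trait table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, trait_table_columns()]
  df$species_id <- as.character(df$species_id)
  df$taxon_class <- tolower(as.character(df$taxon_class))
  df$iucn_category <- toupper(as.character(df$iucn_category))
  if (anyDuplicated(df$species_id))
    stop("duplicate species_id: ",
         paste(unique(df$species_id[duplicated(df$species_id)]),
               collapse = ", "))
  bad_class <- !df$taxon_class %in% c("mammal", "bird")
  if (any(bad_class))
    stop("taxon_class must be 'mammal' or 'bird' (offending: ",
         paste(head(df$species_id[bad_class]), collapse = ", "), ")")
  bad_iucn <- !is.na(df$iucn_category) & !df$iucn_category %in% iucn_codes()
  if (any(bad_iucn))
    stop("unknown IUCN category code for: ",
         paste(head(df$species_id[bad_iucn]), collapse = ", "))
  chk_pos <- function(col, lo = 0) {
    v <- df[[col]]
    bad <- !is.na(v) & v <= lo
    if (any(bad))
      stop(col, " must be > ", lo, " (offending: ",
           paste(head(df$species_id[bad]), collapse = ", "), ")")
  }
  chk_pos("body_mass"); chk_pos("generation_length")
  v <- df$litter_clutch_size
  if (any(!is.na(v) & v < 1))
    stop("litter_clutch_size must be >= 1 (offending: ",
         paste(head(df$species_id[!is.na(v) & v < 1]), collapse = ", "), ")")
  hb <- df$habitat_breadth
  bad <- !is.na(hb) & (hb < 1 | abs(hb - round(hb)) > 1e-8)
  if (any(bad))
    stop("habitat_breadth must be a positive integer (offending: ",
         paste(head(df$species_id[bad]), collapse = ", "), ")")
  dm <- as.matrix(df[, diet_categories()])
  some <- rowSums(!is.na(dm)) > 0
  partial <- some & rowSums(is.na(dm)) > 0
  if (any(partial))
    stop("diet rows must be complete or entirely missing (offending: ",
         paste(head(df$species_id[partial]), collapse = ", "), ")")
  if (any(dm[some, ] < 0, na.rm = TRUE))
    stop("negative diet percentages")
  sums <- rowSums(dm[some, , drop = FALSE])
  off <- abs(sums - 100) > 0.5
  if (any(off))
    stop("diet composition does not sum to 100 (+-0.5) for: ",
         paste(head(df$species_id[some][off]), collapse = ", "))
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a species-by-trait CSV
#'
#' Reads a UTF-8 CSV with a header, translates external column names
#' (EltonTraits / figshare conventions) via the built-in column
#' dictionary, validates the result against the trait-table schema and
#' logs a per-trait missing-value report. Empty cells and `"NA"` are
#' the missing-value markers.
#'
#' @param path path to the CSV file.
#' @param quiet suppress the validation report message.
#' @return a validated [trait_table()].
#' @export
read_trait_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  dict <- column_dictionary()
  known <- names(df) %in% names(dict)
  names(df)[known] <- dict[names(df)[known]]
  tt <- trait_table(df)
  if (!quiet) {
    miss <- vapply(c(core_traits(), "diet"), function(tr) {
      if (tr == "diet") sum(is.na(tt[[diet_categories()[1]]]))
      else sum(is.na(tt[[tr]]))
    }, integer(1))
    message("read ", nrow(tt), " species; missing per trait: ",
            paste(names(miss), miss, sep = "=", collapse = ", "))
  }
  tt
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_table()]: the written file reads back to a
#' semantically identical table (missing cells as empty strings).
#'
#' @param x a `trait_table`.
#' @param path output path.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a Newick phylogeny and compute patristic distances
#'
#' Parses a Newick tree (branch lengths required), computes the matrix
#' of patristic (sum-of-branch-length) distances between tips, and, if
#' `species` is given, restricts it to the intersection of tip labels
#' and species ids (exact string match), warning about tips and species
#' left unmatched.
#'
#' @param path path to a Newick file.
#' @param species optional character vector of species ids to match.
#' @return symmetric distance matrix with tip labels as dimnames;
#'   attribute `unmatched_tips` / `unmatched_species` list the leftovers.
#' @export
read_tree <- function(path, species = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  patristic_distances(tr, species = species)
}

#' Patristic distance matrix of a phylo object
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @inheritParams read_tree
#' @return see [read_tree()].
#' @export
patristic_distances <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree")
  d <- ape::cophenetic.phylo(tree)
  unmatched_tips <- character(0); unmatched_species <- character(0)
  if (!is.null(species)) {
    common <- intersect(rownames(d), species)
    if (length(common) == 0L)
      stop("no tips in common between tree and trait table")
    unmatched_tips <- setdiff(rownames(d), species)
    unmatched_species <- setdiff(species, rownames(d))
    if (length(unmatched_tips))
      warning("tree tips absent from trait table: ",
              paste(head(unmatched_tips), collapse = ", "))
    d <- d[common, common]
  }
  structure(d, unmatched_tips = unmatched_tips,
            unmatched_species = unmatched_species)
}
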