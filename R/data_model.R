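# Core record types, tabular I/O, clinical-label mapping, dataset filters and
# sequence-derived residue attributes.

#' Canonical amino acids
#'
#' The 20 canonical single-letter amino-acid codes.
#' @export
CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue-set attribute definitions: membership sets over the canonical
# alphabet, each a binary residue property commonly linked to missense impact.
RESIDUE_SETS <- list(
  polar              = c("S", "T", "C", "Y", "N", "Q", "G"),
  hydrophobic        = c("A", "V", "I", "L", "M", "F", "Y", "W"),
  charged            = c("R", "H", "K", "D", "E"),
  aromatic           = c("F", "W", "Y", "H"),
  acidic             = c("D", "E"),
  basic              = c("R", "H", "K"),
  uncharged_polar    = c("S", "T", "N", "Q", "C", "Y"),
  small              = c("G", "A", "S", "T", "P"),
  sulfur_binding     = c("C", "M"),
  proline_or_glycine = c("P", "G"),
  aliphatic          = c("V", "I", "L", "M", "A"),
  helix_breaker      = c("G", "P"),
  beta_branched      = c("I", "V", "T")
)

# Default column names for tab-separated variant tables; every entry can be
# remapped through the `dialect` argument of read_variant_table().
DEFAULT_DIALECT <- c(protein_id = "protein_id", position = "position",
                     wt = "wt", mut = "mut", score = "score", label = "label",
                     disorder = "disorder", ppi = "ppi",
                     cluster_size = "cluster_size", length = "length")

#' Construct a variant table
#'
#' A variant table is a data frame with one row per missense variant and
#' columns \code{protein_id}, \code{position} (1-based), \code{wt},
#' \code{mut} (single-letter amino acids), \code{score} (raw predictor score
#' or LLR), optional \code{label} (1 = pathogenic, 0 = benign, NA = unknown)
#' and any number of tri-state logical attribute columns (TRUE/FALSE/NA,
#' where NA means the annotation is missing and is never imputed).
#'
#' @param df data frame holding at least the mandatory columns.
#' @param attributes character vector naming the attribute columns; defaults
#'   to every logical column of \code{df}.
#' @return an object of class \code{variant_table} (a data frame).
#' @export
variant_table <- function(df, attributes = NULL) {
  mandatory <- c("protein_id", "position", "wt", "mut", "score")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$protein_id <- as.character(df$protein_id)
  df$position <- as.integer(df$position)
  df$wt <- toupper(as.character(df$wt))
  df$mut <- toupper(as.character(df$mut))
  df$score <- as.numeric(df$score)
  bad_aa <- which(!(df$wt %in% CANONICAL_AA) | !(df$mut %in% CANONICAL_AA))
  if (length(bad_aa) > 0) {
    stop("invalid amino-acid letter in row(s): ",
         paste(utils::head(bad_aa, 5), collapse = ", "))
  }
  if (any(df$position < 1, na.rm = TRUE)) stop("positions must be >= 1")
  same <- which(df$wt == df$mut)
  if (length(same) > 0) {
    stop("wild-type equals mutant amino acid in row(s): ",
         paste(utils::head(same, 5), collapse = ", "))
  }
  if ("label" %in% names(df)) {
    df$label <- as.integer(df$label)
    if (!all(df$label %in% c(0L, 1L, NA_integer_))) {
      stop("labels must be 0, 1 or NA")
    }
  }
  if (is.null(attributes)) {
    attributes <- names(df)[vapply(df, is.logical, logical(1))]
  }
  stopifnot(all(attributes %in% names(df)))
  for (a in attributes) df[[a]] <- as.logical(df[[a]])
  rownames(df) <- NULL
  structure(df, attributes = attributes,
            class = c("variant_table", "data.frame"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x), "variants across",
      length(unique(x$protein_id)), "proteins\n")
  attrs <- attr(x, "attributes")
  if (length(attrs) > 0) cat("  attributes:", paste(attrs, collapse = ", "), "\n")
  if ("label" %in% names(x) && any(!is.na(x$label))) {
    cat("  labels:", sum(x$label == 1L, na.rm = TRUE), "pathogenic /",
        sum(x$label == 0L, na.rm = TRUE), "benign\n")
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Attribute names of a variant table
#' @param table a \code{variant_table}.
#' @return character vector of attribute column names.
#' @export
attribute_names <- function(table) attr(table, "attributes") %||% character(0)

#' Read a variant table from a tab-separated file
#'
#' The file must be tab-separated with a header row.  Core columns are located
#' through \code{dialect}; every remaining column not matched by the dialect is
#' parsed as a tri-state logical attribute (accepted spellings: TRUE/FALSE,
#' T/F, 1/0, yes/no; anything unparseable, including empty cells, becomes NA).
#'
#' @param path file path.
#' @param dialect named character vector remapping canonical column names
#'   (\code{protein_id}, \code{position}, \code{wt}, \code{mut}, \code{score},
#'   \code{label}, \code{disorder}, \code{ppi}, \code{cluster_size},
#'   \code{length}) to the file's header names.
#' @return a \code{variant_table}; the numeric annotation columns
#'   \code{disorder}, \code{cluster_size} and \code{length} are kept under
#'   their canonical names when present.
#' @export
read_variant_table <- function(path, dialect = DEFAULT_DIALECT) {
  dialect <- c(dialect, DEFAULT_DIALECT[setdiff(names(DEFAULT_DIALECT),
                                                names(dialect))])
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  mandatory <- c("protein_id", "position", "wt", "mut", "score")
  for (col in mandatory) {
    if (!(dialect[[col]] %in% names(raw))) {
      stop("input file lacks mandatory column '", dialect[[col]],
           "' (", col, ")")
    }
  }
  out <- data.frame(protein_id = as.character(raw[[dialect[["protein_id"]]]]),
                    position = raw[[dialect[["position"]]]],
                    wt = raw[[dialect[["wt"]]]],
                    mut = raw[[dialect[["mut"]]]],
                    score = raw[[dialect[["score"]]]],
                    stringsAsFactors = FALSE)
  used <- vapply(mandatory, function(col) dialect[[col]], character(1))
  numeric_annot <- c("disorder", "cluster_size", "length")
  for (col in numeric_annot) {
    if (dialect[[col]] %in% names(raw)) {
      out[[col]] <- as.numeric(raw[[dialect[[col]]]])
      used <- c(used, dialect[[col]])
    }
  }
  if (dialect[["label"]] %in% names(raw)) {
    out$label <- as.integer(raw[[dialect[["label"]]]])
    used <- c(used, dialect[["label"]])
  }
  attrs <- character(0)
  for (col in setdiff(names(raw), used)) {
    canonical <- if (identical(col, dialect[["ppi"]])) "ppi" else col
    out[[canonical]] <- parse_tristate(raw[[col]])
    attrs <- c(attrs, canonical)
  }
  variant_table(out, attributes = attrs)
}

parse_tristate <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  as.logical(out)
}

#' Write a variant table to a tab-separated file
#' @param table a \code{variant_table}.
#' @param path output file path.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Map clinical-significance strings to binary labels
#'
#' Likely pathogenic / Pathogenic\\Likely pathogenic / Pathogenic map to 1;
#' Benign / Benign\\Likely benign / Likely benign map to 0; every other
#' string (e.g. uncertain significance, conflicting interpretations) is
#' rejected and yields NA.
#'
#' @param text character vector of clinical-significance strings.
#' @return integer vector of 1 (pathogenic), 0 (benign) or NA (rejected).
#' @export
map_clinical_significance <- function(text) {
  pathogenic <- c("likely pathogenic", "pathogenic/likely pathogenic",
                  "pathogenic")
  benign <- c("benign", "benign/likely benign", "likely benign")
  key <- tolower(trimws(text))
  out <- rep(NA_integer_, length(key))
  out[key %in% pathogenic] <- 1L
  out[key %in% benign] <- 0L
  out
}

#' Sequence-derived residue attributes
#'
#' Membership of an amino acid in each binary residue-property set (polar,
#' hydrophobic, charged, aromatic, acidic, basic, uncharged polar, small,
#' sulfur-binding, proline-or-glycine, aliphatic, helix-breaker,
#' beta-branched).
#'
#' @param aa single canonical amino-acid letter.
#' @return named logical vector, one entry per residue-set attribute.
#' @export
sequence_attributes <- function(aa) {
  aa <- toupper(aa)
  if (length(aa) != 1 || !(aa %in% CANONICAL_AA)) {
    stop("'", aa, "' is not a canonical amino-acid letter")
  }
  vapply(RESIDUE_SETS, function(set) aa %in% set, logical(1))
}

#' Threshold-based residue and protein attributes
#'
#' Binarizes continuous annotations: a residue is disordered when its
#' predicted disorder score exceeds 0.7 (strict), a sequence is low-homology
#' when its homolog-cluster size is at most \code{homology_cutoff} (default
#' 10), and a protein is long when its length exceeds 1022 residues (the
#' context limit that forces sliding-window scoring).  Missing inputs yield
#' missing outputs.
#'
#' @param disorder_score per-residue disorder score in [0,1], or NA.
#' @param cluster_size homolog-cluster size (non-negative integer), or NA.
#' @param protein_length protein length in residues (>= 1).
#' @param disorder_cutoff disorder threshold, default 0.7 (strict >).
#' @param homology_cutoff low-homology cutoff, default 10 (inclusive <=).
#' @param length_cutoff long-protein cutoff, default 1022 (strict >).
#' @return named logical vector with entries \code{disordered},
#'   \code{low_homology}, \code{long_protein} (NA where the input is NA).
#' @export
threshold_attributes <- function(disorder_score = NA, cluster_size = NA,
                                 protein_length,
                                 disorder_cutoff = 0.7,
                                 homology_cutoff = 10,
                                 length_cutoff = 1022) {
  if (any(protein_length < 1, na.rm = TRUE)) stop("protein_length must be >= 1")
  if (any(cluster_size < 0, na.rm = TRUE)) stop("cluster_size must be >= 0")
  c(disordered = ifelse(is.na(disorder_score), NA,
                        disorder_score > disorder_cutoff),
    low_homology = ifelse(is.na(cluster_size), NA,
                          cluster_size <= homology_cutoff),
    long_protein = ifelse(is.na(protein_length), NA,
                          protein_length > length_cutoff))
}

#' Add derived attribute columns to a variant table
#'
#' Computes residue-set attributes from the wild-type amino acid and
#' threshold attributes from the numeric annotation columns
#' (\code{disorder}, \code{cluster_size}, \code{length}) when present.
#'
#' @param table a \code{variant_table}.
#' @param residue_sets character vector of residue-set attributes to add
#'   (default: sulfur_binding only, the set used for calibration).
#' @param ... passed to \code{\link{threshold_attributes}} (cutoffs).
#' @return the table with the new logical attribute columns appended.
#' @export
add_derived_attributes <- function(table,
                                   residue_sets = "sulfur_binding", ...) {
  attrs <- attribute_names(table)
  for (a in residue_sets) {
    set <- RESIDUE_SETS[[a]]
    if (is.null(set)) stop("unknown residue set: ", a)
    table[[a]] <- table$wt %in% set
    attrs <- union(attrs, a)
  }
  dots <- list(...)
  disorder_cutoff <- dots$disorder_cutoff %||% 0.7
  homology_cutoff <- dots$homology_cutoff %||% 10
  length_cutoff <- dots$length_cutoff %||% 1022
  if ("disorder" %in% names(table)) {
    table$disordered <- table$disorder > disorder_cutoff
    attrs <- union(attrs, "disordered")
  }
  if ("cluster_size" %in% names(table)) {
    if (any(table$cluster_size < 0, na.rm = TRUE)) {
      stop("cluster_size must be >= 0")
    }
    table$low_homology <- table$cluster_size <= homology_cutoff
    attrs <- union(attrs, "low_homology")
  }
  if ("length" %in% names(table)) {
    table$long_protein <- table$length > length_cutoff
    attrs <- union(attrs, "long_protein")
  }
  attr(table, "attributes") <- attrs
  table
}

#' Restrict a labeled table to well-annotated proteins
#'
#' Keeps only proteins with at least \code{min_total} labeled variants, of
#' which at least \code{min_pos} pathogenic and \code{min_neg} benign.  Record
#' order is preserved; the filter is idempotent.
#'
#' @param table a labeled \code{variant_table}.
#' @param min_total minimum labeled variants per protein (default 10).
#' @param min_pos minimum pathogenic variants (default 4).
#' @param min_neg minimum benign variants (default 4).
#' @return the filtered \code{variant_table}.
#' @export
filter_well_annotated <- function(table, min_total = 10, min_pos = 4,
                                  min_neg = 4) {
  if (nrow(table) == 0) return(table)
  if (!("label" %in% names(table))) stop("table carries no labels")
  lab <- table$label
  pid <- table$protein_id
  tot <- tapply(!is.na(lab), pid, sum)
  pos <- tapply(lab == 1L, pid, sum, na.rm = TRUE)
  neg <- tapply(lab == 0L, pid, sum, na.rm = TRUE)
  ok <- names(tot)[tot >= min_total & pos >= min_pos & neg >= min_neg]
  out <- table[pid %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attributes") <- attribute_names(table)
  class(out) <- class(table)
  out
}
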