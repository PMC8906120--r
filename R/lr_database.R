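#' Construct a ligand-receptor database
#'
#' An `lr_database` is a data.frame of ligand->receptor signaling mechanisms,
#' one row per pair, with columns `mechanism_id` (the unique `ligand|receptor`
#' key), `ligand`, `receptor`, `family` (a single signaling-family designation
#' per mechanism; `"unassigned"` when unknown) and `mode` (e.g. secreted /
#' contact; `NA` when unknown). Duplicate ligand+receptor rows are collapsed,
#' keeping first occurrence order. A gene may appear as a ligand in one pair
#' and a receptor in another; one ligand may hit multiple receptors and
#' vice-versa.
#'
#' @param ligand,receptor character vectors of gene symbols (recycled to equal
#'   length not allowed; must match).
#' @param family optional character vector of family labels; missing or empty
#'   entries become `"unassigned"`.
#' @param mode optional character vector of mode labels.
#' @return an object of class `lr_database` (a data.frame).
#' @export
lr_database <- function(ligand, receptor, family = NULL, mode = NULL) {
  ligand <- as.character(ligand); receptor <- as.character(receptor)
  if (length(ligand) != length(receptor))
    stop("ligand and receptor must have the same length")
  if (length(ligand) == 0L)
    stop("empty ligand-receptor database: no valid rows")
  bad <- !nzchar(ligand) | !nzchar(receptor) | is.na(ligand) | is.na(receptor)
  if (any(bad)) {
    ligand <- ligand[!bad]; receptor <- receptor[!bad]
    if (!is.null(family)) family <- family[!bad]
    if (!is.null(mode)) mode <- mode[!bad]
    if (length(ligand) == 0L) stop("empty ligand-receptor database: no valid rows")
  }
  family <- if (is.null(family)) rep("unassigned", length(ligand)) else as.character(family)
  family[is.na(family) | !nzchar(family)] <- "unassigned"
  mode <- if (is.null(mode)) rep(NA_character_, length(ligand)) else as.character(mode)
  db <- data.frame(
    mechanism_id = paste(ligand, receptor, sep = "|"),
    ligand = ligand, receptor = receptor, family = family, mode = mode,
    stringsAsFactors = FALSE
  )
  db <- db[!duplicated(db$mechanism_id), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("lr_database", "data.frame")
  db
}

#' Load a ligand-receptor reference table from CSV/TSV
#'
#' Reads a delimited file with a header (delimiter auto-detected) and builds an
#' [lr_database] from the named columns. Duplicated ligand+receptor rows are
#' collapsed to the first occurrence.
#'
#' @param path path to a CSV or TSV file, UTF-8, with a header row.
#' @param ligand_column,receptor_column names of the ligand and receptor
#'   gene-symbol columns.
#' @param family_column,mode_column optional column names for the signaling
#'   family and mode annotations.
#' @param case_fold if `TRUE`, gene symbols are upper-cased on load so that
#'   human (upper-case) and mouse (title-case) symbol conventions can be
#'   matched; default `FALSE` (exact, case-sensitive symbols).
#' @return an [lr_database].
#' @export
load_lr_database <- function(path, ligand_column = "ligand",
                             receptor_column = "receptor",
                             family_column = NULL, mode_column = NULL,
                             case_fold = FALSE) {
  if (!file.exists(path)) stop("ligand-receptor table not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE, encoding = "UTF-8")
  need <- c(ligand_column, receptor_column, family_column, mode_column)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("ligand-receptor table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lig <- as.character(tab[[ligand_column]])
  rec <- as.character(tab[[receptor_column]])
  if (case_fold) { lig <- toupper(lig); rec <- toupper(rec) }
  fam <- if (!is.null(family_column)) tab[[family_column]] else NULL
  mod <- if (!is.null(mode_column)) tab[[mode_column]] else NULL
  lr_database(lig, rec, family = fam, mode = mod)
}

#' Write a ligand-receptor database as canonical CSV
#'
#' Columns, in order: mechanism_id, ligand, receptor, family, mode.
#' @param db an [lr_database].
#' @param path output file path.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  write_csv_atomic(as.data.frame(db)[, c("mechanism_id", "ligand", "receptor",
                                         "family", "mode")], path)
}

#' Subset a database to given signaling families
#'
#' Unknown family names yield empty subsets rather than errors, so a request
#' can safely mix present and absent families.
#' @param db an [lr_database].
#' @param families character vector of family labels to keep.
#' @return an [lr_database] (possibly with zero rows).
#' @export
subset_by_family <- function(db, families) {
  stopifnot(inherits(db, "lr_database"), length(families) > 0)
  out <- db[db$family %in% families, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(db)
  out
}

#' Restrict a database to mechanisms whose genes were measured
#'
#' Keeps only pairs with both ligand and receptor among `measured_genes`.
#' Dropped pairs are reported with a message; a fully disjoint gene set yields
#' an empty database with a warning.
#' @param db an [lr_database].
#' @param measured_genes character vector of gene symbols present in the data.
#' @return an [lr_database].
#' @export
restrict_to_genes <- function(db, measured_genes) {
  stopifnot(inherits(db, "lr_database"), length(measured_genes) > 0)
  keep <- db$ligand %in% measured_genes & db$receptor %in% measured_genes
  if (any(!keep))
    message("restrict_to_genes: dropped ", sum(!keep), " pair(s) with unmeasured genes: ",
            paste(utils::head(db$mechanism_id[!keep], 10), collapse = ", "),
            if (sum(!keep) > 10) ", ..." else "")
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(db)
  if (nrow(out) == 0L)
    warning("no ligand-receptor pair has both genes measured; database is empty")
  out
}

#' @export
print.lr_database <- function(x, ...) {
  cat("lr_database:", nrow(x), "mechanism(s),",
      length(unique(x$ligand)), "ligand(s),",
      length(unique(x$receptor)), "receptor(s),",
      length(unique(x$family)), "family label(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' Bundled example ligand-receptor table
#'
#' Loads the small ligand-receptor table shipped with the package (a few dozen
#' well-known secreted and contact-dependent pairs with illustrative family
#' labels), intended for tests and demos. For real analyses supply a full
#' curated reference via [load_lr_database].
#' @return an [lr_database].
#' @export
example_lr_database <- function() {
  load_lr_database(system.file("extdata", "lr_pairs_example.csv", package = "lrnet"),
                   ligand_column = "ligand", receptor_column = "receptor",
                   family_column = "family", mode_column = "mode")
}
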