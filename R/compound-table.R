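#' Compound-abundance tables
#'
#' A `compound_table` holds a samples x compounds matrix of percent relative
#' abundances (each row of a normalized table sums to 100) together with
#' optional per-compound annotations (name, PubChem ChemID, molecular class,
#' spectral match score). Rows are individual secretion samples; columns are
#' identified molecules. Compound identity is carried by the `compound_id`
#' column token; the ChemID is annotation only, since distinct compounds can
#' share names across molecular classes.
#'
#' @param abundances numeric matrix, rows = samples, columns = compounds.
#'   Must have unique non-empty rownames (sample ids) and colnames
#'   (compound ids) and no negative values.
#' @param annotations optional data.frame with columns `compound_id` and any
#'   of `name`, `chem_id`, `mol_class`, `match_score` (percent in \[0, 100\]).
#'   Row order is matched to the matrix columns.
#' @return An object of class `compound_table`: a list with elements
#'   `abundances` and `annotations`.
#' @export
compound_table <- function(abundances, annotations = NULL) {
  if (!is.matrix(abundances) || !is.numeric(abundances))
    stop("`abundances` must be a numeric matrix")
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("`abundances` must have sample rownames and compound colnames")
  dup <- unique(rownames(abundances)[duplicated(rownames(abundances))])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(abundances)[duplicated(colnames(abundances))])
  if (length(dup))
    stop("duplicate compound ids: ", paste(dup, collapse = ", "))
  neg <- which(abundances < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative abundance at sample '%s', compound '%s'",
                 rownames(abundances)[neg[1, 1]],
                 colnames(abundances)[neg[1, 2]]))
  if (is.null(annotations)) {
    annotations <- data.frame(compound_id = colnames(abundances),
                              name = colnames(abundances),
                              chem_id = NA_character_,
                              mol_class = NA_character_,
                              match_score = NA_real_,
                              stringsAsFactors = FALSE)
  } else {
    if (!"compound_id" %in% names(annotations))
      stop("annotations must have a compound_id column")
    if (anyDuplicated(annotations$compound_id))
      stop("duplicate compound_id in annotations")
    missing_ann <- setdiff(colnames(abundances), annotations$compound_id)
    if (length(missing_ann))
      stop("compounds missing from annotations: ",
           paste(missing_ann, collapse = ", "))
    annotations <- annotations[match(colnames(abundances),
                                     annotations$compound_id), , drop = FALSE]
    rownames(annotations) <- NULL
    for (col in c("name", "chem_id", "mol_class"))
      if (!col %in% names(annotations)) annotations[[col]] <- NA_character_
    if (!"match_score" %in% names(annotations))
      annotations$match_score <- NA_real_
    ms <- annotations$match_score
    if (any(!is.na(ms) & (ms < 0 | ms > 100)))
      stop("match_score outside [0, 100]")
  }
  structure(list(abundances = abundances, annotations = annotations),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d samples x %d compounds\n",
              nrow(x$abundances), ncol(x$abundances)))
  rs <- rowSums(x$abundances)
  cat(sprintf("  row sums: [%g, %g]; %d annotated classes\n",
              min(rs), max(rs),
              length(unique(stats::na.omit(x$annotations$mol_class)))))
  invisible(x)
}

#' @export
dim.compound_table <- function(x) dim(x$abundances)

#' Sample ids of a compound table
#' @param x a `compound_table`
#' @return character vector of sample ids in table order.
#' @export
sample_ids <- function(x) rownames(x$abundances)

#' Compound ids of a compound table
#' @param x a `compound_table`
#' @return character vector of compound ids in column order.
#' @export
compound_ids <- function(x) colnames(x$abundances)

guess_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a compound-abundance matrix (and optional annotations) from disk
#'
#' The matrix file is CSV or TSV (by extension), UTF-8, with a header row of
#' compound ids and a first column of sample ids. Empty cells are read as 0
#' (absence of the compound in that profile) with a warning giving the count.
#'
#' @param matrix_path path to the abundance matrix (.csv or .tsv).
#' @param annotation_path optional path to a CSV with columns
#'   `compound_id, name, chem_id, mol_class, match_score`.
#' @return a validated [compound_table()].
#' @export
read_compound_table <- function(matrix_path, annotation_path = NULL) {
  header <- strsplit(readLines(matrix_path, n = 1),
                     guess_delim(matrix_path), fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("duplicate compound ids in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  raw <- utils::read.table(matrix_path, sep = guess_delim(matrix_path),
                           header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(raw) < 2) stop("matrix file needs a sample-id column plus compounds")
  sample_id <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  n_missing <- sum(is.na(cells) | trimws(cells) == "")
  if (n_missing > 0) {
    warning(sprintf("%d missing cells read as 0", n_missing))
    cells[is.na(cells) | trimws(cells) == ""] <- "0"
  }
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at sample '%s', compound '%s'",
                 sample_id[bad[1]], colnames(cells)[bad[2]]))
  }
  dimnames(vals) <- list(sample_id, colnames(cells))
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE,
                           colClasses = c(chem_id = "character"))
  }
  compound_table(vals, ann)
}

#' Write a compound table to disk
#'
#' Values are printed at full precision (`format(..., digits = 17)`) so that
#' read -> write -> read round-trips exactly.
#'
#' @param x a `compound_table`
#' @param matrix_path output path (.csv or .tsv decides the delimiter).
#' @param annotation_path optional output path for the annotation CSV.
#' @return `x`, invisibly.
#' @export
write_compound_table <- function(x, matrix_path, annotation_path = NULL) {
  cells <- apply(x$abundances, c(1, 2), function(v) sprintf("%.17g", v))
  df <- data.frame(sample_id = rownames(x$abundances),
                   cells, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = guess_delim(matrix_path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(annotation_path))
    utils::write.csv(x$annotations, annotation_path, row.names = FALSE)
  invisible(x)
}

#' Rescale every sample profile to percent (row sum 100)
#'
#' Idempotent; annotations and column order are untouched.
#'
#' @param x a `compound_table`
#' @return a `compound_table` whose rows each sum to 100.
#' @export
normalize_rows <- function(x) {
  rs <- rowSums(x$abundances)
  if (any(rs <= 0)) {
    bad <- rownames(x$abundances)[rs <= 0]
    stop("all-zero abundance row for sample(s): ", paste(bad, collapse = ", "))
  }
  out <- x
  out$abundances <- x$abundances / rs * 100
  out
}

#' Drop compounds whose spectral match score falls below a threshold
#'
#' Mirrors the retention rule applied upstream of the study's statistics:
#' only molecules identified with a library similarity index above the
#' threshold are kept. Compounds without a score are retained. Surviving
#' rows are re-normalized to percent.
#'
#' @param x a `compound_table`
#' @param threshold percent in \[0, 100\]; compounds with
#'   `match_score < threshold` are dropped.
#' @return a filtered, re-normalized `compound_table`.
#' @export
filter_by_match_score <- function(x, threshold = 85) {
  stopifnot(threshold >= 0, threshold <= 100)
  ms <- x$annotations$match_score
  keep <- is.na(ms) | ms >= threshold
  if (!any(keep)) stop("no compounds retained at threshold ", threshold)
  if (any(!keep))
    message("dropped compounds below match threshold: ",
            paste(x$annotations$compound_id[!keep], collapse = ", "))
  out <- compound_table(x$abundances[, keep, drop = FALSE],
                        x$annotations[keep, , drop = FALSE])
  normalize_rows(out)
}

#' Subset samples by a predicate on the metadata
#'
#' The predicate is evaluated in the metadata columns (like [base::subset()]).
#' Matched samples keep their original order. Compound columns that become
#' all-zero in the subset are retained so that compound indices stay aligned
#' across subsets (e.g. per-season SIMPER runs on the same column universe).
#'
#' @param x a `compound_table`
#' @param metadata data.frame with a `sample_id` column matching `x` plus
#'   factor columns (`species`, `sex`, `year`, `season`).
#' @param predicate an unquoted expression on metadata columns, e.g.
#'   `year %in% c(2012, 2014)`, or a logical vector of length `nrow(metadata)`.
#' @return list with elements `table` (compound_table) and `metadata`.
#' @export
subset_samples <- function(x, metadata, predicate) {
  metadata <- check_metadata(metadata, x)
  keep <- eval(substitute(predicate), metadata, parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(metadata))
    stop("predicate must yield one logical per sample")
  keep <- !is.na(keep) & keep
  if (!any(keep)) stop("predicate matched no samples")
  tab <- compound_table(x$abundances[keep, , drop = FALSE], x$annotations)
  list(table = tab, metadata = metadata[keep, , drop = FALSE])
}

#' Read a sample metadata CSV
#'
#' Expected columns: `sample_id, species, sex, year, season` with
#' `species` in {marthae, subcristatus}, `sex` in {F, M}, `season` in
#' {rs, nrs} (reproductive / non-reproductive).
#'
#' @param path CSV path.
#' @param table optional `compound_table` to check sample alignment against.
#' @return data.frame of per-sample factors.
#' @export
read_sample_metadata <- function(path, table = NULL) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_metadata(md, table)
}

check_metadata <- function(metadata, table = NULL) {
  req <- c("sample_id", "species", "sex", "year", "season")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$species), c("marthae", "subcristatus"))
  if (length(bad)) stop("unknown species level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$sex), c("F", "M"))
  if (length(bad)) stop("unknown sex level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$season), c("rs", "nrs"))
  if (length(bad)) stop("unknown season level(s): ", paste(bad, collapse = ", "))
  metadata$year <- as.integer(metadata$year)
  if (!is.null(table)) {
    if (!identical(sort(metadata$sample_id), sort(sample_ids(table))))
      stop("metadata sample ids do not match the compound table")
    metadata <- metadata[match(sample_ids(table), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}
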