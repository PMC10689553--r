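## read a delimited or Excel table into a data.frame of character columns
.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      check.names = FALSE, colClasses = "character",
                      comment.char = "", fileEncoding = "UTF-8")
  }
}

## coerce character cells to numeric; "", "NA", "NaN" become missing,
## "<LOQ" is resolved through the LOQ map or raises an error
.numericCells <- function(v, loq, column) {
  v <- trimws(v)
  below <- grepl("^<\\s*LOQ$", v, ignore.case = TRUE)
  if (any(below)) {
    if (is.na(loq))
      stop("column '", column, "' contains '<LOQ' cells but no LOQ is ",
           "known; supply one via the LOQ map")
    v[below] <- as.character(loq)
  }
  v[v %in% c("", "NA", "NaN", "na", "nan")] <- NA
  suppressWarnings(out <- as.numeric(v))
  bad <- sum(!is.na(v) & is.na(out))
  list(values = out, nNonNumeric = bad)
}

#' Read an abundance table
#'
#' Reads a CSV/TSV/XLSX abundance table into the canonical
#' samples-by-metabolites matrix.  The first column holds the row
#' identifiers (sample IDs, or metabolite names when
#' \code{orientation = "metabolites_in_rows"}, the MetaboLights deposition
#' layout, in which case the table is transposed).  Non-numeric cells
#' become missing values with a reported count; \code{"<LOQ"} cells are
#' replaced by the metabolite's limit of quantification from \code{loqMap}
#' (an error without one).
#'
#' @param path file path (.csv, .tsv, .txt or .xlsx).
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"metabolites_in_rows"}.
#' @param loqMap optional named numeric vector of limits of quantification,
#'   see [readLoqMap()].
#' @return numeric matrix, samples in rows, metabolites in columns, both
#'   dimensions named.
#' @export
readAbundance <- function(path,
                          orientation = c("samples_in_rows",
                                          "metabolites_in_rows"),
                          loqMap = NULL) {
  orientation <- match.arg(orientation)
  df <- .readTable(path)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty abundance table: ", path)
  ids <- as.character(df[[1L]])
  vars <- colnames(df)[-1L]
  if (anyDuplicated(vars))
    stop("duplicated column names in ", path, ": ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicated row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  metNames <- if (orientation == "metabolites_in_rows") ids else vars
  if (anyDuplicated(metNames))
    stop("duplicated metabolite names: ",
         paste(unique(metNames[duplicated(metNames)]), collapse = ", "))
  nbad <- 0L
  cols <- lapply(seq_along(vars), function(j) {
    met <- if (orientation == "samples_in_rows") vars[j] else NA
    lq <- if (!is.null(loqMap) && !is.na(met) && met %in% names(loqMap))
      loqMap[[met]] else NA_real_
    r <- .numericCells(df[[j + 1L]], lq, vars[j])
    nbad <<- nbad + r$nNonNumeric
    r$values
  })
  m <- do.call(cbind, cols)
  rownames(m) <- ids; colnames(m) <- vars
  if (orientation == "metabolites_in_rows") {
    m <- t(m)
    ## LOQ substitution for "<LOQ" cells happens per metabolite row there
    if (!is.null(loqMap)) {
      ## re-read metabolite-wise so the map applies to rows
      raw <- df[, -1L, drop = FALSE]
      for (i in seq_len(nrow(df))) {
        met <- ids[i]
        if (met %in% names(loqMap)) {
          r <- .numericCells(as.character(unlist(raw[i, ])),
                             loqMap[[met]], met)
          m[, met] <- r$values
        }
      }
    }
  }
  if (nbad > 0L)
    message(nbad, " non-numeric cell(s) in ", basename(path),
            " set to missing")
  m
}

#' Write an abundance matrix in the canonical CSV dialect
#'
#' UTF-8, comma-separated, decimal point, sample IDs in a leading
#' \code{sample} column, missing values as empty cells.  A table written by
#' this function and read back with [readAbundance()] round-trips exactly.
#'
#' @param m samples-by-metabolites numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundance <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod =
                     "double", na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' @param path file path (.csv, .tsv, .txt or .xlsx); the first column
#'   holds the sample IDs.
#' @param exposure name of the variable-of-interest column (checked,
#'   numeric-coerced, summarized in a message).
#' @param covariates further required columns (e.g. \code{"bmi"}),
#'   numeric-coerced.
#' @return data.frame with sample IDs as row names.
#' @export
readMetadata <- function(path, exposure, covariates = character()) {
  df <- .readTable(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty metadata table: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated sample IDs in ", path)
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  need <- c(exposure, covariates)
  missCols <- setdiff(need, colnames(out))
  if (length(missCols))
    stop("metadata lacks column(s) ", paste(missCols, collapse = ", "),
         "; available: ", paste(colnames(out), collapse = ", "))
  for (cc in need) {
    r <- .numericCells(as.character(out[[cc]]), NA_real_, cc)
    out[[cc]] <- r$values
  }
  x <- out[[exposure]]
  message("metadata: ", nrow(out), " samples; ", exposure, " range [",
          format(min(x, na.rm = TRUE)), ", ", format(max(x, na.rm = TRUE)),
          "]")
  out
}

#' Parse a limit-of-quantification map
#'
#' Accepts either an inline specification like \code{"GUDCA=25,C12:0=3"}
#' or the path of a two-column CSV/TSV file (metabolite, loq).
#'
#' @param x character(1).
#' @return named numeric vector.
#' @examples
#' readLoqMap("GUDCA=25")
#' @export
readLoqMap <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x)) {
    df <- .readTable(x)
    if (ncol(df) < 2L) stop("LOQ map file needs two columns")
    vals <- suppressWarnings(as.numeric(df[[2L]]))
    if (anyNA(vals)) stop("non-numeric LOQ values in ", x)
    return(stats::setNames(vals, as.character(df[[1L]])))
  }
  parts <- strsplit(strsplit(x, ",")[[1L]], "=", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("cannot parse LOQ map '", x, "'; expected 'name=value,...' or a file")
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric LOQ values in '", x, "'")
  stats::setNames(vals, trimws(vapply(parts, `[`, "", 1L)))
}

#' Read a MetaboLights metabolite-assignment table
#'
#' MetaboLights deposits metabolite-assignment files (\code{m_*.tsv}) with
#' one metabolite per row: an identification column plus one intensity
#' column per sample, mixed with annotation columns.  This reader selects
#' the identification column, keeps the sample-intensity columns (all
#' mostly-numeric columns by default, or those matching
#' \code{samplePattern}) and returns the canonical samples-by-metabolites
#' matrix.
#'
#' @param path path to the \code{m_*.tsv} file.
#' @param idColumn name of the metabolite-identification column (default
#'   \code{"metabolite_identification"}).
#' @param samplePattern optional regular expression selecting the sample
#'   intensity columns by name; by default every column in which at least
#'   90 percent of non-empty cells parse as numbers is taken as a sample.
#' @return numeric matrix, samples in rows, metabolites in columns.
#' @export
readMetaboLights <- function(path, idColumn = "metabolite_identification",
                             samplePattern = NULL) {
  df <- .readTable(path)
  if (!idColumn %in% colnames(df))
    stop("column '", idColumn, "' not found; available: ",
         paste(utils::head(colnames(df), 10L), collapse = ", "), ", ...")
  mets <- make.unique(as.character(df[[idColumn]]))
  ## standard ISA-Tab annotation fields of m_*.tsv files, never samples
  annot <- c("database_identifier", "chemical_formula", "smiles", "inchi",
             "metabolite_identification", "mass_to_charge",
             "fragmentation", "modifications", "charge", "retention_time",
             "taxid", "species", "database", "database_version",
             "reliability", "uri", "search_engine", "search_engine_score",
             "smallmolecule_abundance_sub",
             "smallmolecule_abundance_stdev_sub",
             "smallmolecule_abundance_std_error_sub")
  if (is.null(samplePattern)) {
    isSample <- vapply(colnames(df), function(cc) {
      if (cc == idColumn || tolower(cc) %in% annot) return(FALSE)
      v <- trimws(as.character(df[[cc]]))
      v <- v[!(v %in% c("", "NA"))]
      length(v) > 0 &&
        mean(!is.na(suppressWarnings(as.numeric(v)))) >= 0.9
    }, TRUE)
    sampleCols <- colnames(df)[isSample]
  } else {
    sampleCols <- grep(samplePattern, colnames(df), value = TRUE)
  }
  if (!length(sampleCols))
    stop("no sample intensity columns identified in ", path)
  m <- vapply(sampleCols, function(cc)
    .numericCells(as.character(df[[cc]]), NA_real_, cc)$values,
    numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(mets, sampleCols))
  t(m)
}
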