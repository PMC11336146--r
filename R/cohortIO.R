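## Reading, writing and summarising the cohort's tabular artifacts.

#' Read a gene-expression matrix
#'
#' Reads a TSV or CSV matrix (gzip transparently supported) with one header
#' row of ids and one leading id column, and returns it in the package's
#' canonical orientation: genes in rows, samples in columns. Files laid out
#' samples-in-rows are transposed on read via \code{orientation}.
#'
#' Values must parse as finite nonnegative reals; duplicated row or column
#' ids, non-numeric cells and negative values are rejected with the
#' offending id or cell location named.
#'
#' @param path file path (.tsv/.csv, optionally .gz).
#' @param orientation layout of the file: \code{"samples_by_genes"}
#'   (samples in rows; the canonical on-disk layout) or
#'   \code{"genes_by_samples"}.
#' @param sep field separator; guessed from the extension when \code{NULL}.
#' @return numeric matrix, genes x samples.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tMKI67\tCDKN1A", "s1\t100\t200", "s2\t150\t250",
#'              "s3\t120\t180"), tf)
#' readExpression(tf)
#' @export
readExpression <- function(path,
                           orientation = c("samples_by_genes", "genes_by_samples"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", row.names = NULL)
  if (ncol(df) < 2L) stopf("expression file needs an id column plus data columns")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids))
    stopf("duplicated row id(s): %s",
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    stopf("duplicated column id(s): %s",
          paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric cell at row '%s', column '%s': '%s'",
          row_ids[bad[1, 1]], col_ids[bad[1, 2]], raw[bad[1, 1], bad[1, 2]])
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stopf("missing value at row '%s', column '%s'",
          row_ids[bad[1, 1]], col_ids[bad[1, 2]])
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative intensity at row '%s', column '%s': %g",
          row_ids[neg[1, 1]], col_ids[neg[1, 2]], vals[neg[1, 1], neg[1, 2]])
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_by_genes") vals <- t(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: writes genes x samples data in the
#' requested on-disk orientation. Values round-trip bit-identically for
#' decimal representations of up to 15 significant digits.
#'
#' @param exprs genes x samples numeric matrix.
#' @param path output path.
#' @param orientation on-disk layout (see [readExpression()]).
#' @export
writeExpression <- function(exprs, path,
                            orientation = c("samples_by_genes", "genes_by_samples")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "samples_by_genes") t(exprs) else exprs
  id_col <- if (orientation == "samples_by_genes") "sample_id" else "gene_id"
  df <- data.frame(rownames(m), format(m, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default vocabulary for clinical categorical covariates
#'
#' The declared levels for each optional covariate; any non-missing value
#' outside its vocabulary is a read error (fail loudly on vocabulary
#' drift). Missing tokens are the empty string, \code{"NA"} and
#' \code{"NaN"}, case-insensitively.
#'
#' @return named list of character vectors.
#' @export
clinicalVocabulary <- function() {
  list(sex      = c("female", "male"),
       t_stage  = c("1", "2", "3", "4"),
       n_stage  = c("0", "1", "2", "3"),
       m_stage  = c("0", "1"),
       stage    = c("1", "2", "3", "4"),
       grade    = c("1", "2", "3"),
       location = c("proximal", "distal"),
       msi      = c("stable", "stable_or_low", "high"))
}

#' Read a clinical table
#'
#' Reads a TSV with mandatory columns \code{sample_id}, \code{time}
#' (relapse-free survival in months, strictly positive) and \code{event}
#' (0/1), an optional \code{dataset_id} (defaulting to a single dataset),
#' and any of the vocabulary-controlled covariate columns. Missing
#' covariate cells are kept as \code{NA} — they are never imputed, matching
#' cohorts in which not every patient has every clinical parameter.
#'
#' @param path TSV path (gzip accepted).
#' @param vocabulary named list of allowed levels per covariate column,
#'   as from [clinicalVocabulary()].
#' @return data.frame with parsed columns; covariates as character with
#'   \code{NA} for missing.
#' @export
readClinical <- function(path, vocabulary = clinicalVocabulary()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  for (col in c("sample_id", "time", "event"))
    if (!col %in% colnames(df)) stopf("clinical table lacks column '%s'", col)
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  time <- suppressWarnings(as.numeric(df$time))
  if (anyNA(time) || any(!is.finite(time)))
    stopf("non-numeric survival time for sample '%s'",
          df$sample_id[which(is.na(time))[1]])
  if (any(time <= 0))
    stopf("non-positive survival time for sample '%s'",
          df$sample_id[which(time <= 0)[1]])
  event <- suppressWarnings(as.numeric(df$event))
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stopf("event indicator must be 0 or 1 (sample '%s')",
          df$sample_id[which(is.na(event) | !event %in% c(0, 1))[1]])
  out <- data.frame(sample_id = df$sample_id, time = time, event = event,
                    dataset_id = if ("dataset_id" %in% colnames(df))
                      df$dataset_id else "dataset1",
                    stringsAsFactors = FALSE)
  for (col in intersect(names(vocabulary), colnames(df))) {
    v <- df[[col]]
    v[isMissingToken(v)] <- NA_character_
    bad <- !is.na(v) & !v %in% vocabulary[[col]]
    if (any(bad))
      stopf("unknown level '%s' in column '%s' (sample '%s'); allowed: %s",
            v[which(bad)[1]], col, df$sample_id[which(bad)[1]],
            paste(vocabulary[[col]], collapse = ", "))
    out[[col]] <- v
  }
  out
}

#' Write a clinical table as TSV
#' @param clin data.frame as returned by [readClinical()].
#' @param path output path.
#' @export
writeClinical <- function(clin, path) {
  df <- clin
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 15, trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Clinical characteristics summary
#'
#' Tabulates each categorical covariate as count and percentage of
#' non-missing records, the layout of a clinical-characteristics table in
#' a cohort report. Percentages are computed over non-missing records
#' only and rounded half-away-from-zero to 2 decimals; within a feature
#' they sum to 100 up to rounding slack.
#'
#' @param clin data.frame with covariate columns (missing as \code{NA});
#'   at least one record.
#' @param features which columns to summarise; defaults to the covariate
#'   columns present.
#' @return data.frame with columns \code{feature}, \code{level},
#'   \code{count}, \code{percent}.
#' @examples
#' clin <- data.frame(sex = c(rep("male", 492), rep("female", 435)))
#' clinicalSummary(clin, "sex")
#' @export
clinicalSummary <- function(clin, features = NULL) {
  if (nrow(clin) < 1L) stopf("clinical table is empty")
  if (is.null(features))
    features <- intersect(names(clinicalVocabulary()), colnames(clin))
  out <- list()
  for (f in features) {
    v <- clin[[f]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    vocab <- clinicalVocabulary()[[f]]
    lev <- if (!is.null(vocab)) intersect(vocab, unique(v)) else
      sort(unique(v))
    cnt <- as.integer(table(factor(v, levels = lev)))
    out[[f]] <- data.frame(feature = f, level = lev, count = cnt,
                           percent = roundHalfAway(100 * cnt / sum(cnt), 2L),
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(feature = character(), level = character(),
                      count = integer(), percent = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a signature gene list
#'
#' Reads a gene list with optional probe ids and optional fixed weights
#' from TSV or XLSX (first sheet). Recognized columns (case-insensitive):
#' \code{gene} (or \code{gene_id}), \code{probe} (or \code{probe_id},
#' \code{probe_set}) and \code{weight}.
#'
#' @param path TSV or XLSX path.
#' @return data.frame with columns \code{gene_id}, \code{probe_id},
#'   \code{fixed_weight} (\code{NA} where absent).
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = 1L,
                                           col_types = "text"))
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                     colClasses = "character")
  }
  nm <- tolower(colnames(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) NULL else df[[i]]
  }
  gene <- pick(c("gene", "gene_id", "gene_symbol", "symbol"))
  if (is.null(gene)) stopf("gene list lacks a gene column")
  probe <- pick(c("probe", "probe_id", "probe_set", "probeset", "affy_id"))
  weight <- pick(c("weight", "fixed_weight"))
  if (anyDuplicated(gene))
    stopf("duplicated gene id(s) in gene list: %s",
          paste(unique(gene[duplicated(gene)]), collapse = ", "))
  w <- if (is.null(weight)) rep(NA_real_, length(gene)) else
    suppressWarnings(as.numeric(weight))
  if (!is.null(weight) && any(!is.na(w) & !w %in% c(-1, 1)))
    stopf("fixed weights must be -1 or +1 (gene '%s')",
          gene[which(!is.na(w) & !w %in% c(-1, 1))[1]])
  data.frame(gene_id = gene,
             probe_id = if (is.null(probe)) NA_character_ else probe,
             fixed_weight = w, stringsAsFactors = FALSE)
}
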