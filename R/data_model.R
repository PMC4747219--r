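## Core domain containers and I/O.
##
## An expression matrix is a plain numeric matrix (features x samples, log2
## scale) with rownames = feature ids and colnames = sample ids.  Clinical
## tables, gene-pair annotations and genomic intervals are plain data frames;
## genomic coordinates are 0-based half-open (BED convention) throughout.

GRADES   <- c("G1", "G2", "G3", "unknown")
SUBTYPES <- c("basal", "non_basal", "normal_tissue", "unknown")

validate_expression <- function(values, what = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop(what, " must carry feature and sample ids as dimnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 3L)
    stop(what, " needs at least 2 features and 3 samples", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at feature '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'", call. = FALSE)
  }
  invisible(values)
}

#' Read a tab-delimited expression matrix
#'
#' The first column holds feature ids; the header row holds sample ids.
#' Values are log2-scale intensities.  Missing or non-numeric cells are
#' rejected (matrices are expected complete after upstream preprocessing),
#' with the offending feature/sample named in the error.
#'
#' @param path Path to a tab-delimited file.
#' @return A numeric matrix (features x samples) with id dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stop("expression file needs id column plus samples", call. = FALSE)
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at feature '", ids[bad[1L]],
         "', sample '", samples[bad[2L]], "'", call. = FALSE)
  }
  dimnames(vals) <- list(ids, samples)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: `feature_id` column plus one column per
#' sample.
#'
#' @param expr Numeric matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(feature_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `dfs_years` (disease-free survival, years)
#' and `event` (1 = recurrence/event, 0 = censored).  Optional columns
#' `grade` (G1/G2/G3), `subtype` (basal/non_basal/normal_tissue) and
#' `cohort` default to `"unknown"` when absent.
#'
#' @param path Path to a tab-delimited file.
#' @return A data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  as_clinical(df)
}

#' Coerce a data frame to a validated clinical table
#'
#' @param df Data frame with at least `sample_id`, `dfs_years`, `event`.
#' @return Validated clinical data frame with all optional columns filled.
#' @export
as_clinical <- function(df) {
  need <- c("sample_id", "dfs_years", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    dfs_years = as.numeric(df$dfs_years),
    event     = as.numeric(df$event),
    grade     = if ("grade" %in% names(df)) as.character(df$grade) else "unknown",
    subtype   = if ("subtype" %in% names(df)) as.character(df$subtype) else "unknown",
    cohort    = if ("cohort" %in% names(df)) as.character(df$cohort) else "unknown",
    stringsAsFactors = FALSE
  )
  if (anyNA(out$dfs_years) || any(out$dfs_years < 0))
    stop("dfs_years must be non-negative", call. = FALSE)
  if (!all(out$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  out$event <- as.integer(out$event)
  if (!all(out$grade %in% GRADES))
    stop("grade must be one of ", paste(GRADES, collapse = "/"), call. = FALSE)
  if (!all(out$subtype %in% SUBTYPES))
    stop("subtype must be one of ", paste(SUBTYPES, collapse = "/"), call. = FALSE)
  out
}

#' Read a gene-pair annotation table
#'
#' Tab-delimited with columns `pair_id`, `gene_a`, `gene_b`, `orientation`
#' (divergent/convergent/embedded), `chrom`, `startA`, `endA`, `strandA`,
#' `startB`, `endB`, `strandB`, `class_tag` (SAGP/NGN/PNG).  Coordinates are
#' 0-based half-open.
#'
#' @param path Path to a tab-delimited file.
#' @return A data frame of pair annotations.
#' @export
read_gene_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  as_gene_pairs(df)
}

#' Validate a gene-pair annotation data frame
#'
#' @param df Data frame of pair annotations (see [read_gene_pairs()]).
#' @return The validated data frame.
#' @export
as_gene_pairs <- function(df) {
  need <- c("pair_id", "gene_a", "gene_b", "orientation", "class_tag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene-pair table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$gene_a == df$gene_b))
    stop("gene_a and gene_b must differ within a pair", call. = FALSE)
  if (!all(df$orientation %in% c("divergent", "convergent", "embedded")))
    stop("orientation must be divergent/convergent/embedded", call. = FALSE)
  if (!all(df$class_tag %in% c("SAGP", "NGN", "PNG")))
    stop("class_tag must be SAGP/NGN/PNG", call. = FALSE)
  for (cc in intersect(c("startA", "endA", "startB", "endB"), names(df))) {
    df[[cc]] <- as.integer(df[[cc]])
    if (any(df[[cc]] < 0)) stop("coordinates must be non-negative", call. = FALSE)
  }
  if (all(c("startA", "endA") %in% names(df)) && any(df$startA >= df$endA))
    stop("interval start must be < end", call. = FALSE)
  if (all(c("startB", "endB") %in% names(df)) && any(df$startB >= df$endB))
    stop("interval start must be < end", call. = FALSE)
  df
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3-6 column BED (chrom, start, end, then optional name, score,
#' strand).  Coordinates stay 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns chrom, start, end and, when present,
#'   name and strand.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end   = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  if (ncol(df) >= 6L) out$strand <- as.character(df[[6L]])
  if (any(out$start >= out$end)) stop("interval start must be < end", call. = FALSE)
  if (any(out$start < 0)) stop("coordinates must be non-negative", call. = FALSE)
  out
}

#' Bundle an expression matrix with its clinical table
#'
#' @param expression Numeric expression matrix (features x samples).
#' @param clinical Clinical data frame (see [as_clinical()]); every
#'   `sample_id` must be a column of `expression`.
#' @param name Cohort identifier.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(expression, clinical, name) {
  validate_expression(expression)
  clinical <- as_clinical(clinical)
  missing_ids <- setdiff(clinical$sample_id, colnames(expression))
  if (length(missing_ids))
    stop("clinical samples absent from expression matrix: ",
         paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  structure(list(expression = expression, clinical = clinical,
                 name = as.character(name)),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", x$name, ": ", nrow(x$expression), " features x ",
      ncol(x$expression), " samples (", nrow(x$clinical),
      " with clinical records, ", sum(x$clinical$event), " events)\n", sep = "")
  invisible(x)
}

#' Standardize expression rows to zero mean and unit variance
#'
#' Each listed feature is z-scored across the matrix's samples using the
#' population standard deviation, so that rotation of a gene-pair plane
#' about the origin is meaningful.  Constant rows map to all zeros.
#' Standardization is per cohort by construction: it uses only the samples
#' present in `expr`.
#'
#' @param expr Numeric expression matrix.
#' @param feature_ids Features to standardize; default all rows.
#' @return The matrix with the listed rows standardized.
#' @export
standardize <- function(expr, feature_ids = rownames(expr)) {
  validate_expression(expr)
  missing_ids <- setdiff(feature_ids, rownames(expr))
  if (length(missing_ids))
    stop("features not in matrix: ", paste(head(missing_ids, 5L), collapse = ", "),
         call. = FALSE)
  for (f in feature_ids) {
    v <- expr[f, ]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    expr[f, ] <- if (sdv > 0) (v - mu) / sdv else 0
  }
  expr
}
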