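#' Read a species x sample abundance table
#'
#' Reads a tab-delimited abundance table into a numeric matrix with species as
#' rows and samples as columns, regardless of the orientation on disk. The
#' first header cell may be blank or an identifier label; the remaining header
#' entries and the first column hold sample and species identifiers (or vice
#' versa for `orientation = "sample_rows"`).
#'
#' @param path Path to a TSV file with an identifier header row and column.
#' @param orientation Either `"species_rows"` (default) if rows on disk are
#'   species, or `"sample_rows"` if rows are samples; the returned matrix
#'   always has species as rows.
#' @return A numeric matrix (species x samples) with identifier dimnames.
#' @seealso [preprocess_abundance()], [write_abundance()]
#' @export
read_abundance <- function(path, orientation = c("species_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("abundance table must have an identifier column plus at least one data column")
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & nzchar(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   body[[j]][bad[1L]], ids[bad[1L]], colnames(body)[j]))
    num[, j] <- v
  }
  A <- if (orientation == "sample_rows") t(num) else num
  validate_abundance(A)
  A
}

#' Write an abundance matrix as TSV
#'
#' @param A Species x sample numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(A, path) {
  validate_abundance(A)
  df <- data.frame(species_id = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_abundance <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop("abundance must be a numeric matrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("abundance matrix needs species rownames and sample colnames")
  dup_s <- unique(rownames(A)[duplicated(rownames(A))])
  if (length(dup_s))
    stop("duplicate species identifier(s): ", paste(dup_s, collapse = ", "))
  dup_p <- unique(colnames(A)[duplicated(colnames(A))])
  if (length(dup_p))
    stop("duplicate sample identifier(s): ", paste(dup_p, collapse = ", "))
  if (anyNA(A)) stop("abundance matrix contains missing values")
  if (any(A < 0)) stop("abundance values must be non-negative")
  invisible(A)
}

#' Filter rare species and renormalise to relative abundance
#'
#' Rows (species) whose fraction of non-zero entries across samples is below
#' `min_nonzero_frac` are removed, then every column is divided by its sum so
#' each sample's retained abundances sum to one. The default threshold 0.05%
#' only removes all-zero rows unless the study has thousands of samples; the
#' intended stringency is exposed as a parameter rather than hard-coded.
#'
#' @param A Species x sample numeric matrix.
#' @param min_nonzero_frac Minimum fraction of samples in which a species must
#'   be non-zero to be retained; default `5e-4` (0.05%).
#' @return The filtered, column-renormalised matrix; species order preserved.
#' @export
preprocess_abundance <- function(A, min_nonzero_frac = 5e-4) {
  validate_abundance(A)
  stopifnot(min_nonzero_frac >= 0, min_nonzero_frac <= 1)
  frac <- rowMeans(A > 0)
  keep <- frac >= min_nonzero_frac & frac > 0
  A <- A[keep, , drop = FALSE]
  cs <- colSums(A)
  if (any(cs == 0))
    stop("sample(s) with no retained species after filtering: ",
         paste(colnames(A)[cs == 0], collapse = ", "))
  sweep(A, 2L, cs, "/")
}

#' Read a sample label table
#'
#' @param path TSV with header columns `sample_id` and `label`.
#' @return Named character vector of labels, names = sample ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop("label table must have columns 'sample_id' and 'label'")
  stats::setNames(df$label, df$sample_id)
}

#' One-hot encode sample class labels
#'
#' Builds the binary label matrix used by the classifier. Class order is
#' lexicographic unless `classes` supplies an explicit order. When
#' `sample_ids` is given (normally the abundance matrix column order), labels
#' are aligned to it and unlabelled samples are an error.
#'
#' @param labels Named character vector (names = sample ids) or unnamed vector.
#' @param sample_ids Optional sample order to align to.
#' @param classes Optional explicit class order; must cover all labels.
#' @return An object of class `"sample_labels"`: list with `sample_ids`,
#'   `labels`, `classes`, and the N x C binary matrix `onehot`.
#' @export
encode_labels <- function(labels, sample_ids = NULL, classes = NULL) {
  if (is.null(names(labels)) && !is.null(sample_ids)) {
    if (length(labels) != length(sample_ids))
      stop("unnamed labels must match sample_ids in length")
    names(labels) <- sample_ids
  }
  if (is.null(names(labels)))
    names(labels) <- paste0("sample", seq_along(labels))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("unlabelled sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  }
  ids <- names(labels)
  labels <- stats::setNames(as.character(labels), ids)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes))
    stop("label(s) outside the supplied class set: ",
         paste(setdiff(labels, classes), collapse = ", "))
  n <- length(labels)
  onehot <- matrix(0L, n, length(classes),
                   dimnames = list(names(labels), classes))
  onehot[cbind(seq_len(n), match(labels, classes))] <- 1L
  structure(list(sample_ids = names(labels), labels = labels,
                 classes = classes, onehot = onehot),
            class = "sample_labels")
}

#' @export
print.sample_labels <- function(x, ...) {
  cat("Sample labels:", length(x$sample_ids), "samples,",
      length(x$classes), "classes\n")
  print(table(factor(x$labels, levels = x$classes)))
  invisible(x)
}
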