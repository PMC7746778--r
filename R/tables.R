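#' Construct an AbundanceTable
#'
#' Wraps a features-by-samples numeric matrix, with optional per-sample
#' case/control group labels and study IDs, into an [AbundanceTable-class].
#'
#' @param values numeric matrix with feature row names and sample column
#'   names; counts or intensities, finite and non-negative.
#' @param group optional character/factor of length `ncol(values)`:
#'   case/control labels.
#' @param study optional character of length `ncol(values)`: study IDs.
#' @return An [AbundanceTable-class].
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("ko:K", 1:3), paste0("s", 1:4)))
#' AbundanceTable(m, group = c("case", "case", "control", "control"))
#' @export
AbundanceTable <- function(values, group = NULL, study = NULL) {
  .new_table("AbundanceTable", values, group, study)
}

#' Construct a CMPMatrix
#'
#' Like [AbundanceTable()] but for signed community-metabolic-potential
#' scores (negative values permitted).
#'
#' @inheritParams AbundanceTable
#' @return A [CMPMatrix-class].
#' @export
CMPMatrix <- function(values, group = NULL, study = NULL) {
  .new_table("CMPMatrix", values, group, study)
}

.new_table <- function(class, values, group = NULL, study = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature row names and sample column names")
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(group)) {
    stopifnot(length(group) == ncol(values))
    cd$group <- as.character(group)
  }
  if (!is.null(study)) {
    stopifnot(length(study) == ncol(values))
    cd$study <- as.character(study)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
  new(class, se)
}

## carry an existing table's colData onto a new value matrix (shared samples)
.retable <- function(class, values, template) {
  g <- sampleGroups(template); s <- sampleStudies(template)
  .new_table(class, values,
             group = if (!is.null(g)) unname(g[colnames(values)]) else NULL,
             study = if (!is.null(s)) unname(s[colnames(values)]) else NULL)
}

#' Read / write abundance tables as TSV
#'
#' The on-disk dialect: UTF-8 tab-separated, first column the feature ID,
#' header row the sample IDs. `readAbundanceTable()` optionally joins a
#' metadata table (sample ID, group, study) by sample ID.
#'
#' @param path file path.
#' @param metadata optional data.frame with columns `sample` plus any of
#'   `group`, `study`; or a path to such a TSV.
#' @param signed logical; read as [CMPMatrix-class] (signed values allowed)?
#' @return `readAbundanceTable()` an [AbundanceTable-class] (or
#'   [CMPMatrix-class]); `writeAbundanceTable()` invisibly, the path.
#' @export
readAbundanceTable <- function(path, metadata = NULL, signed = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("table must have a feature-ID column plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature IDs in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp))
    stop("duplicate sample columns in ", path, ": ",
         paste(head(unique(samp[duplicated(samp)]), 3), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("numeric parse failure at row %d ('%s'), column '%s'",
                   bad[1, 1], ids[bad[1, 1]], samp[bad[1, 2]]))
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  group <- study <- NULL
  if (!is.null(metadata)) {
    if (is.character(metadata)) metadata <- read.delim(metadata, sep = "\t",
                                                       stringsAsFactors = FALSE)
    if (!"sample" %in% names(metadata)) stop("metadata needs a 'sample' column")
    idx <- match(samp, metadata$sample)
    if (anyNA(idx)) stop("metadata is missing sample(s): ",
                         paste(head(samp[is.na(idx)], 3), collapse = ", "))
    if ("group" %in% names(metadata)) group <- metadata$group[idx]
    if ("study" %in% names(metadata)) study <- metadata$study[idx]
  }
  if (signed) CMPMatrix(m, group, study) else AbundanceTable(m, group, study)
}

#' @param table an [AbundanceTable-class] or [CMPMatrix-class].
#' @param idColumn name for the first (feature ID) column.
#' @rdname readAbundanceTable
#' @export
writeAbundanceTable <- function(table, path, idColumn = "feature_id") {
  m <- abundances(table)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
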