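#' Expression matrix with phenotype labels
#'
#' Container for a genes-by-samples matrix of non-negative, linear-scale
#' (non-log) intensities together with a phenotype assignment of every sample
#' to `"R"` (resistant) or `"S"` (sensitive). All pairwise scores operate on
#' linear intensities; log2 is used internally only by the normalisation
#' helpers.
#'
#' @param values numeric matrix, rows = genes (unique rownames), columns =
#'   samples (unique colnames), all entries finite and >= 0.
#' @param phenotype named character vector mapping every sample id to `"R"`
#'   or `"S"`; names must cover `colnames(values)` exactly.
#' @return An object of class `expr_matrix`: the matrix with a `phenotype`
#'   attribute.
#' @examples
#' m <- matrix(c(10, 20, 30, 12, 18, 33), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("R1", "S1")))
#' x <- expr_matrix(m, c(R1 = "R", S1 = "S"))
#' phenotypes(x)
#' @export
expr_matrix <- function(values, phenotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyNA(values))
    stop("missing values present; drop or filter rows before construction", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity at gene ", rownames(values)[bad[1L]],
         ", sample ", colnames(values)[bad[2L]], call. = FALSE)
  }
  phenotype <- unlist(phenotype)
  if (is.null(names(phenotype)) || !all(colnames(values) %in% names(phenotype)))
    stop("`phenotype` must name every sample", call. = FALSE)
  phenotype <- phenotype[colnames(values)]
  if (!all(phenotype %in% c("R", "S")))
    stop("phenotypes must be 'R' or 'S'; offending sample(s): ",
         paste(names(phenotype)[!phenotype %in% c("R", "S")], collapse = ", "),
         call. = FALSE)
  structure(values, phenotype = phenotype, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
phenotypes <- function(x) attr(x, "phenotype")

#' @export
print.expr_matrix <- function(x, ...) {
  ph <- phenotypes(x)
  cat(sprintf("expr_matrix: %d genes x %d samples (%d R, %d S)\n",
              nrow(x), ncol(x), sum(ph == "R"), sum(ph == "S")))
  cat("samples:", paste0(colnames(x), "[", ph, "]", collapse = " "), "\n")
  invisible(x)
}

# subsetting keeps the phenotype attribute in step with the columns
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  ph <- phenotypes(x)
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "phenotype") <- ph[colnames(out)]
    class(out) <- c("expr_matrix", "matrix", "array")
  }
  out
}

#' Read an expression matrix and its phenotype annotation
#'
#' Reads a tab- or comma-separated intensity table (header row of sample ids,
#' first column of gene ids) and a phenotype annotation, returning a validated
#' [expr_matrix]. Rows with any missing value are dropped with a message.
#' Duplicate gene ids are collapsed by the arithmetic mean of their log2
#' values, back-transformed to the linear scale (see [collapse_probes]).
#'
#' @param path path to the matrix file (TSV or CSV, detected from the header).
#' @param annotation either a path to a two-column `sample<TAB>phenotype`
#'   table (no header required; one is tolerated) or a named character vector
#'   `c(sample = "R", ...)`.
#' @return An [expr_matrix].
#' @export
read_expr_matrix <- function(path, annotation) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("malformed header: need a gene-id column plus samples", call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric intensity column present", call. = FALSE)
  keep <- stats::complete.cases(vals)
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity at row ", ids[bad[1L]], ", column ",
         colnames(vals)[bad[2L]], call. = FALSE)
  }
  rownames(vals) <- make.unique(ids)  # temporary; duplicates collapsed below
  ph <- if (is.character(annotation) && length(annotation) == 1L && is.null(names(annotation)))
    read_phenotypes(annotation) else unlist(annotation)
  unknown <- setdiff(colnames(vals), names(ph))
  if (length(unknown))
    stop("sample(s) missing from annotation: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids)) {
    vals <- collapse_rows_log2(vals, ids)
  } else {
    rownames(vals) <- ids
  }
  expr_matrix(vals, ph)
}

#' Read a two-column phenotype annotation table
#'
#' @param path two-column text file `sample_id<TAB>phenotype` with phenotype
#'   `R` or `S`; a header line is skipped if present.
#' @return Named character vector of phenotypes.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation needs two columns: sample, phenotype", call. = FALSE)
  if (!df[1L, 2L] %in% c("R", "S")) df <- df[-1L, , drop = FALSE]  # header row
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write an expression matrix (and optionally its annotation) to TSV
#'
#' @param x an [expr_matrix].
#' @param path output path for the intensity table.
#' @param annotation_path optional path for the two-column phenotype table.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, annotation_path = NULL) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ph <- phenotypes(x)
    utils::write.table(data.frame(sample_id = names(ph), phenotype = ph),
                       annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# arithmetic mean on the log2 scale per group of rows, back to linear
collapse_rows_log2 <- function(vals, groups) {
  if (any(vals <= 0))
    stop("collapsing duplicate ids requires strictly positive intensities", call. = FALSE)
  lv <- log2(vals)
  out <- rowsum(lv, group = groups, reorder = FALSE) /
    as.vector(table(factor(groups, levels = unique(groups))))
  2^out
}

#' Quantile-normalise on the log2 scale
#'
#' Log2-transforms the intensities, quantile-normalises the columns so every
#' sample shares the identical sorted distribution (each rank set to the mean
#' of that rank across samples, average-rank convention for ties), and
#' back-transforms to the linear scale, since the pairwise scores are defined
#' on non-log intensities.
#'
#' @param x an [expr_matrix] with all values strictly positive.
#' @return A quantile-normalised [expr_matrix] on the linear scale.
#' @export
quantile_normalize_log2 <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (any(x == 0))
    stop("zero intensities present; apply floor_values() first", call. = FALSE)
  ln <- limma::normalizeQuantiles(log2(unclass(x)), ties = TRUE)
  expr_matrix(2^ln, phenotypes(x))
}

#' Collapse probe-level rows to genes
#'
#' Maps probe ids to gene ids and summarises multi-probe genes as the
#' arithmetic mean of the probe values on the log2 scale, back-transformed to
#' linear intensities. Probes absent from the map are dropped with a message.
#'
#' @param x an [expr_matrix] whose rows are probes.
#' @param probe_to_gene named character vector `c(probe_id = gene_id, ...)`,
#'   or a two-column data frame (probe, gene).
#' @return An [expr_matrix] with one row per gene.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2L]]),
                                     as.character(probe_to_gene[[1L]]))
  if (length(probe_to_gene) == 0L) stop("empty probe map", call. = FALSE)
  if (anyDuplicated(names(probe_to_gene)))
    stop("a probe maps to more than one gene", call. = FALSE)
  mapped <- rownames(x) %in% names(probe_to_gene)
  if (!all(mapped)) message(sum(!mapped), " unmapped probe(s) dropped")
  if (!any(mapped)) stop("no probe of the matrix is present in the map", call. = FALSE)
  vals <- unclass(x)[mapped, , drop = FALSE]
  genes <- probe_to_gene[rownames(vals)]
  expr_matrix(collapse_rows_log2(vals, genes), phenotypes(x))
}

#' Floor low intensities
#'
#' Replaces every value below `floor` by `floor`. Used ahead of fold-change
#' scoring to guard against division by (near-)zero intensities.
#'
#' @param x an [expr_matrix].
#' @param floor positive lower bound, default 1.
#' @return The floored [expr_matrix].
#' @export
floor_values <- function(x, floor = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("`floor` must be a single positive number", call. = FALSE)
  vals <- unclass(x)
  vals[vals < floor] <- floor
  expr_matrix(vals, phenotypes(x))
}
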