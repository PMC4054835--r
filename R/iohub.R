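# Core containers and readers/writers for the external formats the pipeline
# touches: expression matrices (TSV), sample annotations, FASTQ reads, GMT
# gene sets.

VALID_UNITS <- c("FPKM", "tpm", "RMA_log2", "arbitrary")

#' Construct an expression matrix
#'
#' The central container consumed by every metric: a genes x samples matrix of
#' nonnegative expression values with a declared unit scale and optional
#' per-gene metadata (transcript length, GC fraction) used by the QC and
#' simulation modules.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique; they become the gene and
#'   sample identifiers.
#' @param unit One of `"FPKM"`, `"tpm"`, `"RMA_log2"`, `"arbitrary"`. For
#'   FPKM/tpm matrices values must be nonnegative and zeros encode
#'   non-detection (absence is never NA).
#' @param gene_meta Optional data.frame with one row per gene (rownames =
#'   gene ids) carrying `transcript_length` (bp, >= 1) and `gc_fraction`
#'   (in \[0, 1\]).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, unit = "arbitrary", gene_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  unit <- match.arg(unit, VALID_UNITS)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ", colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values))
    stop("missing values are not allowed; encode non-detection as 0")
  if (unit %in% c("FPKM", "tpm") && any(values < 0))
    stop("negative values are invalid under unit ", unit)
  if (!is.null(gene_meta)) {
    gene_meta <- as.data.frame(gene_meta)
    if (!all(rownames(values) %in% rownames(gene_meta)))
      stop("gene_meta must cover every gene id")
    gene_meta <- gene_meta[rownames(values), , drop = FALSE]
    if ("gc_fraction" %in% names(gene_meta) &&
        any(gene_meta$gc_fraction < 0 | gene_meta$gc_fraction > 1))
      stop("gc_fraction must lie in [0, 1]")
    if ("transcript_length" %in% names(gene_meta) &&
        any(gene_meta$transcript_length < 1))
      stop("transcript_length must be >= 1")
  }
  structure(list(values = values, unit = unit, gene_meta = gene_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Construct a sample annotation table
#'
#' One row per sample: cell type (e.g. ES, PrE), cell-cycle phase, sample
#' class (real single cell, single-cell-sized aliquot from a pooled lysate,
#' or bulk reference) and a replicate-batch label.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param cell_type Character vector (recycled) of cell-type labels.
#' @param cycle_phase One of "G1", "S", "G2M" or NA per sample.
#' @param sample_class One of "single_cell", "pooled_equivalent",
#'   "bulk_reference" per sample.
#' @param batch Replicate-set label.
#' @return A data.frame of class `SampleAnnotation`.
#' @export
sample_annotation <- function(sample_id, cell_type, cycle_phase = NA_character_,
                              sample_class = "single_cell", batch = "batch1") {
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in annotation")
  phases <- c("G1", "S", "G2M")
  classes <- c("single_cell", "pooled_equivalent", "bulk_reference")
  ann <- data.frame(sample_id = as.character(sample_id),
                    cell_type = rep_len(as.character(cell_type), length(sample_id)),
                    cycle_phase = rep_len(as.character(cycle_phase), length(sample_id)),
                    sample_class = rep_len(as.character(sample_class), length(sample_id)),
                    batch = rep_len(as.character(batch), length(sample_id)),
                    stringsAsFactors = FALSE)
  bad <- !is.na(ann$cycle_phase) & !ann$cycle_phase %in% phases
  if (any(bad)) stop("unknown cycle_phase: ", ann$cycle_phase[which(bad)[1L]])
  if (!all(ann$sample_class %in% classes))
    stop("sample_class must be one of ", paste(classes, collapse = ", "))
  class(ann) <- c("SampleAnnotation", "data.frame")
  ann
}

# every sample in the matrix must have exactly one annotation row
check_annotation <- function(mat, annotation) {
  missing <- setdiff(sample_ids(mat), annotation$sample_id)
  if (length(missing))
    stop("samples lack annotation: ", paste(utils::head(missing, 3), collapse = ", "))
  invisible(TRUE)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column;
#' genes are rows (transposed input is never guessed).
#'
#' @param path Path to a tab-separated file.
#' @param unit Declared unit scale of the values.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, unit = "arbitrary") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file must have a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncols <- length(header)
  for (i in seq_along(fields)[-1L]) {
    if (length(fields[[i]]) != ncols)
      stop("ragged row at line ", i, ": expected ", ncols, " fields, got ",
           length(fields[[i]]))
  }
  gene <- vapply(fields[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(gene))
    stop("duplicate gene id: ", gene[duplicated(gene)][1L])
  samples <- header[-1L]
  vals <- matrix(NA_real_, nrow = length(gene), ncol = length(samples),
                 dimnames = list(gene, samples))
  for (i in seq_along(gene)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(v)) stop("non-numeric value at line ", i + 1L)
    vals[i, ] <- v
  }
  expression_matrix(vals, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Full-precision round trip: `read_matrix(write_matrix(m, f))` reproduces
#' values and ordering exactly.
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat$values)), function(i) {
    paste(c(gene_ids(mat)[i],
            format(mat$values[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a sample annotation table to TSV
#' @param annotation A [sample_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#' @param path Path written by [write_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_annotation(df$sample_id, df$cell_type, df$cycle_phase,
                    df$sample_class, df$batch)
}

#' Read FASTQ reads
#'
#' Plain or gzip-compressed 4-line FASTQ records (Phred+33 qualities).
#' Malformed input is rejected, never coerced: a truncated record or a
#' base/quality length mismatch raises an error naming the record index.
#'
#' @param path FASTQ path (`.gz` handled transparently).
#' @return A data.frame with columns `read_id`, `bases`, `qualities`
#'   (class `ReadSet`); zero rows for an empty file.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  ids <- character(); bases <- character(); quals <- character()
  idx <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0L) break
    idx <- idx + 1L
    if (length(rec) < 4L)
      stop("truncated FASTQ record at record ", idx)
    if (!startsWith(rec[1L], "@"))
      stop("record ", idx, ": header must start with '@'")
    if (rec[3L] != "+" && !startsWith(rec[3L], "+"))
      stop("record ", idx, ": separator line must start with '+'")
    if (nchar(rec[2L]) != nchar(rec[4L]))
      stop("record ", idx, ": base and quality strings differ in length")
    ids[idx] <- sub("^@", "", rec[1L])
    bases[idx] <- rec[2L]
    quals[idx] <- rec[4L]
  }
  reads <- data.frame(read_id = ids, bases = bases, qualities = quals,
                      stringsAsFactors = FALSE)
  class(reads) <- c("ReadSet", "data.frame")
  reads
}

#' Write FASTQ reads
#' @param reads A data.frame with `read_id`, `bases`, `qualities` columns.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$bases) != nchar(reads$qualities)))
    stop("base and quality strings differ in length")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$read_id, "\n", reads$bases, "\n+\n",
                      reads$qualities), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Duplicate members within a set are deduplicated; duplicate set names are
#' an error.
#'
#' @param path GMT path.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}
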