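#' Write a dataset to MatrixMarket + TSV sidecars
#'
#' Emits the counts as a MatrixMarket coordinate integer matrix in the
#' conventional genes x cells orientation, with `barcodes.tsv` (one barcode
#' per line), `genes.tsv` (`gene_id`, `chromosome`, `start`, `mito` as 0/1),
#' and `labels.tsv` (`barcode`, `truth_label`). Round-trips losslessly
#' through [read_dataset()].
#'
#' @param dataset A `scgain_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written (the manifest).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scgain_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(dataset$counts) != nrow(dataset$cells) ||
      ncol(dataset$counts) != nrow(dataset$genes))
    abort("counts dimensions do not match cell/gene sidecars.")
  files <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "genes.tsv",
                            "labels.tsv"))
  Matrix::writeMM(Matrix::t(dataset$counts), files[1])
  writeLines(dataset$cells$cell_id, files[2])
  gtab <- dataset$genes
  write.table(
    data.frame(gene_id = gtab$gene_id, chromosome = gtab$chromosome,
               start = gtab$start, mito = as.integer(gtab$mito)),
    files[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(barcode = dataset$cells$cell_id,
               truth_label = dataset$cells$truth_label),
    files[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `genes.tsv` and (optionally) `labels.tsv`.
#' @return A `scgain_dataset` (without generative `params`).
#' @export
read_dataset <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(sprintf("no matrix.mtx under '%s'.", dir))
  m <- Matrix::t(Matrix::readMM(mtx))
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- as_tibble(read.delim(file.path(dir, "genes.tsv"),
                                colClasses = c(gene_id = "character")))
  genes$mito <- as.logical(genes$mito)
  if (nrow(m) != length(barcodes) || ncol(m) != nrow(genes))
    abort("matrix dimensions do not match barcodes/genes sidecars.")
  dimnames(m) <- list(barcodes, genes$gene_id)
  lab_path <- file.path(dir, "labels.tsv")
  cells <- if (file.exists(lab_path)) {
    lab <- read.delim(lab_path, colClasses = "character")
    tibble(cell_id = lab$barcode, truth_label = lab$truth_label)
  } else tibble(cell_id = barcodes, truth_label = NA_character_)
  if (!"marker" %in% names(genes)) genes$marker <- FALSE
  structure(list(counts = m, cells = cells, genes = genes,
                 params = NULL, config = NULL),
            class = "scgain_dataset")
}

#' Ingest an externally produced count matrix
#'
#' Normalizes external layouts into a `scgain_dataset`: either a
#' MatrixMarket triplet (genes x cells, with barcode and gene sidecars) or
#' a dense TSV (genes in rows, cells in columns, first column gene ids).
#' An optional annotation table (columns `barcode`, `cell_type`) marks
#' reference cells for CNV scoring via `reference_types`.
#'
#' @param matrix_path Path to `.mtx` or dense TSV matrix.
#' @param barcodes_path Barcode file (one per line); ignored for dense TSV.
#' @param genes_path Gene table TSV with at least `gene_id`; `chromosome`
#'   and `start` enable CNV scoring, `mito` the QC mito rule (otherwise
#'   genes prefixed `MT-` are flagged).
#' @param annotations_path Optional TSV with `barcode` and `cell_type`.
#' @param reference_types Cell-type labels treated as the diploid CNV
#'   reference (e.g. fibroblasts and B cells).
#' @return A `scgain_dataset`; `cells$truth_label` is `"reference"` for
#'   annotated reference cells, the annotation otherwise, `NA` if no
#'   annotation file is given.
#' @export
ingest_external <- function(matrix_path, barcodes_path = NULL,
                            genes_path = NULL, annotations_path = NULL,
                            reference_types = c("Fibroblast", "B cell")) {
  if (grepl("\\.mtx$", matrix_path)) {
    m <- Matrix::t(Matrix::readMM(matrix_path))
    m <- as(as(m, "CsparseMatrix"), "dMatrix")
    if (is.null(barcodes_path) || is.null(genes_path))
      abort("MTX ingestion needs barcodes and genes sidecars.")
    barcodes <- readLines(barcodes_path)
    genes <- as_tibble(read.delim(genes_path,
                                  colClasses = c(gene_id = "character")))
  } else {
    dense <- read.delim(matrix_path, check.names = FALSE)
    gene_ids <- as.character(dense[[1]])
    m <- Matrix(t(as.matrix(dense[, -1, drop = FALSE])), sparse = TRUE)
    m <- as(m, "CsparseMatrix")
    rownames(m) <- colnames(dense)[-1]
    barcodes <- rownames(m)
    genes <- if (!is.null(genes_path))
      as_tibble(read.delim(genes_path, colClasses = c(gene_id = "character")))
    else tibble(gene_id = gene_ids)
  }
  if (anyDuplicated(barcodes))
    abort("duplicated barcodes in input.", class = "scgain_ingest_error")
  if (nrow(m) != length(barcodes) || ncol(m) != nrow(genes))
    abort("matrix dimensions disagree with sidecars.",
          class = "scgain_ingest_error")
  if (!all(c("chromosome", "start") %in% names(genes))) {
    warn("gene table lacks chromosome/start positions; CNV scoring disabled.")
    if (!"chromosome" %in% names(genes)) genes$chromosome <- NA_character_
    if (!"start" %in% names(genes)) genes$start <- NA_integer_
  }
  if (!"mito" %in% names(genes)) {
    genes$mito <- grepl("^MT-", genes$gene_id)
  } else genes$mito <- as.logical(as.integer(genes$mito))
  if (!"marker" %in% names(genes)) genes$marker <- FALSE
  dimnames(m) <- list(barcodes, genes$gene_id)

  truth <- rep(NA_character_, length(barcodes))
  if (!is.null(annotations_path)) {
    ann <- read.delim(annotations_path, colClasses = "character")
    idx <- match(barcodes, ann$barcode)
    truth <- ann$cell_type[idx]
    truth[!is.na(truth) & truth %in% reference_types] <- "reference"
  }
  message(sprintf("ingested %d cells x %d genes", nrow(m), ncol(m)))
  structure(list(counts = m,
                 cells = tibble(cell_id = barcodes, truth_label = truth),
                 genes = genes, params = NULL, config = NULL),
            class = "scgain_dataset")
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and one or more member genes,
#' tab-separated. Duplicate genes within a set are removed with a warning;
#' lines with fewer than three fields raise a parse error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique-gene character vectors, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(sprintf("GMT parse error at line %d: fewer than 3 fields.", i),
            class = "scgain_gmt_error")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warn(sprintf("gene set '%s' contains duplicated genes; deduplicated.",
                   fields[1]))
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (second column).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
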