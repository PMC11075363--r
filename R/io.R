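# Readers and writers for the standard formats the pipeline consumes and
# produces. All genomic output is 0-based half-open BED; input CpG tables
# are 1-based (bedGraph-of-CpG dialect).

read_tsv_clean <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)  # tolerate CRLF
  read.table(text = lines, sep = "\t", header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read a per-CpG beta table as TSV
#'
#' Columns: `chrom`, `pos` (1-based), one beta column per sample. The
#' sample-to-group map travels separately as YAML.
#'
#' @param table A [cpg_table()].
#' @param path Output TSV path.
#' @param groups_path Optional YAML path for the sample-group map.
#' @return `path`, invisibly.
#' @export
write_beta_tsv <- function(table, path, groups_path = NULL) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(groups_path))
    yaml::write_yaml(as.list(attr(table, "groups")), groups_path)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @param groups Named group vector, or a YAML path written by
#'   [write_beta_tsv()].
#' @export
read_beta_tsv <- function(path, groups) {
  df <- read_tsv_clean(path)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- unlist(yaml::read_yaml(groups))
  cpg_table(df, groups)
}

#' Write / read a BED file (0-based half-open)
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path File path.
#' @return `path` invisibly (write); a `data.frame` (read).
#' @export
write_bed <- function(regions, path) {
  cols <- c("chrom", "start", "end")
  extra <- intersect(c("name", "score", "strand"), names(regions))
  write.table(regions[c(cols, extra)], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("malformed BED record at line ", bad[1L], ": start >= end",
         call. = FALSE)
  df
}

#' Write finalized DMRs as BED6
#'
#' `name` is `direction;cluster_id`; `score` is
#' `floor(1000 * |mean_delta_beta|)`.
#'
#' @param dmrs Output of [finalize_dmr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                    end = dmrs$end,
                    name = if (nrow(dmrs)) paste(dmrs$direction,
                                                 dmrs$cluster_id,
                                                 sep = ";") else character(),
                    score = floor(1000 * abs(dmrs$mean_delta_beta)),
                    strand = rep(".", nrow(dmrs)))
  write_bed(bed, path)
}

#' Write / read a sparse expression matrix (MatrixMarket + metadata TSVs)
#'
#' Explicit zeros are dropped (the sparse dialect); gene and cell
#' metadata travel as TSVs alongside the `.mtx`.
#'
#' @param counts Genes x cells sparse matrix.
#' @param dir Output directory (created if needed); files
#'   `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param cell_meta Optional per-cell `data.frame` (must contain
#'   `cell_id` matching the matrix columns).
#' @return The directory, invisibly (write); a list with `counts` and
#'   `cell_meta` (read).
#' @export
write_expression_dir <- function(counts, dir, cell_meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene = rownames(counts)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cm <- if (is.null(cell_meta)) data.frame(cell_id = colnames(counts))
    else cell_meta
  write.table(cm, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_dir
#' @export
read_expression_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- read_tsv_clean(file.path(dir, "genes.tsv"))
  cells <- read_tsv_clean(file.path(dir, "cells.tsv"))
  dimnames(counts) <- list(genes$gene, cells$cell_id)
  list(counts = counts, cell_meta = cells)
}

#' Write a PWM as a JASPAR-style position frequency matrix text file
#'
#' @param pwm A 4 x width matrix (rows A, C, G, T).
#' @param path Output path.
#' @param name Motif name header.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pwm, path, name = "motif") {
  lines <- c(paste0(">", name),
             vapply(rownames(pwm), function(b)
               paste0(b, " [ ", paste(sprintf("%.4f", pwm[b, ]),
                                      collapse = " "), " ]"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
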