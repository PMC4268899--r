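# Plain-text readers and writers -----------------------------------------
#
# Matrices travel as TSV with a probe_id column and sample-id header;
# the sample sheet as CSV; interval tracks as BED (0-based, half-open)
# through rtracklayer. Every writer round-trips losslessly through its
# reader.

#' Write / read a probes-by-samples matrix as TSV
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return the path (writer, invisibly) or the matrix (reader).
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read the sample sheet as CSV
#'
#' @param sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(sheet) <- sheet$sample_id
  sheet
}

#' Write / read the probe annotation as TSV
#'
#' @param annotation data.frame.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  anno <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(anno) <- anno$probe_id
  anno
}

#' Write / read an interval track as BED
#'
#' BED is 0-based half-open; the in-memory representation used across
#' this package (`chrom`, `start`, `end`, `class`/`name` data.frame)
#' uses the same convention, and [rtracklayer::export.bed()] /
#' [rtracklayer::import.bed()] handle the conversion to and from the
#' 1-based `GRanges` world.
#'
#' @param track data.frame with `chrom`, `start`, `end` and a `class` or
#'   `name` column.
#' @param path file path (`.bed`).
#' @export
write_bed <- function(track, path) {
  gr <- bed_to_granges(track)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_bed
#' @param name_as column name for the BED name field on reading
#'   (`"class"` for repeat tracks, `"name"` for microRNA loci).
#' @export
read_bed <- function(path, name_as = "class") {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out[[name_as]] <- gr$name
  out
}

#' Materialize a synthetic dataset as a pipeline-readable fixture
#'
#' Writes the generator's outputs in the exact dialects the pipeline
#' readers expect: beta and detection-p TSV, sample sheet CSV, probe
#' annotation TSV, repeat and microRNA BED, ground-truth TSV.
#'
#' @param sim a `"crossmeth_sim"` object (or a [simulation_config()],
#'   which is generated first).
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture <- function(sim, dir) {
  if (inherits(sim, "simulation_config")) sim <- generate_dataset(sim)
  stopifnot(inherits(sim, "crossmeth_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             detp = file.path(dir, "detection_p.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             annotation = file.path(dir, "annotation.tsv"),
             repeats = file.path(dir, "repeats.bed"),
             mirna = file.path(dir, "mirna.bed"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_matrix_tsv(sim$beta, paths["beta"])
  write_matrix_tsv(sim$detp, paths["detp"])
  write_sample_sheet(sim$sheet, paths["sheet"])
  write_annotation(sim$annotation, paths["annotation"])
  write_bed(sim$repeats, paths["repeats"])
  write_bed(sim$mirna_loci, paths["mirna"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into a dataset bundle
#'
#' @param dir directory written by [make_fixture()].
#' @return list with `beta`, `detp`, `sheet`, `annotation`, `repeats`,
#'   `mirna_loci` (and `truth` when present).
#' @export
read_fixture <- function(dir) {
  out <- list(beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
              detp = read_matrix_tsv(file.path(dir, "detection_p.tsv")),
              sheet = read_sample_sheet(file.path(dir, "sample_sheet.csv")),
              annotation = read_annotation(file.path(dir, "annotation.tsv")),
              repeats = read_bed(file.path(dir, "repeats.bed"), "class"),
              mirna_loci = read_bed(file.path(dir, "mirna.bed"), "name"))
  tp <- file.path(dir, "ground_truth.tsv")
  if (file.exists(tp))
    out$truth <- utils::read.delim(tp, stringsAsFactors = FALSE)
  out
}
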