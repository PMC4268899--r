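# Repeat-element and microRNA locus overlap ------------------------------
#
# Array probes are ~50 bp footprints; a probe is assigned to a repeat
# class (Alu, LINE1) when it overlaps an interval of that class by at
# least `min_overlap_bp` (default 15 bp, i.e. at least 30% of the probe
# inside the repeat). Repeat tracks use the BED dialect (0-based,
# half-open); probe annotation positions are 1-based, per array manifest
# convention. The conversion is explicit here and nowhere else.

#' Probe footprints as genomic intervals
#'
#' Builds the 1-based closed genomic interval covered by each probe from
#' the annotated CpG position. The footprint is `probe_length` bp and,
#' by default, end-anchored: the probe ends at the interrogated CpG.
#'
#' @param annotation annotation data.frame with `probe_id`, `chr`, `pos`.
#' @param probe_length footprint length in bp (default 50).
#' @param anchor `"end"` (footprint ends at `pos`), `"start"` (begins at
#'   `pos`) or `"center"`.
#' @return a [GenomicRanges::GRanges] with probe ids as names.
#' @export
probe_intervals <- function(annotation, probe_length = 50L,
                            anchor = c("end", "start", "center")) {
  anchor <- match.arg(anchor)
  start <- switch(anchor,
    end = annotation$pos - probe_length + 1L,
    start = annotation$pos,
    center = annotation$pos - probe_length %/% 2L)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chr,
    ranges = IRanges::IRanges(start = pmax(start, 1L),
                              width = probe_length))
  names(gr) <- annotation$probe_id
  gr
}

# BED data.frame (0-based half-open) -> GRanges (1-based closed)
bed_to_granges <- function(bed) {
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  if (!is.null(bed$class)) gr$name <- bed$class
  if (!is.null(bed$name)) gr$name <- bed$name
  gr
}

#' Probes overlapping repeat elements, per class
#'
#' A probe belongs to a repeat class when its footprint overlaps some
#' interval of that class by at least `min_overlap_bp` base pairs
#' (overlap of half-open intervals \[a,b) and \[x,y) is
#' `max(0, min(b,y) - max(a,x))`). A probe may belong to several
#' classes. Records on chromosomes absent from the other input are
#' simply non-overlapping; truly malformed records are skipped with a
#' warning by the BED reader.
#'
#' @param probes a `GRanges` of probe footprints ([probe_intervals()]).
#' @param track repeat track: data.frame with `chrom`, `start`, `end`,
#'   `class` (BED dialect) or a `GRanges` with a `name` column.
#' @param min_overlap_bp minimum overlap in bp (default 15).
#' @return named list of character vectors of probe ids, one per class.
#' @examples
#' anno <- data.frame(probe_id = "p1", chr = "chr1", pos = 150)
#' track <- data.frame(chrom = "chr1", start = 135, end = 200,
#'                     class = "Alu")
#' probes_in_repeats(probe_intervals(anno), track)$Alu  # 15 bp: included
#' @export
probes_in_repeats <- function(probes, track, min_overlap_bp = 15L) {
  stopifnot(min_overlap_bp >= 1L)
  gr <- if (methods::is(track, "GRanges")) track else bed_to_granges(track)
  classes <- sort(unique(gr$name))
  out <- lapply(classes, function(cls) {
    sub <- gr[gr$name == cls]
    hits <- GenomicRanges::findOverlaps(probes, sub,
                                        minoverlap = min_overlap_bp)
    sort(unique(names(probes)[S4Vectors::queryHits(hits)]))
  })
  names(out) <- classes
  for (cls in classes)
    message(length(out[[cls]]), " probes overlap ", cls,
            " by >= ", min_overlap_bp, " bp")
  out
}

#' Probes overlapping microRNA loci
#'
#' Probes whose footprint overlaps a named locus by at least one base
#' pair, annotated with the locus name.
#'
#' @param probes a `GRanges` of probe footprints.
#' @param mirna_loci data.frame with `chrom`, `start`, `end`, `name`
#'   (BED dialect) or a named `GRanges`.
#' @return data.frame with columns `probe_id`, `mirna` (empty when the
#'   locus table is empty).
#' @export
probes_in_mirna <- function(probes, mirna_loci) {
  if ((is.data.frame(mirna_loci) && nrow(mirna_loci) == 0L) ||
      (methods::is(mirna_loci, "GRanges") && length(mirna_loci) == 0L))
    return(data.frame(probe_id = character(0), mirna = character(0),
                      stringsAsFactors = FALSE))
  gr <- if (methods::is(mirna_loci, "GRanges")) mirna_loci
        else bed_to_granges(mirna_loci)
  hits <- GenomicRanges::findOverlaps(probes, gr, minoverlap = 1L)
  data.frame(probe_id = names(probes)[S4Vectors::queryHits(hits)],
             mirna = gr$name[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Differential methylation analysis within region probe sets
#'
#' Runs the per-probe mixed model and DMP calling on each region probe
#' set (e.g. Alu, LINE1, microRNA probes) with the q-value family
#' restricted to that set. Region DMPs are deliberately not required to
#' pass any PCA loading cutoff; repeat-element effects are typically too
#' diffuse to surface in single components.
#'
#' @param m probes x samples M matrix (analysis-ready).
#' @param beta matching beta matrix (for effect sizes).
#' @param sheet sample sheet.
#' @param region_sets named list of probe-id vectors.
#' @param cell_result cell-composition result passed to [call_dmps()].
#' @param fdr FDR level (default 0.10).
#' @return named list of `"dmp_report"` objects.
#' @export
region_dmp_analysis <- function(m, beta, sheet, region_sets,
                                cell_result = NULL, fdr = 0.10) {
  out <- lapply(names(region_sets), function(cls) {
    probes <- intersect(region_sets[[cls]], rownames(m))
    if (!length(probes)) {
      warning("region set ", cls, " has no probes in the matrix; skipped")
      return(NULL)
    }
    if (length(probes) < 10L)
      warning("region set ", cls, " has only ", length(probes),
              " probes; q-values over a small family are unstable")
    fit <- fit_lme(m, sheet, probes)
    db <- delta_beta(beta, sheet, probes)
    call_dmps(fit, db, cell_result = cell_result, fdr = fdr)
  })
  names(out) <- names(region_sets)
  out[!vapply(out, is.null, TRUE)]
}
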