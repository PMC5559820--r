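## Pfam vs CATH domain-region overlap per protein: union each source's
## residue intervals, intersect the two unions, report coverage percents.

#' Union of 1-based inclusive residue intervals
#'
#' Coalesces a set of possibly overlapping intervals into sorted disjoint
#' ones and reports the total residue count.
#'
#' @param starts,ends parallel integer vectors, \code{starts <= ends}.
#' @return A list with \code{intervals} (data.frame \code{start},
#'   \code{end}) and \code{length} (total residues covered).
#' @examples
#' regionUnion(c(1, 102), c(176, 176))  # -> [1,176], length 176
#' @export
regionUnion <- function(starts, ends) {
    if (any(starts > ends)) stop("interval start exceeds end")
    merged <- IRanges::reduce(IRanges::IRanges(starts, ends))
    list(intervals = data.frame(start = IRanges::start(merged),
                                end = IRanges::end(merged)),
         length = sum(IRanges::width(merged)))
}

# round half-up to integer, the convention used for reported percentages
.roundHalfUp <- function(x) floor(x + 0.5)

#' Overlap between a protein's Pfam and CATH domain regions
#'
#' The Pfam region is the union of all Pfam occurrence intervals on the
#' protein, likewise for CATH; the overlap is the intersection of the two
#' unions. Percentages are kept at full precision in \code{pct_of_cath} /
#' \code{pct_of_pfam}; columns \code{pct_of_cath_rounded} /
#' \code{pct_of_pfam_rounded} carry the half-up integer rounding used for
#' reporting.
#'
#' @param gene gene symbol.
#' @param annotations domain annotation table covering this gene.
#' @return One-row \code{data.frame} (\code{gene}, \code{pfam_region_len},
#'   \code{cath_region_len}, \code{overlap_len}, percent columns), or
#'   \code{NULL} when the gene lacks annotations from one of the sources
#'   (a skip, not an error).
#' @examples
#' ann <- data.frame(
#'     domain_id = c("1.10.10.10", "1.10.10.570", "ESCRT-II"),
#'     source = c("CATH", "CATH", "PFAM"),
#'     gene = "VPS25",
#'     start_res = c(102L, 1L, 10L), end_res = c(176L, 176L, 145L))
#' proteinOverlap("VPS25", ann)  # 77% of CATH, 100% of Pfam
#' @export
proteinOverlap <- function(gene, annotations) {
    a <- annotations[annotations$gene == gene, , drop = FALSE]
    pf <- a[a$source == "PFAM", , drop = FALSE]
    ca <- a[a$source == "CATH", , drop = FALSE]
    if (!nrow(pf) || !nrow(ca)) return(NULL)
    pfU <- IRanges::reduce(IRanges::IRanges(pf$start_res, pf$end_res))
    caU <- IRanges::reduce(IRanges::IRanges(ca$start_res, ca$end_res))
    ov <- IRanges::intersect(pfU, caU)
    pfLen <- sum(IRanges::width(pfU))
    caLen <- sum(IRanges::width(caU))
    ovLen <- sum(IRanges::width(ov))
    data.frame(gene = gene, pfam_region_len = pfLen,
               cath_region_len = caLen, overlap_len = ovLen,
               pct_of_cath = 100 * ovLen / caLen,
               pct_of_pfam = 100 * ovLen / pfLen,
               pct_of_cath_rounded = .roundHalfUp(100 * ovLen / caLen),
               pct_of_pfam_rounded = .roundHalfUp(100 * ovLen / pfLen),
               stringsAsFactors = FALSE)
}

#' Overlap table over all proteins annotated by both sources
#'
#' @param annotations domain annotation table.
#' @return \code{data.frame} of \code{\link{proteinOverlap}} rows (may be
#'   empty); proteins with only one source are skipped.
#' @export
overlapTable <- function(annotations) {
    genes <- sort(unique(annotations$gene))
    rows <- lapply(genes, proteinOverlap, annotations = annotations)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(gene = character(0), pfam_region_len = integer(0),
                          cath_region_len = integer(0),
                          overlap_len = integer(0),
                          pct_of_cath = numeric(0), pct_of_pfam = numeric(0),
                          pct_of_cath_rounded = numeric(0),
                          pct_of_pfam_rounded = numeric(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Average overlap percentages across proteins
#'
#' Unweighted (per-protein) arithmetic means of the full-precision
#' coverage percentages, over proteins carrying both sources.
#'
#' @param results an \code{\link{overlapTable}} result.
#' @return Named numeric: \code{mean_pct_of_cath}, \code{mean_pct_of_pfam}.
#' @export
averageOverlap <- function(results) {
    if (!nrow(results)) stop("no proteins with both Pfam and CATH regions")
    c(mean_pct_of_cath = mean(results$pct_of_cath),
      mean_pct_of_pfam = mean(results$pct_of_pfam))
}
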