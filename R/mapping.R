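## Genomic position -> protein residue conversion and domain assignment.
## One canonical transcript per gene; coordinates 1-based inclusive.

# All exons of all genes as one plain table (one GRanges unlist total:
# much cheaper than touching the GRangesList once per gene in hot loops).
.exonTable <- function(models) {
    exl <- exonRanges(models)
    ex <- unlist(exl, use.names = FALSE)
    data.frame(gene = rep(names(exl), lengths(exl)),
               start = GenomicRanges::start(ex),
               end = GenomicRanges::end(ex),
               stringsAsFactors = FALSE, row.names = NULL)
}

# Per-gene CDS segment table: genomic exon pieces clipped to the CDS span,
# with the cumulative spliced-CDS offset preceding each piece, oriented
# 5'->3' on the coding strand.
.cdsSegments <- function(models, gene, exonTab = NULL) {
    g <- geneTable(models)
    i <- match(gene, g$gene)
    if (is.na(i)) return(NULL)
    if (is.null(exonTab)) exonTab <- .exonTable(models)
    e <- exonTab[exonTab$gene == gene, , drop = FALSE]
    st <- pmax(e$start, g$cds_start[i])
    en <- pmin(e$end, g$cds_end[i])
    keep <- st <= en
    st <- st[keep]; en <- en[keep]
    ord <- if (g$strand[i] == "-") order(st, decreasing = TRUE) else
        order(st)
    st <- st[ord]; en <- en[ord]
    w <- en - st + 1L
    data.frame(start = st, end = en,
               cum_before = cumsum(c(0L, w))[seq_along(w)],
               stringsAsFactors = FALSE, row.names = NULL,
               strand = g$strand[i])
}

#' Convert a genomic position to a protein residue index
#'
#' Returns \eqn{\lceil o/3 \rceil} where \eqn{o} is the 1-based offset of
#' the position within the spliced, strand-oriented CDS of the gene, or
#' \code{NA} when the position falls outside the CDS (intron, UTR, or off
#' the gene entirely). Vectorised over \code{pos}.
#'
#' @param pos genomic position(s), 1-based.
#' @param models a \linkS4class{GeneModelSet}.
#' @param gene the gene whose transcript to map against.
#' @return Integer residue indices, \code{NA} where unmapped.
#' @examples
#' # a single-exon gene with CDS starting at 101: positions 101..103 are
#' # residue 1, position 104 starts residue 2
#' @export
genomicToResidue <- function(pos, models, gene) {
    .residueFromSegments(pos, .cdsSegments(models, gene))
}

.residueFromSegments <- function(pos, seg) {
    res <- rep(NA_integer_, length(pos))
    if (is.null(seg)) return(res)
    for (j in seq_len(nrow(seg))) {
        inside <- pos >= seg$start[j] & pos <= seg$end[j]
        if (!any(inside)) next
        off <- if (seg$strand[1] == "-")
            seg$cum_before[j] + (seg$end[j] - pos[inside] + 1L)
        else
            seg$cum_before[j] + (pos[inside] - seg$start[j] + 1L)
        res[inside] <- as.integer(ceiling(off / 3))
    }
    res
}

# residue index for every record (NA: gene unknown or position non-coding)
.mapResidues <- function(records, models) {
    res <- rep(NA_integer_, nrow(records))
    exonTab <- .exonTable(models)
    for (gene in unique(records$gene)) {
        sel <- records$gene == gene
        res[sel] <- .residueFromSegments(
            records$pos[sel], .cdsSegments(models, gene, exonTab))
    }
    res
}

#' Keep coding, non-synonymous mutations
#'
#' Retains records whose \code{variant_class} is not synonymous and whose
#' genomic position maps to a residue of its gene's transcript. Input order
#' is preserved; the operation is idempotent.
#'
#' @param records mutation table (see \code{\link{readMutations}}).
#' @param models a \linkS4class{GeneModelSet}.
#' @return The retained subset of \code{records}.
#' @export
filterCodingNonsynonymous <- function(records, models) {
    if (!nrow(records)) return(records)
    keep <- records$variant_class != "synonymous" &
        !is.na(.mapResidues(records, models))
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Assign mutations to the domain occurrences they fall in
#'
#' Produces one hit per (mutation, distinct domain id) pair: a mutation
#' inside occurrences of two different domain ids yields two hits, while
#' overlapping occurrences of the same id count once, so a domain's
#' mutation count is never inflated by self-overlap. Indels are assigned by
#' their 1-based start position. Mutations whose gene has no model are
#' skipped with a warning (the count is attached as attribute
#' \code{"skipped"}).
#'
#' @param records filtered mutation table.
#' @param models a \linkS4class{GeneModelSet}.
#' @param annotations domain annotation table (see \code{\link{readDomains}}).
#' @return Hit table: \code{patient_id}, \code{cancer_type}, \code{gene},
#'   \code{pos}, \code{residue}, \code{domain_id}, \code{source},
#'   \code{mut_index} (row of \code{records}).
#' @export
assignToDomains <- function(records, models, annotations) {
    empty <- data.frame(patient_id = character(0), cancer_type = character(0),
                        gene = character(0), pos = integer(0),
                        residue = integer(0), domain_id = character(0),
                        source = character(0), mut_index = integer(0),
                        stringsAsFactors = FALSE)
    if (!nrow(records)) return(empty)
    known <- records$gene %in% geneTable(models)$gene
    nskip <- sum(!known)
    if (nskip)
        warning(nskip, " mutation(s) in genes without a model were skipped")
    rec <- records[known, , drop = FALSE]
    idx <- which(known)
    residue <- .mapResidues(rec, models)
    ok <- !is.na(residue)
    rec <- rec[ok, , drop = FALSE]; idx <- idx[ok]; residue <- residue[ok]
    if (!nrow(rec) || !nrow(annotations)) {
        attr(empty, "skipped") <- nskip
        return(empty)
    }
    lv <- union(unique(rec$gene), unique(annotations$gene))
    mutGR <- GenomicRanges::GRanges(
        factor(rec$gene, levels = lv), IRanges::IRanges(residue, residue))
    domGR <- GenomicRanges::GRanges(
        factor(annotations$gene, levels = lv),
        IRanges::IRanges(annotations$start_res, annotations$end_res))
    ov <- GenomicRanges::findOverlaps(mutGR, domGR, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    hits <- data.frame(
        patient_id = rec$patient_id[q], cancer_type = rec$cancer_type[q],
        gene = rec$gene[q], pos = rec$pos[q], residue = residue[q],
        domain_id = annotations$domain_id[s],
        source = annotations$source[s],
        mut_index = idx[q], stringsAsFactors = FALSE)
    # one hit per (mutation, domain id, source)
    hits <- hits[!duplicated(hits[c("mut_index", "domain_id", "source")]), ,
                 drop = FALSE]
    hits <- hits[order(hits$mut_index, hits$source, hits$domain_id), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    attr(hits, "skipped") <- nskip
    hits
}
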