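# Shared fixtures and independent oracles.

# Build a GeneModelSet from an exon spec list:
#   list(gene = list(strand=, exons=matrix(start,end), cds=c(start,end)))
# protein length is derived from the CDS overlap so invariants hold.
makeModels <- function(spec) {
    rows <- list(); exons <- list()
    for (g in names(spec)) {
        s <- spec[[g]]
        ir <- IRanges::IRanges(s$exons[, 1], s$exons[, 2])
        cdsNt <- sum(IRanges::width(IRanges::restrict(ir, s$cds[1],
                                                      s$cds[2])))
        rows[[g]] <- data.frame(
            gene = g, transcript_id = paste0(g, ".t1"), chrom = "chrT",
            strand = s$strand, cds_start = s$cds[1], cds_end = s$cds[2],
            protein_length = cdsNt %/% 3L, stringsAsFactors = FALSE)
        exons[[g]] <- GenomicRanges::GRanges(
            "chrT", ir, strand = s$strand)
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    methods::new("GeneModelSet", genes = genes,
                 exons = GenomicRanges::GRangesList(exons))
}

# Independent mapping oracle: explicitly build the strand-oriented spliced
# CDS genomic coordinate list, then index into it.
splicedCdsPositions <- function(models, gene) {
    g <- geneTable(models)
    i <- match(gene, g$gene)
    ex <- exonRanges(models)[[gene]]
    pos <- unlist(lapply(seq_along(ex), function(j)
        seq.int(GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j])))
    pos <- sort(pos[pos >= g$cds_start[i] & pos <= g$cds_end[i]])
    if (g$strand[i] == "-") pos <- rev(pos)
    pos
}

oracleResidue <- function(p, spliced) {
    idx <- match(p, spliced)
    ifelse(is.na(idx), NA_integer_, as.integer(ceiling(idx / 3)))
}

# mutation record builder with defaults
mutRec <- function(gene, pos, patient = "P1", ct = "CTX",
                   cls = "missense") {
    data.frame(patient_id = patient, cancer_type = ct, gene = gene,
               chrom = "chrT", pos = as.integer(pos), ref_allele = "A",
               alt_allele = "C", variant_class = cls,
               stringsAsFactors = FALSE)
}

# the printed VPS25 geometry: two nested CATH occurrences, one Pfam domain
vps25Annotations <- function() {
    data.frame(
        domain_id = c("1.10.10.10", "1.10.10.570", "ESCRT-II"),
        source = c("CATH", "CATH", "PFAM"),
        gene = "VPS25",
        start_res = c(102L, 1L, 10L),
        end_res = c(176L, 176L, 145L),
        stringsAsFactors = FALSE)
}

# single-exon plus-strand gene: CDS 101..160, 20 residues
simpleModels <- function() {
    makeModels(list(GS = list(strand = "+",
                              exons = cbind(101L, 160L),
                              cds = c(101L, 160L))))
}
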