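## Seeded synthetic scenarios: gene models on one synthetic chromosome,
## Pfam/CATH-style annotations, and multi-cancer cohorts with uniform
## background mutation and optional planted enrichment.

SYNTH_CHROM <- "chrS"
.INTRON_GAP <- 100L     # nt between exons
.INTERGENIC_GAP <- 1000L  # nt between genes

#' Construct a SyntheticConfig
#'
#' Defaults describe a small null scenario: 50 genes of 1-4 exons (30-120
#' codons each), 20 Pfam-style and 10 CATH-style domain ids of 20-80
#' residues, two cancer types of 20 patients averaging 30 mutations each,
#' 25\% synonymous, no planted enrichment.
#'
#' @param nGenes,exonsPerGene,exonLength,nDomainsPfam,nDomainsCath,domainLength
#'   see \linkS4class{SyntheticConfig}; ranges are length-2 (min, max).
#' @param cancerTypes,patientsPerCancer,mutationsPerPatient cohort shape;
#'   mutation counts per patient are Poisson with this mean.
#' @param plantedEnrichments named numeric of fold multipliers (>= 1) keyed
#'   by domain id; positions inside that domain's occurrences receive
#'   fold-times the background per-position rate.
#' @param synonymousFraction Bernoulli probability of a synonymous class.
#' @param seed integer; fixes all generator randomness.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' syntheticConfig(nGenes = 5, seed = 7)
#' @export
syntheticConfig <- function(nGenes = 50L, exonsPerGene = c(1L, 4L),
                            exonLength = c(30L, 120L),
                            nDomainsPfam = 20L, nDomainsCath = 10L,
                            domainLength = c(20L, 80L),
                            cancerTypes = c("CT1", "CT2"),
                            patientsPerCancer = 20L,
                            mutationsPerPatient = 30,
                            plantedEnrichments = numeric(0),
                            synonymousFraction = 0.25,
                            seed = 1L) {
    methods::new("SyntheticConfig",
                 nGenes = as.integer(nGenes),
                 exonsPerGene = as.integer(exonsPerGene),
                 exonLength = as.integer(exonLength),
                 nDomainsPfam = as.integer(nDomainsPfam),
                 nDomainsCath = as.integer(nDomainsCath),
                 domainLength = as.integer(domainLength),
                 cancerTypes = as.character(cancerTypes),
                 patientsPerCancer = as.integer(patientsPerCancer),
                 mutationsPerPatient = as.numeric(mutationsPerPatient),
                 plantedEnrichments = plantedEnrichments,
                 synonymousFraction = synonymousFraction,
                 seed = as.integer(seed))
}

.sampleRange <- function(r, n) {
    if (r[1] == r[2]) rep(r[1], n) else sample(seq.int(r[1], r[2]), n,
                                               replace = TRUE)
}

#' Generate synthetic gene models
#'
#' Genes are laid end-to-end on one synthetic chromosome with fixed
#' intergenic (1000 nt) and intron (100 nt) gaps; every exon is a whole
#' number of codons, so the CDS is the full exon span and total CDS length
#' is divisible by 3 by construction. Strand is drawn at random per gene.
#' The same config (including seed) always yields the identical set.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{GeneModelSet}.
#' @export
generateGeneModels <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    n <- config@nGenes
    nex <- .sampleRange(config@exonsPerGene, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- sprintf("G%04d", seq_len(n))
    cursor <- 1L + .INTERGENIC_GAP
    rows <- vector("list", n)
    exons <- vector("list", n)
    for (i in seq_len(n)) {
        codons <- .sampleRange(config@exonLength, nex[i])
        w <- 3L * codons
        starts <- integer(nex[i]); ends <- integer(nex[i])
        for (j in seq_len(nex[i])) {
            starts[j] <- cursor
            ends[j] <- cursor + w[j] - 1L
            cursor <- ends[j] + 1L + .INTRON_GAP
        }
        cursor <- cursor - .INTRON_GAP + .INTERGENIC_GAP
        exons[[i]] <- GenomicRanges::GRanges(
            SYNTH_CHROM, IRanges::IRanges(starts, ends), strand = strand[i])
        rows[[i]] <- data.frame(
            gene = genes[i], transcript_id = paste0(genes[i], ".t1"),
            chrom = SYNTH_CHROM, strand = strand[i],
            cds_start = starts[1], cds_end = ends[nex[i]],
            protein_length = sum(codons), stringsAsFactors = FALSE)
    }
    names(exons) <- genes
    methods::new("GeneModelSet", genes = do.call(rbind, rows),
                 exons = GenomicRanges::GRangesList(exons))
}

#' Generate synthetic domain annotations
#'
#' Each domain id receives 1-2 occurrences placed uniformly on genes long
#' enough to hold the drawn length; a domain id may therefore recur on
#' several proteins. Residue intervals always lie within
#' \code{[1, protein_length]}.
#'
#' @param genes a \linkS4class{GeneModelSet}.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A domain annotation \code{data.frame}
#'   (see \code{\link{readDomains}}).
#' @export
generateDomainAnnotations <- function(genes, config) {
    methods::validObject(config)
    set.seed(config@seed + 1L)
    g <- geneTable(genes)
    if (config@domainLength[1] > max(g$protein_length))
        stop("generation error: minimum domain length ",
             config@domainLength[1], " exceeds every protein length")
    ids <- c(sprintf("PF%05d", seq_len(config@nDomainsPfam)),
             sprintf("1.10.%d.%d",
                     10L + (seq_len(config@nDomainsCath) - 1L) %/% 10L,
                     seq_len(config@nDomainsCath)))
    src <- rep(c("PFAM", "CATH"),
               c(config@nDomainsPfam, config@nDomainsCath))
    rows <- list()
    for (d in seq_along(ids)) {
        for (occ in seq_len(sample(1:2, 1))) {
            len <- .sampleRange(config@domainLength, 1L)
            fits <- which(g$protein_length >= len)
            if (!length(fits))
                stop("generation error: domain length ", len,
                     " exceeds every protein length")
            gi <- fits[sample.int(length(fits), 1L)]
            start <- sample.int(g$protein_length[gi] - len + 1L, 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                domain_id = ids[d], source = src[d], gene = g$gene[gi],
                start_res = start, end_res = start + len - 1L,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# strand-oriented spliced CDS genomic positions per gene, concatenated,
# with parallel gene labels
.codingPositions <- function(models) {
    g <- geneTable(models)
    exonTab <- .exonTable(models)
    posL <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
        seg <- .cdsSegments(models, g$gene[i], exonTab)
        posL[[i]] <- unlist(lapply(seq_len(nrow(seg)), function(j) {
            if (seg$strand[1] == "-") seq.int(seg$end[j], seg$start[j])
            else seq.int(seg$start[j], seg$end[j])
        }), use.names = FALSE)
    }
    list(pos = unlist(posL, use.names = FALSE),
         gene = rep(g$gene, lengths(posL)),
         offsets = cumsum(c(0L, lengths(posL)[-nrow(g)])))
}

#' Generate a multi-cancer mutation cohort
#'
#' Background mutations fall uniformly over the coding positions of all
#' gene models; for each planted enrichment \code{(d, f)} the per-position
#' rate inside domain \code{d}'s occurrences is multiplied by \code{f}
#' (weighted mixture sampling, so the fold factor is exact). Per-patient
#' mutation counts are Poisson; the variant class is synonymous with the
#' configured Bernoulli probability, otherwise missense or nonsense (9:1).
#'
#' @param genes a \linkS4class{GeneModelSet}.
#' @param domains domain annotation table.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A mutation \code{data.frame} (see \code{\link{readMutations}}).
#' @export
generateCohort <- function(genes, domains, config) {
    methods::validObject(config)
    planted <- config@plantedEnrichments
    if (length(planted)) {
        unknown <- setdiff(names(planted), domains$domain_id)
        if (length(unknown))
            stop("unknown planted domain id(s): ",
                 paste(unknown, collapse = ", "), "; known ids: ",
                 paste(unique(domains$domain_id), collapse = ", "))
    }
    set.seed(config@seed + 2L)
    univ <- .codingPositions(genes)
    w <- rep(1, length(univ$pos))
    if (length(planted)) {
        g <- geneTable(genes)
        for (d in names(planted)) {
            occ <- domains[domains$domain_id == d, , drop = FALSE]
            for (r in seq_len(nrow(occ))) {
                gi <- match(occ$gene[r], g$gene)
                # residues [a,b] occupy spliced CDS offsets [3a-2, 3b]
                span <- seq.int(3L * occ$start_res[r] - 2L,
                                3L * occ$end_res[r])
                w[univ$offsets[gi] + span] <- planted[[d]]
            }
        }
    }
    cts <- config@cancerTypes
    patientIds <- as.vector(vapply(cts, function(ct)
        sprintf("%s_P%03d", ct, seq_len(config@patientsPerCancer)),
        character(config@patientsPerCancer)))
    patientCt <- rep(cts, each = config@patientsPerCancer)
    counts <- stats::rpois(length(patientIds), config@mutationsPerPatient)
    total <- sum(counts)
    cols <- c("patient_id", "cancer_type", "gene", "chrom", "pos",
              "ref_allele", "alt_allele", "variant_class")
    if (total == 0L) {
        out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
        out$pos <- integer(0)
        return(out)
    }
    draw <- sample.int(length(univ$pos), total, replace = TRUE, prob = w)
    syn <- stats::runif(total) < config@synonymousFraction
    cls <- ifelse(syn, "synonymous",
                  sample(c("missense", "nonsense"), total, replace = TRUE,
                         prob = c(0.9, 0.1)))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, total, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample.int(3L, total,
                                                 replace = TRUE) - 1L) %% 4L
                 + 1L]
    data.frame(patient_id = rep(patientIds, counts),
               cancer_type = rep(patientCt, counts),
               gene = univ$gene[draw], chrom = SYNTH_CHROM,
               pos = univ$pos[draw], ref_allele = ref, alt_allele = alt,
               variant_class = cls, stringsAsFactors = FALSE)
}

#' Generate simple gene-set definitions for a synthetic scenario
#'
#' Builds one grouped set (members partitioned into two groups, exercising
#' the complex-level grouped test) and one ungrouped set, drawn
#' deterministically from the gene list.
#'
#' @param genes a \linkS4class{GeneModelSet}.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A gene-set \code{data.frame} (see \code{\link{readGeneSets}}).
#' @export
generateGeneSets <- function(genes, config) {
    set.seed(config@seed + 3L)
    g <- geneTable(genes)$gene
    k <- min(10L, length(g))
    members <- sort(sample(g, k))
    rbind(
        data.frame(set_name = "grouped_set", gene = members,
                   group = rep(c("grpA", "grpB"), length.out = k),
                   stringsAsFactors = FALSE),
        data.frame(set_name = "flat_set",
                   gene = sort(sample(g, min(5L, length(g)))),
                   group = "", stringsAsFactors = FALSE))
}
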