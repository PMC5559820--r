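#' @import methods
NULL

## closed vocabulary for variant consequence classes (MAF-style)
VARIANT_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift",
                     "inframe_indel", "other")

## domain annotation sources
DOMAIN_SOURCES <- c("PFAM", "CATH")

## label used for the union-of-all-types cohort
PAN_CANCER <- "pan-cancer"

#' SyntheticConfig: parameters of a synthetic multi-cancer scenario
#'
#' Describes a complete synthetic dataset: gene models laid end-to-end on
#' one synthetic chromosome, Pfam-style and CATH-style domain annotations,
#' and per-cancer patient cohorts whose mutations fall uniformly over
#' coding positions except where an enrichment is planted.
#'
#' @slot nGenes number of genes.
#' @slot exonsPerGene integer range (min, max) of exons per gene.
#' @slot exonLength integer range (min, max) of exon length in codons.
#' @slot nDomainsPfam,nDomainsCath number of distinct domain identifiers
#'   per source.
#' @slot domainLength integer range (min, max) of domain length in residues.
#' @slot cancerTypes labels of the simulated cancer types.
#' @slot patientsPerCancer patients per cancer type.
#' @slot mutationsPerPatient Poisson mean of mutations per patient.
#' @slot plantedEnrichments named numeric: fold multiplier (>= 1) per
#'   planted domain id; empty for a pure null scenario.
#' @slot synonymousFraction Bernoulli probability that a mutation is
#'   synonymous (removed by the coding filter downstream).
#' @slot seed integer seed; fixing it makes every generator output
#'   byte-identical across runs.
#' @export
setClass("SyntheticConfig", representation(
    nGenes = "integer",
    exonsPerGene = "integer",
    exonLength = "integer",
    nDomainsPfam = "integer",
    nDomainsCath = "integer",
    domainLength = "integer",
    cancerTypes = "character",
    patientsPerCancer = "integer",
    mutationsPerPatient = "numeric",
    plantedEnrichments = "numeric",
    synonymousFraction = "numeric",
    seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character(0)
    chkRange <- function(x, what) {
        if (length(x) != 2L || any(x < 1L) || x[1] > x[2])
            sprintf("'%s' must be an increasing positive range (min, max)",
                    what)
        else character(0)
    }
    if (object@nGenes < 1L) msg <- c(msg, "'nGenes' must be >= 1")
    msg <- c(msg, chkRange(object@exonsPerGene, "exonsPerGene"),
             chkRange(object@exonLength, "exonLength"),
             chkRange(object@domainLength, "domainLength"))
    if (object@nDomainsPfam < 0L || object@nDomainsCath < 0L)
        msg <- c(msg, "domain counts must be >= 0")
    if (length(object@cancerTypes) < 1L || any(!nzchar(object@cancerTypes)))
        msg <- c(msg, "'cancerTypes' must be non-empty labels")
    if (object@patientsPerCancer < 1L)
        msg <- c(msg, "'patientsPerCancer' must be >= 1")
    if (object@mutationsPerPatient < 0)
        msg <- c(msg, "'mutationsPerPatient' must be >= 0")
    if (length(object@plantedEnrichments) &&
        (is.null(names(object@plantedEnrichments)) ||
         any(object@plantedEnrichments < 1)))
        msg <- c(msg, "'plantedEnrichments' must be named folds >= 1")
    if (object@synonymousFraction < 0 || object@synonymousFraction > 1)
        msg <- c(msg, "'synonymousFraction' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' GeneModelSet: transcript structures for genomic-to-residue mapping
#'
#' One canonical transcript per gene. The \code{genes} table carries gene
#' symbol, transcript id, chromosome, strand, CDS span and protein length;
#' \code{exons} is a \linkS4class{GRangesList} named by gene. The total CDS
#' nucleotide count of each gene must equal 3 x protein length (the stop
#' codon is excluded by convention so residue coordinates align with domain
#' annotations).
#'
#' @slot genes data.frame with columns \code{gene}, \code{transcript_id},
#'   \code{chrom}, \code{strand}, \code{cds_start}, \code{cds_end},
#'   \code{protein_length}.
#' @slot exons \linkS4class{GRangesList}, one element per gene, sorted
#'   non-overlapping exon intervals.
#' @export
setClass("GeneModelSet", representation(
    genes = "data.frame",
    exons = "GRangesList"
))

setValidity("GeneModelSet", function(object) {
    g <- object@genes
    need <- c("gene", "transcript_id", "chrom", "strand",
              "cds_start", "cds_end", "protein_length")
    if (!all(need %in% names(g)))
        return(paste("genes table must have columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(g$gene))
        return("one transcript per gene: duplicated gene symbols")
    if (!setequal(names(object@exons), g$gene))
        return("exons list names must match gene symbols")
    if (!all(g$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    for (i in seq_len(nrow(g))) {
        ex <- object@exons[[g$gene[i]]]
        st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
        if (is.unsorted(st) ||
            (length(ex) > 1L && any(st[-1] <= en[-length(en)])))
            return(sprintf("gene %s: exons must be sorted, non-overlapping",
                           g$gene[i]))
        cds <- IRanges::restrict(IRanges::IRanges(st, en),
                                 g$cds_start[i], g$cds_end[i])
        if (sum(IRanges::width(cds)) != 3L * g$protein_length[i])
            return(sprintf(
                "gene %s: CDS length %d nt != 3 x protein_length (%d)",
                g$gene[i], sum(IRanges::width(cds)), g$protein_length[i]))
    }
    TRUE
})

#' CancerCohort: one cancer type's patients, mutations and domain hits
#'
#' Mutations are post-filter (coding, non-synonymous); \code{hits} holds one
#' row per (mutation, distinct domain id) pair. The pan-cancer cohort is the
#' union of all per-type cohorts and keeps the original per-record cancer
#' type labels.
#'
#' @slot cancerType the cohort label (or \code{"pan-cancer"}).
#' @slot patients patient identifiers.
#' @slot mutations filtered mutation records (data.frame).
#' @slot hits domain-hit table (data.frame).
#' @export
setClass("CancerCohort", representation(
    cancerType = "character",
    patients = "character",
    mutations = "data.frame",
    hits = "data.frame"
))

setValidity("CancerCohort", function(object) {
    if (length(object@cancerType) != 1L || !nzchar(object@cancerType))
        return("'cancerType' must be one non-empty label")
    if (nrow(object@mutations)) {
        if (!all(object@mutations$patient_id %in% object@patients))
            return("every mutation's patient must be in the patient set")
        if (object@cancerType != PAN_CANCER &&
            !all(object@mutations$cancer_type == object@cancerType))
            return("mutation cancer_type inconsistent with cohort label")
    }
    TRUE
})

#' CandidateProfile: per-cancer candidate regions and their derivations
#'
#' Holds the region test results of one cohort for one source (PFAM, CATH
#' or GENE), per-region patient coverage, and the cancer-type-specific
#' region and protein sets filled in by \code{\link{specificRegions}} and
#' \code{\link{specificProteins}}.
#'
#' @slot cancerType cohort label.
#' @slot source one of \code{"PFAM"}, \code{"CATH"}, \code{"GENE"}.
#' @slot results region test table (see \code{\link{testRegion}}).
#' @slot coverage named numeric, percent of patients covered per region.
#' @slot specificRegions regions candidate here and in no other type.
#' @slot specificProteins genes all of whose candidate domains are specific.
#' @export
setClass("CandidateProfile", representation(
    cancerType = "character",
    source = "character",
    results = "data.frame",
    coverage = "numeric",
    specificRegions = "character",
    specificProteins = "character"
))

setValidity("CandidateProfile", function(object) {
    if (!object@source %in% c(DOMAIN_SOURCES, "GENE"))
        return("source must be PFAM, CATH or GENE")
    if (length(object@coverage) &&
        (any(object@coverage < 0) || any(object@coverage > 100)))
        return("coverage percentages must lie in [0, 100]")
    cand <- object@results$region_id[object@results$candidate]
    if (!all(object@specificRegions %in% cand))
        return("specific regions must be candidate regions")
    TRUE
})

#' @describeIn SyntheticConfig-class compact display
#' @param object a \code{SyntheticConfig}
#' @export
setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nGenes, "genes,",
        object@nDomainsPfam, "Pfam +", object@nDomainsCath, "CATH domains,",
        length(object@cancerTypes), "cancer types x",
        object@patientsPerCancer, "patients, seed", object@seed, "\n")
    if (length(object@plantedEnrichments))
        cat("  planted:",
            paste(sprintf("%s x%g", names(object@plantedEnrichments),
                          object@plantedEnrichments), collapse = ", "), "\n")
})

#' @describeIn GeneModelSet-class compact display
#' @param object a \code{GeneModelSet}
#' @export
setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet:", nrow(object@genes), "genes,",
        sum(object@genes$protein_length), "residues total\n")
})

#' @describeIn CancerCohort-class compact display
#' @param object a \code{CancerCohort}
#' @export
setMethod("show", "CancerCohort", function(object) {
    cat("CancerCohort", object@cancerType, ":",
        length(object@patients), "patients,",
        nrow(object@mutations), "mutations,",
        nrow(object@hits), "domain hits\n")
})

#' @describeIn CandidateProfile-class compact display
#' @param object a \code{CandidateProfile}
#' @export
setMethod("show", "CandidateProfile", function(object) {
    cat("CandidateProfile", object@cancerType, "/", object@source, ":",
        sum(object@results$candidate), "candidates of",
        nrow(object@results), "regions;",
        length(object@specificRegions), "specific\n")
})

#' Accessors for MutDomains containers
#'
#' @param x a package container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "GeneModelSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("cancerType", function(x) standardGeneric("cancerType"))
#' @rdname accessors
#' @export
setMethod("cancerType", "CancerCohort", function(x) x@cancerType)
#' @rdname accessors
#' @export
setMethod("cancerType", "CandidateProfile", function(x) x@cancerType)

#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "CancerCohort", function(x) x@patients)

#' @rdname accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @rdname accessors
#' @export
setMethod("mutations", "CancerCohort", function(x) x@mutations)

#' @rdname accessors
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))
#' @rdname accessors
#' @export
setMethod("domainHits", "CancerCohort", function(x) x@hits)

#' @rdname accessors
#' @export
setGeneric("results", function(x) standardGeneric("results"))
#' @rdname accessors
#' @export
setMethod("results", "CandidateProfile", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("regionCoverage", function(x) standardGeneric("regionCoverage"))
#' @rdname accessors
#' @export
setMethod("regionCoverage", "CandidateProfile", function(x) x@coverage)

#' @rdname accessors
#' @export
setGeneric("candidateRegions", function(x) standardGeneric("candidateRegions"))
#' @rdname accessors
#' @export
setMethod("candidateRegions", "CandidateProfile", function(x)
    x@results$region_id[x@results$candidate])
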