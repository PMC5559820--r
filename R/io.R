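## Tabular input/output. All coordinates are 1-based inclusive, on disk and
## in memory (MAF / UniProt convention). Tab-separated, UTF-8, fixed headers.

MUTATION_COLUMNS <- c("patient_id", "cancer_type", "gene", "chrom", "pos",
                      "ref_allele", "alt_allele", "variant_class")
GENEMODEL_COLUMNS <- c("gene", "transcript_id", "chrom", "strand",
                       "exon_starts", "exon_ends", "cds_start", "cds_end",
                       "protein_length")
DOMAIN_COLUMNS <- c("domain_id", "source", "gene", "start_res", "end_res")
GENESET_COLUMNS <- c("set_name", "gene", "group")

.readTsv <- function(path, required) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("format error in ", path, ": missing required column(s) ",
             paste(missing, collapse = ", "))
    df
}

# parse an integer column, reporting 1-based file line numbers (header = 1)
.parseInt <- function(x, col, path, allowEmpty = FALSE) {
    v <- suppressWarnings(as.integer(x))
    bad <- is.na(v) & !(allowEmpty & !nzchar(x))
    if (any(bad))
        stop("record error in ", path, ": unparseable ", col,
             " at line(s) ", paste(which(bad) + 1L, collapse = ", "))
    v
}

.lineErr <- function(bad, path, msg) {
    if (any(bad))
        stop("validation error in ", path, ": ", msg,
             " at line(s) ", paste(which(bad) + 1L, collapse = ", "))
}

#' Read a mutation table (simplified MAF-like TSV)
#'
#' Columns: \code{patient_id}, \code{cancer_type}, \code{gene},
#' \code{chrom}, \code{pos} (1-based genomic), \code{ref_allele},
#' \code{alt_allele} (either may be empty for indels),
#' \code{variant_class} (one of synonymous, missense, nonsense, frameshift,
#' inframe_indel, other). Every record is validated; malformed lines are
#' reported with their file line numbers.
#'
#' @param path TSV file path.
#' @return A validated \code{data.frame} of mutation records.
#' @export
readMutations <- function(path) {
    df <- .readTsv(path, MUTATION_COLUMNS)[MUTATION_COLUMNS]
    df$pos <- .parseInt(df$pos, "pos", path)
    .lineErr(df$pos < 1L, path, "pos must be >= 1")
    .lineErr(!nzchar(df$patient_id), path, "empty patient_id")
    .lineErr(!nzchar(df$cancer_type), path, "empty cancer_type")
    bad <- !df$variant_class %in% VARIANT_CLASSES
    .lineErr(bad, path, paste("variant_class outside {",
             paste(VARIANT_CLASSES, collapse = ", "), "}"))
    rownames(df) <- NULL
    df
}

#' Read gene models (BED12-like TSV) into a GeneModelSet
#'
#' One row per gene/canonical transcript with comma-separated
#' \code{exon_starts} / \code{exon_ends} (1-based inclusive, genomic),
#' the CDS span, and the protein length in residues (stop codon excluded:
#' CDS nucleotides must equal 3 x protein length).
#'
#' @param path TSV file path.
#' @return A \linkS4class{GeneModelSet}.
#' @export
readGeneModels <- function(path) {
    df <- .readTsv(path, GENEMODEL_COLUMNS)[GENEMODEL_COLUMNS]
    df$cds_start <- .parseInt(df$cds_start, "cds_start", path)
    df$cds_end <- .parseInt(df$cds_end, "cds_end", path)
    df$protein_length <- .parseInt(df$protein_length, "protein_length", path)
    exons <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
        st <- suppressWarnings(
            as.integer(strsplit(df$exon_starts[i], ",", fixed = TRUE)[[1]]))
        en <- suppressWarnings(
            as.integer(strsplit(df$exon_ends[i], ",", fixed = TRUE)[[1]]))
        if (anyNA(st) || anyNA(en) || length(st) != length(en))
            stop("record error in ", path, ": malformed exon lists at line ",
                 i + 1L)
        exons[[i]] <- GenomicRanges::GRanges(
            df$chrom[i], IRanges::IRanges(st, en), strand = df$strand[i])
    }
    names(exons) <- df$gene
    genes <- df[, c("gene", "transcript_id", "chrom", "strand",
                    "cds_start", "cds_end", "protein_length")]
    rownames(genes) <- NULL
    methods::new("GeneModelSet", genes = genes,
                 exons = GenomicRanges::GRangesList(exons))
}

#' Read domain annotations (TSV)
#'
#' Columns: \code{domain_id}, \code{source} (PFAM or CATH), \code{gene},
#' \code{start_res}, \code{end_res} (1-based inclusive residues). A domain
#' id may occur on several proteins and several times on one protein. When
#' \code{models} is supplied, residue intervals are checked against each
#' gene's protein length.
#'
#' @param path TSV file path.
#' @param models optional \linkS4class{GeneModelSet} for bound checking.
#' @return A validated \code{data.frame} of domain annotations.
#' @export
readDomains <- function(path, models = NULL) {
    df <- .readTsv(path, DOMAIN_COLUMNS)[DOMAIN_COLUMNS]
    df$start_res <- .parseInt(df$start_res, "start_res", path)
    df$end_res <- .parseInt(df$end_res, "end_res", path)
    bad <- !df$source %in% DOMAIN_SOURCES
    .lineErr(bad, path, "source must be PFAM or CATH")
    bad <- df$start_res < 1L | df$start_res > df$end_res
    .lineErr(bad, path, "require 1 <= start_res <= end_res")
    if (!is.null(models)) {
        g <- geneTable(models)
        plen <- g$protein_length[match(df$gene, g$gene)]
        bad <- !is.na(plen) & df$end_res > plen
        .lineErr(bad, path, "end_res exceeds protein length")
    }
    rownames(df) <- NULL
    df
}

#' Read gene-set definitions (TSV)
#'
#' Columns: \code{set_name}, \code{gene}, \code{group} (optional group
#' label, e.g. a mitochondrial complex; empty when the set is ungrouped).
#'
#' @param path TSV file path.
#' @return A \code{data.frame} of set memberships.
#' @export
readGeneSets <- function(path) {
    df <- .readTsv(path, GENESET_COLUMNS)[GENESET_COLUMNS]
    .lineErr(!nzchar(df$set_name), path, "empty set_name")
    .lineErr(!nzchar(df$gene), path, "empty gene")
    rownames(df) <- NULL
    df
}

#' Write a record table as TSV
#'
#' Deterministic column order (as supplied), header line, UTF-8,
#' tab-separated, no quoting. Writing then reading any of the package's
#' record tables is the identity.
#'
#' @param records a \code{data.frame}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTable <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a GeneModelSet back to the BED12-like TSV dialect
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneModels <- function(models, path) {
    g <- geneTable(models)
    ex <- exonRanges(models)
    df <- data.frame(
        gene = g$gene, transcript_id = g$transcript_id, chrom = g$chrom,
        strand = g$strand,
        exon_starts = vapply(g$gene, function(gg)
            paste(GenomicRanges::start(ex[[gg]]), collapse = ","), ""),
        exon_ends = vapply(g$gene, function(gg)
            paste(GenomicRanges::end(ex[[gg]]), collapse = ","), ""),
        cds_start = g$cds_start, cds_end = g$cds_end,
        protein_length = g$protein_length,
        stringsAsFactors = FALSE)
    writeTable(df, path)
}
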