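## Per-cancer and pan-cancer orchestration: cohorts, domain- and gene-level
## binomial tests, patient coverage, cancer-type specificity, gene-set
## restriction and causal-list comparison.

#' Split filtered mutations into per-cancer cohorts plus pan-cancer
#'
#' One \linkS4class{CancerCohort} per distinct cancer type plus a
#' pan-cancer cohort that is the union of all records and patients; the
#' pan-cancer cohort is analysed downstream as one additional "type".
#' Domain hits are computed once and partitioned.
#'
#' @param records filtered mutation table
#'   (\code{\link{filterCodingNonsynonymous}}).
#' @param models a \linkS4class{GeneModelSet}.
#' @param annotations domain annotation table.
#' @param patientTable optional \code{data.frame(patient_id, cancer_type)}
#'   enumerating all cohort patients (so patients without qualifying
#'   mutations still count in coverage denominators); defaults to the
#'   patients observed in \code{records}.
#' @return Named list of \linkS4class{CancerCohort} (last element
#'   \code{"pan-cancer"}); empty list with a warning on empty input.
#' @export
buildCohorts <- function(records, models, annotations, patientTable = NULL) {
    if (!nrow(records)) {
        warning("no mutation records; returning no cohorts")
        return(list())
    }
    if (is.null(patientTable))
        patientTable <- unique(records[c("patient_id", "cancer_type")])
    hits <- assignToDomains(records, models, annotations)
    types <- sort(unique(patientTable$cancer_type))
    cohorts <- lapply(types, function(ct) {
        sel <- records$cancer_type == ct
        methods::new("CancerCohort", cancerType = ct,
            patients = sort(patientTable$patient_id[
                patientTable$cancer_type == ct]),
            mutations = records[sel, , drop = FALSE],
            hits = hits[hits$cancer_type == ct, , drop = FALSE])
    })
    pan <- methods::new("CancerCohort", cancerType = PAN_CANCER,
                        patients = sort(unique(patientTable$patient_id)),
                        mutations = records, hits = hits)
    stats::setNames(c(cohorts, pan), c(types, PAN_CANCER))
}

#' Test one source's domains for excess mutation in a cohort
#'
#' For each domain id of the source, \eqn{l_i} is the summed residue length
#' of all its occurrences proteome-wide and \eqn{L} the total over all
#' domains of that source; \eqn{n} counts the cohort's hits on that source
#' (one per mutation and domain id) and \eqn{k_i} the hits on domain
#' \eqn{i}. Each domain is then tested against the length-proportional
#' binomial null at the Bonferroni-corrected level \code{alpha / m}.
#'
#' @param cohort a \linkS4class{CancerCohort}.
#' @param annotations domain annotation table (proteome-wide).
#' @param source \code{"PFAM"} or \code{"CATH"}.
#' @param m Bonferroni family size (regions x cohorts in the usual design).
#' @param alpha family-wise level.
#' @return A region test \code{data.frame} (see \code{\link{testRegion}}).
#' @export
testDomains <- function(cohort, annotations, source, m, alpha = 0.05) {
    ann <- annotations[annotations$source == source, , drop = FALSE]
    if (!nrow(ann)) stop("no annotations of source ", source)
    lTab <- tapply(ann$end_res - ann$start_res + 1L, ann$domain_id, sum)
    ids <- names(lTab)
    L <- sum(lTab)
    if (L <= 0) stop("zero total domain length")
    h <- domainHits(cohort)
    h <- h[h$source == source, , drop = FALSE]
    n <- nrow(h)
    k <- integer(length(ids))
    if (n) {
        kt <- table(h$domain_id)
        k[match(names(kt), ids)] <- as.integer(kt)
    }
    testRegion(ids, as.numeric(lTab), L, n, k, m, alpha)
}

#' Test genes (or gene groups) for excess mutation in a cohort
#'
#' \eqn{l_i} is gene \eqn{i}'s coding length in residues and \eqn{L} the
#' total coding length of all modelled protein-coding genes — even when a
#' restricted gene set is tested, the background stays genome-wide while
#' the Bonferroni family size reflects the set. \eqn{n} counts all filtered
#' coding mutations in the cohort and \eqn{k_i} those inside gene \eqn{i}'s
#' CDS. With \code{groups}, member counts and lengths are summed and each
#' group is tested as one region (the complex-level analysis).
#'
#' @param cohort a \linkS4class{CancerCohort}.
#' @param models a \linkS4class{GeneModelSet}.
#' @param geneUniverse genes to test (default all modelled genes); unknown
#'   genes raise an error naming the offenders.
#' @param m Bonferroni family size.
#' @param alpha family-wise level.
#' @param groups optional named character vector mapping each universe gene
#'   to a group label; tests groups instead of genes.
#' @return A region test \code{data.frame}.
#' @export
testGenes <- function(cohort, models, geneUniverse = NULL, m,
                      alpha = 0.05, groups = NULL) {
    g <- geneTable(models)
    if (is.null(geneUniverse)) geneUniverse <- g$gene
    unknown <- setdiff(geneUniverse, g$gene)
    if (length(unknown))
        stop("gene(s) absent from models: ", paste(unknown, collapse = ", "))
    L <- sum(g$protein_length)
    mut <- mutations(cohort)
    n <- nrow(mut)
    l <- g$protein_length[match(geneUniverse, g$gene)]
    k <- integer(length(geneUniverse))
    if (n) {
        kt <- table(mut$gene)
        hit <- match(names(kt), geneUniverse)
        k[hit[!is.na(hit)]] <- as.integer(kt)[!is.na(hit)]
    }
    if (!is.null(groups)) {
        grp <- groups[geneUniverse]
        if (anyNA(grp)) stop("'groups' must cover every universe gene")
        l <- as.numeric(tapply(l, grp, sum))
        k <- as.integer(tapply(k, grp, sum))
        geneUniverse <- sort(unique(unname(grp)))
    }
    testRegion(geneUniverse, as.numeric(l), L, n, k, m, alpha)
}

#' Percent of cohort patients covered by one region
#'
#' A region covers a patient when the patient has at least one mutation
#' inside it: for domains, a domain hit; for genes, a filtered coding
#' mutation in the gene.
#'
#' @param regionId domain id or gene symbol.
#' @param cohort a \linkS4class{CancerCohort}.
#' @param type \code{"domain"} or \code{"gene"}.
#' @return Percent in [0, 100].
#' @export
patientCoverage <- function(regionId, cohort, type = c("domain", "gene")) {
    type <- match.arg(type)
    np <- length(patients(cohort))
    if (!np) stop("cohort has no patients; coverage undefined")
    covered <- if (type == "domain") {
        h <- domainHits(cohort)
        unique(h$patient_id[h$domain_id == regionId])
    } else {
        mu <- mutations(cohort)
        unique(mu$patient_id[mu$gene == regionId])
    }
    100 * length(covered) / np
}

#' Percent of patients covered by any of a set of regions
#'
#' Union coverage: a patient counts once however many listed regions hit
#' them, so the result is at least the maximum single-region coverage and
#' at most their sum.
#'
#' @inheritParams patientCoverage
#' @param regionIds character vector of region ids.
#' @return Percent in [0, 100].
#' @export
cumulativeCoverage <- function(regionIds, cohort,
                               type = c("domain", "gene")) {
    type <- match.arg(type)
    np <- length(patients(cohort))
    if (!np) stop("cohort has no patients; coverage undefined")
    if (!length(regionIds)) return(0)
    covered <- if (type == "domain") {
        h <- domainHits(cohort)
        unique(h$patient_id[h$domain_id %in% regionIds])
    } else {
        mu <- mutations(cohort)
        unique(mu$patient_id[mu$gene %in% regionIds])
    }
    100 * length(covered) / np
}

#' Assemble a CandidateProfile from a cohort's test results
#'
#' Computes per-candidate patient coverage; specificity fields start empty
#' and are filled by \code{\link{specificRegions}} and
#' \code{\link{specificProteins}}.
#'
#' @param cohort a \linkS4class{CancerCohort}.
#' @param res a region test \code{data.frame} for this cohort.
#' @param source \code{"PFAM"}, \code{"CATH"} or \code{"GENE"}.
#' @return A \linkS4class{CandidateProfile}.
#' @export
candidateProfile <- function(cohort, res, source) {
    cand <- res$region_id[res$candidate]
    type <- if (source == "GENE") "gene" else "domain"
    cov <- vapply(cand, patientCoverage, numeric(1), cohort = cohort,
                  type = type)
    methods::new("CandidateProfile", cancerType = cancerType(cohort),
                 source = source, results = res,
                 coverage = if (length(cand)) cov else
                     stats::setNames(numeric(0), character(0)),
                 specificRegions = character(0),
                 specificProteins = character(0))
}

#' Mark regions specific to a single cancer type
#'
#' A region is specific to cancer type \eqn{c} when it is a candidate in
#' \eqn{c} and in no other individual cancer type; the pan-cancer profile
#' is a union of diseases, so it is excluded from the exclusivity count and
#' receives no specific regions itself. Specific sets of distinct types are
#' pairwise disjoint by construction.
#'
#' @param profiles named list of \linkS4class{CandidateProfile}, one per
#'   cohort, all of the same source.
#' @return The list with \code{specificRegions} filled in.
#' @export
specificRegions <- function(profiles) {
    individual <- names(profiles)[names(profiles) != PAN_CANCER]
    candSets <- lapply(profiles[individual], candidateRegions)
    tally <- table(unlist(candSets, use.names = FALSE))
    for (ct in names(profiles)) {
        profiles[[ct]]@specificRegions <- if (ct == PAN_CANCER)
            character(0)
        else {
            cs <- candSets[[ct]]
            cs[tally[cs] == 1L]
        }
        methods::validObject(profiles[[ct]])
    }
    profiles
}

#' Proteins whose candidate domains are all specific to one cancer type
#'
#' A gene qualifies when (a) at least one of its candidate domains carries
#' a mutation in this cohort and (b) every candidate domain annotated on it
#' belongs to this cancer type's specific set.
#'
#' @param profile a \linkS4class{CandidateProfile} with
#'   \code{specificRegions} filled (see \code{\link{specificRegions}}).
#' @param annotations domain annotation table.
#' @param cohort the matching \linkS4class{CancerCohort}.
#' @return The profile with \code{specificProteins} filled in.
#' @export
specificProteins <- function(profile, annotations, cohort) {
    cand <- candidateRegions(profile)
    ann <- annotations[annotations$source == profile@source &
                       annotations$domain_id %in% cand, , drop = FALSE]
    h <- domainHits(cohort)
    keep <- vapply(unique(ann$gene), function(gg) {
        onGene <- unique(ann$domain_id[ann$gene == gg])
        all(onGene %in% profile@specificRegions) &&
            any(h$gene == gg & h$domain_id %in% onGene)
    }, logical(1))
    profile@specificProteins <- sort(unique(ann$gene)[keep])
    methods::validObject(profile)
    profile
}

#' Restrict candidate genes to those containing a candidate domain
#'
#' Keeps the candidate genes that carry at least one domain (of the domain
#' profile's source) which is itself a candidate in the same cancer type —
#' a monotone filter on the candidate gene set.
#'
#' @param geneResults a gene-level region test \code{data.frame}.
#' @param domainProfile the same cancer type's domain
#'   \linkS4class{CandidateProfile}.
#' @param annotations domain annotation table.
#' @return The filtered subset of candidate gene rows.
#' @export
restrictGeneCandidates <- function(geneResults, domainProfile, annotations) {
    candDoms <- candidateRegions(domainProfile)
    ann <- annotations[annotations$source == domainProfile@source &
                       annotations$domain_id %in% candDoms, , drop = FALSE]
    keep <- geneResults$candidate & geneResults$region_id %in% ann$gene
    out <- geneResults[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Compare candidate results against an external causal-gene list
#'
#' For each cancer type (and overall) counts how many listed causal genes
#' have at least one domain annotation of the source, at least one mutation
#' on their domains in the cohort, and at least one candidate domain; each
#' count also as a percentage of the causal genes listed for that type.
#'
#' @param profiles named list of domain \linkS4class{CandidateProfile}.
#' @param cohorts matching named list of \linkS4class{CancerCohort}.
#' @param annotations domain annotation table.
#' @param causal \code{data.frame(gene, cancer_type)} of externally
#'   verified causal genes.
#' @return Summary \code{data.frame}, one row per cancer type plus
#'   \code{"overall"}.
#' @export
compareCausalList <- function(profiles, cohorts, annotations, causal) {
    src <- profiles[[1]]@source
    ann <- annotations[annotations$source == src, , drop = FALSE]
    oneType <- function(genes, profile, cohort) {
        withDom <- genes[genes %in% ann$gene]
        h <- domainHits(cohort)
        withMut <- withDom[vapply(withDom, function(gg)
            any(h$gene == gg & h$source == src), logical(1))]
        cand <- candidateRegions(profile)
        withCand <- withDom[vapply(withDom, function(gg)
            any(ann$domain_id[ann$gene == gg] %in% cand), logical(1))]
        nG <- length(genes)
        pct <- function(x) if (nG) 100 * length(x) / nG else 0
        data.frame(n_causal = nG, with_domain = length(withDom),
                   with_mutated_domain = length(withMut),
                   with_candidate_domain = length(withCand),
                   pct_with_domain = pct(withDom),
                   pct_with_mutated_domain = pct(withMut),
                   pct_with_candidate_domain = pct(withCand))
    }
    types <- names(profiles)[names(profiles) != PAN_CANCER]
    rows <- lapply(types, function(ct) {
        genes <- unique(causal$gene[causal$cancer_type == ct])
        cbind(data.frame(cancer_type = ct), oneType(
            genes, profiles[[ct]], cohorts[[ct]]))
    })
    allGenes <- unique(causal$gene)
    panKey <- if (PAN_CANCER %in% names(profiles)) PAN_CANCER else
        names(profiles)[1]
    rows[[length(rows) + 1L]] <- cbind(
        data.frame(cancer_type = "overall"),
        oneType(allGenes, profiles[[panKey]], cohorts[[panKey]]))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Export candidate regions as a bipartite edge table
#'
#' One row per (cancer type, candidate region) pair with source, patient
#' coverage and the specificity flag — the tabular form of a cancer-to-
#' region bipartite graph. Ordering is deterministic (cancer type, source,
#' region id).
#'
#' @param profiles list of \linkS4class{CandidateProfile}.
#' @return Edge \code{data.frame} (\code{cancer_type}, \code{region_id},
#'   \code{source}, \code{coverage}, \code{specific}).
#' @export
exportBipartite <- function(profiles) {
    rows <- lapply(profiles, function(p) {
        cand <- candidateRegions(p)
        if (!length(cand)) return(NULL)
        data.frame(cancer_type = p@cancerType, region_id = cand,
                   source = p@source,
                   coverage = unname(p@coverage[cand]),
                   specific = cand %in% p@specificRegions,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(cancer_type = character(0),
                          region_id = character(0), source = character(0),
                          coverage = numeric(0), specific = logical(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$cancer_type, out$source, out$region_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
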