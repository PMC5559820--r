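## End-to-end orchestration behind the command-line wrapper
## (inst/scripts/mutdomains.R): simulate / run / overlap / report.

#' Per-family Bonferroni levels for a run-log
#'
#' @param alpha family-wise level.
#' @param m integer vector of family sizes.
#' @param label optional family labels.
#' @return \code{data.frame(family, m, alpha, level)} with
#'   \code{level = alpha / m}.
#' @examples
#' familyLevels(0.05, c(37 * 30, 30 * 6009))
#' @export
familyLevels <- function(alpha, m, label = as.character(m)) {
    data.frame(family = label, m = m, alpha = alpha,
               level = vapply(m, function(mm) bonferroniLevel(alpha, mm),
                              numeric(1)),
               stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates gene models, domain annotations, gene sets and the mutation
#' cohort from one \linkS4class{SyntheticConfig} and writes them in the
#' pipeline's TSV dialects plus a JSON copy of the scenario parameters.
#' Byte-identical across runs for a fixed config.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
pipelineSimulate <- function(config, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    models <- generateGeneModels(config)
    domains <- generateDomainAnnotations(models, config)
    cohort <- generateCohort(models, domains, config)
    sets <- generateGeneSets(models, config)
    paths <- list(
        mutations = file.path(outdir, "mutations.tsv"),
        gene_models = file.path(outdir, "gene_models.tsv"),
        domains = file.path(outdir, "domains.tsv"),
        gene_sets = file.path(outdir, "gene_sets.tsv"),
        scenario = file.path(outdir, "scenario.json"))
    writeTable(cohort, paths$mutations)
    writeGeneModels(models, paths$gene_models)
    writeTable(domains, paths$domains)
    writeTable(sets, paths$gene_sets)
    jsonlite::write_json(list(
        n_genes = config@nGenes, exons_per_gene = config@exonsPerGene,
        exon_length = config@exonLength,
        n_domains_pfam = config@nDomainsPfam,
        n_domains_cath = config@nDomainsCath,
        domain_length = config@domainLength,
        cancer_types = config@cancerTypes,
        patients_per_cancer = config@patientsPerCancer,
        mutations_per_patient = config@mutationsPerPatient,
        planted_enrichments = as.list(config@plantedEnrichments),
        synonymous_fraction = config@synonymousFraction,
        seed = config@seed), paths$scenario, auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

.emptyResults <- function() {
    data.frame(cancer_type = character(0), region_id = character(0),
               l = numeric(0), L = numeric(0), n = integer(0),
               k = integer(0), p = numeric(0), p_upper = numeric(0),
               m = numeric(0), alpha = numeric(0), candidate = logical(0),
               stringsAsFactors = FALSE)
}

#' Run the full candidate-domain / candidate-gene analysis
#'
#' Executes filter, mapping, cohort assembly (per cancer type plus
#' pan-cancer), domain tests for both sources, gene tests, grouped and
#' ungrouped gene-set tests, patient coverage, cancer-type specificity,
#' candidate-gene restriction, optional causal-list comparison, and writes
#' every result as TSV together with a run-log recording \eqn{n}, \eqn{L},
#' \eqn{m} and \eqn{\alpha/m} for every Bonferroni family. Family sizes
#' default to \code{"auto"}: (regions in the tested universe) x (number of
#' cohorts including pan-cancer).
#'
#' @param mutations,geneModels,domains input TSV paths
#'   (\code{\link{readMutations}} etc.).
#' @param geneSets optional gene-set TSV path.
#' @param causal optional causal-list TSV path with columns \code{gene},
#'   \code{cancer_type}.
#' @param alpha family-wise significance level.
#' @param familySize \code{"auto"} or a fixed integer applied to every
#'   family.
#' @param outdir output directory.
#' @return Invisibly, a list with the in-memory objects (cohorts, profiles,
#'   tables) for further inspection.
#' @export
pipelineRun <- function(mutations, geneModels, domains, geneSets = NULL,
                        causal = NULL, alpha = 0.05, familySize = "auto",
                        outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    models <- readGeneModels(geneModels)
    ann <- readDomains(domains, models)
    raw <- readMutations(mutations)
    recs <- filterCodingNonsynonymous(raw, models)
    patientTable <- unique(raw[c("patient_id", "cancer_type")])
    cohorts <- if (nrow(recs))
        buildCohorts(recs, models, ann, patientTable) else list()
    nCoh <- length(cohorts)
    logLines <- character(0)
    famSize <- function(nRegions) {
        if (identical(familySize, "auto")) nRegions * max(nCoh, 1L)
        else as.integer(familySize)
    }
    logFamily <- function(label, n, L, m) {
        lev <- bonferroniLevel(alpha, m)
        logLines <<- c(logLines, sprintf(
            "family=%s n=%d L=%g m=%d alpha=%g alpha_per_test=%.17g",
            label, n, L, as.integer(m), alpha, lev))
    }
    allProfiles <- list()
    domResults <- list()
    for (src in DOMAIN_SOURCES) {
        srcAnn <- ann[ann$source == src, , drop = FALSE]
        if (!nrow(srcAnn) || !nCoh) next
        nRegions <- length(unique(srcAnn$domain_id))
        m <- famSize(nRegions)
        profs <- lapply(cohorts, function(co) {
            res <- testDomains(co, ann, src, m, alpha)
            logFamily(paste0(src, ":", cancerType(co)),
                      res$n[1], res$L[1], m)
            candidateProfile(co, res, src)
        })
        profs <- specificRegions(profs)
        profs <- stats::setNames(lapply(names(profs), function(ct)
            specificProteins(profs[[ct]], ann, cohorts[[ct]])),
            names(profs))
        allProfiles[[src]] <- profs
        domResults[[src]] <- do.call(rbind, lapply(names(profs), function(ct)
            cbind(data.frame(cancer_type = ct), results(profs[[ct]]))))
    }
    for (src in DOMAIN_SOURCES)
        writeTable(if (!is.null(domResults[[src]])) domResults[[src]]
                   else .emptyResults(),
                   file.path(outdir, sprintf("domain_results_%s.tsv", src)))

    # gene-level testing over all modelled genes
    geneProfiles <- list()
    if (nCoh) {
        mGene <- famSize(nrow(geneTable(models)))
        geneProfiles <- lapply(cohorts, function(co) {
            res <- testGenes(co, models, m = mGene, alpha = alpha)
            logFamily(paste0("GENE:", cancerType(co)), res$n[1], res$L[1],
                      mGene)
            candidateProfile(co, res, "GENE")
        })
    }
    geneResTab <- if (length(geneProfiles))
        do.call(rbind, lapply(names(geneProfiles), function(ct)
            cbind(data.frame(cancer_type = ct),
                  results(geneProfiles[[ct]])))) else .emptyResults()
    writeTable(geneResTab, file.path(outdir, "gene_results.tsv"))

    # candidate genes restricted to those containing a candidate domain
    restricted <- list()
    for (src in names(allProfiles))
        for (ct in names(geneProfiles)) {
            r <- restrictGeneCandidates(results(geneProfiles[[ct]]),
                                        allProfiles[[src]][[ct]], ann)
            if (nrow(r))
                restricted[[length(restricted) + 1L]] <-
                    cbind(data.frame(cancer_type = ct, source = src), r)
        }
    writeTable(if (length(restricted)) do.call(rbind, restricted) else
               cbind(data.frame(cancer_type = character(0),
                                source = character(0)), .emptyResults()),
               file.path(outdir, "restricted_gene_candidates.tsv"))

    # gene sets: per set, ungrouped; plus grouped when group labels exist
    setResults <- list()
    if (!is.null(geneSets) && nCoh) {
        sets <- readGeneSets(geneSets)
        for (sn in unique(sets$set_name)) {
            mem <- sets[sets$set_name == sn, , drop = FALSE]
            mem <- mem[mem$gene %in% geneTable(models)$gene, , drop = FALSE]
            if (!nrow(mem)) next
            mSet <- famSize(nrow(mem))
            grouped <- any(nzchar(mem$group))
            groups <- if (grouped)
                stats::setNames(mem$group, mem$gene) else NULL
            mGrp <- if (grouped) famSize(length(unique(mem$group))) else NA
            for (ct in names(cohorts)) {
                res <- testGenes(cohorts[[ct]], models, mem$gene, mSet,
                                 alpha)
                logFamily(paste0("SET:", sn, ":", ct), res$n[1], res$L[1],
                          mSet)
                setResults[[length(setResults) + 1L]] <- cbind(
                    data.frame(set_name = sn, level = "gene",
                               cancer_type = ct), res)
                if (grouped) {
                    resG <- testGenes(cohorts[[ct]], models, mem$gene, mGrp,
                                      alpha, groups = groups)
                    logFamily(paste0("SETGRP:", sn, ":", ct), resG$n[1],
                              resG$L[1], mGrp)
                    setResults[[length(setResults) + 1L]] <- cbind(
                        data.frame(set_name = sn, level = "group",
                                   cancer_type = ct), resG)
                }
            }
        }
    }
    if (length(setResults))
        writeTable(do.call(rbind, setResults),
                   file.path(outdir, "geneset_results.tsv"))

    # bipartite candidate export + cumulative coverage + specific proteins
    flat <- unlist(allProfiles, recursive = FALSE, use.names = FALSE)
    writeTable(exportBipartite(c(flat, unname(geneProfiles))),
               file.path(outdir, "candidates_bipartite.tsv"))
    covRows <- list()
    spRows <- list()
    for (src in names(allProfiles))
        for (ct in names(allProfiles[[src]])) {
            p <- allProfiles[[src]][[ct]]
            covRows[[length(covRows) + 1L]] <- data.frame(
                cancer_type = ct, source = src,
                n_candidates = length(candidateRegions(p)),
                cumulative_coverage = cumulativeCoverage(
                    candidateRegions(p), cohorts[[ct]]),
                stringsAsFactors = FALSE)
            if (length(p@specificProteins))
                spRows[[length(spRows) + 1L]] <- data.frame(
                    cancer_type = ct, source = src,
                    gene = p@specificProteins, stringsAsFactors = FALSE)
        }
    writeTable(if (length(covRows)) do.call(rbind, covRows) else
               data.frame(cancer_type = character(0), source = character(0),
                          n_candidates = integer(0),
                          cumulative_coverage = numeric(0)),
               file.path(outdir, "coverage_summary.tsv"))
    writeTable(if (length(spRows)) do.call(rbind, spRows) else
               data.frame(cancer_type = character(0), source = character(0),
                          gene = character(0)),
               file.path(outdir, "specific_proteins.tsv"))

    causalTab <- NULL
    if (!is.null(causal) && length(allProfiles) && nCoh) {
        causalDf <- .readTsv(causal, c("gene", "cancer_type"))
        src <- names(allProfiles)[1]
        causalTab <- compareCausalList(allProfiles[[src]], cohorts, ann,
                                       causalDf)
        writeTable(causalTab, file.path(outdir, "causal_comparison.tsv"))
    }
    writeLines(logLines, file.path(outdir, "run_log.txt"))
    invisible(list(models = models, annotations = ann, records = recs,
                   cohorts = cohorts, domainProfiles = allProfiles,
                   geneProfiles = geneProfiles, causal = causalTab,
                   logLines = logLines))
}

#' Write the per-protein Pfam/CATH overlap table
#'
#' @param domains domain annotation TSV path.
#' @param outdir output directory.
#' @return Invisibly, the overlap \code{data.frame} (also written to
#'   \code{overlap.tsv}); the protein-averaged percentages go to
#'   \code{overlap_summary.tsv}.
#' @export
pipelineOverlap <- function(domains, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ann <- readDomains(domains)
    tab <- overlapTable(ann)
    writeTable(tab, file.path(outdir, "overlap.tsv"))
    if (nrow(tab)) {
        avg <- averageOverlap(tab)
        writeTable(data.frame(mean_pct_of_cath = avg[["mean_pct_of_cath"]],
                              mean_pct_of_pfam = avg[["mean_pct_of_pfam"]],
                              n_proteins = nrow(tab)),
                   file.path(outdir, "overlap_summary.tsv"))
    }
    invisible(tab)
}

#' Write per-cancer prevalence and variant-class summaries
#'
#' Mirrors the usual cohort-description table: per cancer type (and
#' pan-cancer) the number of patients, total mutations, coding
#' non-synonymous mutations, and mutations hitting Pfam and CATH domains;
#' plus a variant-class frequency table of the raw input.
#'
#' @inheritParams pipelineRun
#' @return Invisibly, the summary \code{data.frame} (also written to
#'   \code{report.tsv}; class frequencies to
#'   \code{variant_class_summary.tsv}).
#' @export
pipelineReport <- function(mutations, geneModels, domains, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    models <- readGeneModels(geneModels)
    ann <- readDomains(domains, models)
    raw <- readMutations(mutations)
    recs <- filterCodingNonsynonymous(raw, models)
    cohorts <- if (nrow(recs))
        buildCohorts(recs, models, ann,
                     unique(raw[c("patient_id", "cancer_type")])) else list()
    rows <- lapply(cohorts, function(co) {
        ct <- cancerType(co)
        h <- domainHits(co)
        data.frame(cancer_type = ct,
                   patients = length(patients(co)),
                   somatic_mutations = if (ct == PAN_CANCER) nrow(raw) else
                       sum(raw$cancer_type == ct),
                   coding_nonsyn_mutations = nrow(mutations(co)),
                   mutations_on_pfam_domains =
                       length(unique(h$mut_index[h$source == "PFAM"])),
                   mutations_on_cath_domains =
                       length(unique(h$mut_index[h$source == "CATH"])),
                   stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cancer_type = character(0), patients = integer(0),
                   somatic_mutations = integer(0),
                   coding_nonsyn_mutations = integer(0),
                   mutations_on_pfam_domains = integer(0),
                   mutations_on_cath_domains = integer(0))
    rownames(tab) <- NULL
    writeTable(tab, file.path(outdir, "report.tsv"))
    cls <- as.data.frame(table(factor(raw$variant_class,
                                      levels = VARIANT_CLASSES)),
                         stringsAsFactors = FALSE)
    names(cls) <- c("variant_class", "count")
    cls$fraction <- if (nrow(raw)) cls$count / nrow(raw) else 0
    writeTable(cls, file.path(outdir, "variant_class_summary.tsv"))
    invisible(tab)
}
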