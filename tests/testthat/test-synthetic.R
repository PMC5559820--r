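# The synthetic scenario generator: determinism, structural invariants,
# uniformity of the background, and planted-enrichment behaviour.

test_that("invalid configurations are rejected naming the field", {
    expect_error(syntheticConfig(nGenes = 0), "nGenes")
    expect_error(syntheticConfig(exonLength = c(10, 5)), "exonLength")
    expect_error(syntheticConfig(patientsPerCancer = 0),
                 "patientsPerCancer")
    expect_error(syntheticConfig(plantedEnrichments = c(D = 0.5)),
                 "plantedEnrichments")
    expect_error(syntheticConfig(synonymousFraction = 1.2),
                 "synonymousFraction")
})

test_that("a single-exon single-gene config gives the stated protein", {
    cfg <- syntheticConfig(nGenes = 1, exonsPerGene = c(1, 1),
                           exonLength = c(30, 30), seed = 3)
    m <- generateGeneModels(cfg)
    g <- geneTable(m)
    expect_identical(nrow(g), 1L)
    expect_identical(g$protein_length, 30L)
    expect_identical(g$cds_end - g$cds_start + 1L, 90L)
})

test_that("the same seed reproduces models, domains and cohort exactly", {
    cfg <- syntheticConfig(seed = 7)
    m1 <- generateGeneModels(cfg); m2 <- generateGeneModels(cfg)
    expect_identical(geneTable(m1), geneTable(m2))
    d1 <- generateDomainAnnotations(m1, cfg)
    d2 <- generateDomainAnnotations(m2, cfg)
    expect_identical(d1, d2)
    c1 <- generateCohort(m1, d1, cfg)
    c2 <- generateCohort(m2, d2, cfg)
    expect_identical(c1, c2)
})

test_that("exon intervals never overlap, within or between genes", {
    cfg <- syntheticConfig(seed = 7)
    m <- generateGeneModels(cfg)
    # independent brute-force pairwise sweep over every exon interval
    ex <- as.data.frame(unlist(exonRanges(m)))
    n <- nrow(ex)
    for (i in seq_len(n - 1))
        expect_true(all(ex$start[(i + 1):n] > ex$end[i] |
                        ex$end[(i + 1):n] < ex$start[i]),
                    label = sprintf("exon %d overlaps a later exon", i))
})

test_that("domain annotations honour residue bounds on every protein", {
    cfg <- syntheticConfig(domainLength = c(10, 10), seed = 5)
    m <- generateGeneModels(cfg)
    ann <- generateDomainAnnotations(m, cfg)
    expect_true(all(ann$end_res - ann$start_res + 1L == 10L))
    plen <- geneTable(m)$protein_length[match(ann$gene, geneTable(m)$gene)]
    expect_true(all(ann$start_res >= 1L & ann$end_res <= plen))
    # impossible domain length errors out
    tiny <- syntheticConfig(nGenes = 2, exonsPerGene = c(1, 1),
                            exonLength = c(10, 10),
                            domainLength = c(500, 600), seed = 5)
    mt <- generateGeneModels(tiny)
    expect_error(generateDomainAnnotations(mt, tiny),
                 "exceeds every protein")
})

test_that("zero mean mutations yields an empty, well-typed cohort", {
    cfg <- syntheticConfig(nGenes = 3, mutationsPerPatient = 0, seed = 2)
    m <- generateGeneModels(cfg)
    ann <- generateDomainAnnotations(m, cfg)
    mu <- generateCohort(m, ann, cfg)
    expect_identical(nrow(mu), 0L)
    expect_identical(names(mu),
                     c("patient_id", "cancer_type", "gene", "chrom", "pos",
                       "ref_allele", "alt_allele", "variant_class"))
})

test_that("every generated record is a coding position of its own gene", {
    cfg <- syntheticConfig(nGenes = 8, seed = 9)
    m <- generateGeneModels(cfg)
    ann <- generateDomainAnnotations(m, cfg)
    mu <- generateCohort(m, ann, cfg)
    for (g in unique(mu$gene)) {
        res <- genomicToResidue(mu$pos[mu$gene == g], m, g)
        expect_false(anyNA(res))
    }
    expect_true(all(mu$ref_allele != mu$alt_allele))
    expect_true(all(mu$variant_class %in%
                    c("synonymous", "missense", "nonsense")))
})

test_that("unplanted cohorts are uniform over coding positions", {
    # chi-square over 10 equal bins of the coding universe, 10 seeds,
    # never rejected at the 0.001 level
    for (s in 1:10) {
        cfg <- syntheticConfig(nGenes = 20, exonsPerGene = c(1, 1),
                               exonLength = c(50, 50),
                               domainLength = c(20, 40),
                               patientsPerCancer = 25,
                               mutationsPerPatient = 40, seed = 100 + s)
        m <- generateGeneModels(cfg)
        ann <- generateDomainAnnotations(m, cfg)
        mu <- generateCohort(m, ann, cfg)
        # map genomic positions to a 0-based coding index via gene offsets
        g <- geneTable(m)
        widths <- 3L * g$protein_length
        offs <- cumsum(c(0L, widths[-nrow(g)]))
        gi <- match(mu$gene, g$gene)
        idx <- offs[gi] + (mu$pos - g$cds_start[gi])
        bins <- cut(idx, breaks = seq(0, sum(widths), length.out = 11),
                    include.lowest = TRUE)
        pval <- suppressWarnings(chisq.test(table(bins))$p.value)
        expect_gt(pval, 0.001)
    }
})

test_that("a strongly planted domain receives far more than its uniform
           share", {
    cfg <- syntheticConfig(nGenes = 20, exonsPerGene = c(1, 1),
                           exonLength = c(100, 100),
                           nDomainsPfam = 10, nDomainsCath = 0,
                           domainLength = c(50, 50),
                           patientsPerCancer = 50,
                           mutationsPerPatient = 50,
                           plantedEnrichments = c(PF00001 = 100),
                           seed = 21)
    m <- generateGeneModels(cfg)
    ann <- generateDomainAnnotations(m, cfg)
    mu <- generateCohort(m, ann, cfg)
    occ <- ann[ann$domain_id == "PF00001", ]
    inPlanted <- 0L
    for (r in seq_len(nrow(occ))) {
        sel <- mu$gene == occ$gene[r]
        res <- genomicToResidue(mu$pos[sel], m, occ$gene[r])
        inPlanted <- inPlanted +
            sum(res >= occ$start_res[r] & res <= occ$end_res[r])
    }
    lPlanted <- sum(occ$end_res - occ$start_res + 1L)
    expected <- nrow(mu) * lPlanted / sum(geneTable(m)$protein_length)
    expect_gt(inPlanted, 5 * expected)
    # planting an unknown id is an error that lists the known ids
    bad <- syntheticConfig(plantedEnrichments = c(NOPE = 10), seed = 21)
    expect_error(generateCohort(m, ann, bad), "unknown planted domain")
})

test_that("a planted id is wildly over-represented across seeds", {
    # fold 100 on a 50-residue domain among 2000 coding residues:
    # the planted count must exceed its uniform expectation in every seed
    wins <- 0L
    for (s in 1:10) {
        cfg <- syntheticConfig(nGenes = 20, exonsPerGene = c(1, 1),
                               exonLength = c(100, 100),
                               nDomainsPfam = 5, nDomainsCath = 0,
                               domainLength = c(50, 50),
                               patientsPerCancer = 25,
                               mutationsPerPatient = 40,
                               plantedEnrichments = c(PF00002 = 100),
                               seed = 300 + s)
        m <- generateGeneModels(cfg)
        ann <- generateDomainAnnotations(m, cfg)
        mu <- generateCohort(m, ann, cfg)
        occ <- ann[ann$domain_id == "PF00002", ]
        cnt <- 0L
        for (r in seq_len(nrow(occ))) {
            res <- genomicToResidue(mu$pos[mu$gene == occ$gene[r]], m,
                                    occ$gene[r])
            cnt <- cnt + sum(res >= occ$start_res[r] &
                             res <= occ$end_res[r])
        }
        lP <- sum(occ$end_res - occ$start_res + 1L)
        if (cnt > nrow(mu) * lP / sum(geneTable(m)$protein_length))
            wins <- wins + 1L
    }
    expect_identical(wins, 10L)
})
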