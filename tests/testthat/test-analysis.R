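# Cohort assembly, domain/gene testing, coverage, specificity, exports.

# shared fixture: two genes, two cancer types, hand-placed mutations
analysisFixture <- function() {
    m <- makeModels(list(
        GA = list(strand = "+", exons = cbind(101L, 400L),
                  cds = c(101L, 400L)),    # 100 residues
        GB = list(strand = "+", exons = cbind(1001L, 1600L),
                  cds = c(1001L, 1600L))))  # 200 residues
    ann <- data.frame(
        domain_id = c("DA", "DB", "DB"),
        source = c("PFAM", "PFAM", "PFAM"),
        gene = c("GA", "GB", "GB"),
        start_res = c(1L, 1L, 150L), end_res = c(50L, 100L, 200L),
        stringsAsFactors = FALSE)
    posOfRes <- function(first, r) first + 3L * (r - 1L)
    recs <- rbind(
        mutRec("GA", posOfRes(101L, 10), "P1", "CT1"),
        mutRec("GA", posOfRes(101L, 20), "P2", "CT1"),
        mutRec("GA", posOfRes(101L, 90), "P3", "CT1"),  # outside DA
        mutRec("GB", posOfRes(1001L, 50), "P4", "CT2"),
        mutRec("GB", posOfRes(1001L, 60), "P4", "CT2"),
        mutRec("GB", posOfRes(1001L, 160), "P5", "CT2"),
        mutRec("GB", posOfRes(1001L, 170), "P6", "CT2"),
        mutRec("GB", posOfRes(1001L, 120), "P7", "CT2"))  # outside DB
    list(models = m, ann = ann, recs = recs)
}

test_that("cohorts split by cancer type and pan-cancer is their union", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    expect_identical(names(co), c("CT1", "CT2", "pan-cancer"))
    expect_identical(length(patients(co$CT1)), 3L)
    expect_identical(length(patients(co$CT2)), 4L)
    expect_identical(length(patients(co[["pan-cancer"]])), 7L)
    expect_identical(nrow(mutations(co[["pan-cancer"]])), nrow(fx$recs))
    # pan-cancer hit count per region = sum of per-cancer counts
    panK <- table(domainHits(co[["pan-cancer"]])$domain_id)
    sumK <- table(c(domainHits(co$CT1)$domain_id,
                    domainHits(co$CT2)$domain_id))
    expect_identical(panK, sumK)
    # a single cancer type: pan-cancer equals it in content
    one <- buildCohorts(fx$recs[1:3, ], fx$models, fx$ann)
    expect_identical(mutations(one[["pan-cancer"]]), mutations(one$CT1))
    expect_warning(buildCohorts(fx$recs[0, ], fx$models, fx$ann),
                   "no mutation")
})

test_that("domain test uses summed occurrence lengths and in-universe
           counts", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    res <- testDomains(co[["pan-cancer"]], fx$ann, "PFAM", m = 6)
    expect_setequal(res$region_id, c("DA", "DB"))
    # l: DA = 50, DB = 100 + 51; L their sum; n = hits in universe
    expect_equal(res$l[res$region_id == "DA"], 50)
    expect_equal(res$l[res$region_id == "DB"], 151)
    expect_equal(unique(res$L), 201)
    expect_identical(unique(res$n), 6L)   # 2 in DA + 4 in DB
    expect_identical(res$k[res$region_id == "DB"], 4L)
    expect_error(testDomains(co$CT1, fx$ann, "CATH", m = 1),
                 "no annotations")
})

test_that("a single-domain universe is degenerate and never flagged", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann[1, ])
    res <- testDomains(co[["pan-cancer"]], fx$ann[1, ], "PFAM", m = 1)
    expect_equal(res$p, 1)
    expect_equal(res$p_upper, 1)
    expect_false(res$candidate)
})

test_that("gene test keeps a genome-wide background for restricted
           universes and supports grouping", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    res <- testGenes(co[["pan-cancer"]], fx$models, m = 6)
    expect_equal(unique(res$L), 300)
    expect_identical(res$k[res$region_id == "GA"], 3L)
    expect_identical(res$k[res$region_id == "GB"], 5L)
    # restricted universe: same L, only the named gene tested
    resA <- testGenes(co[["pan-cancer"]], fx$models, "GA", m = 3)
    expect_equal(unique(resA$L), 300)
    expect_identical(nrow(resA), 1L)
    # grouping sums member lengths and counts
    grp <- testGenes(co[["pan-cancer"]], fx$models, c("GA", "GB"), m = 3,
                     groups = c(GA = "cplx", GB = "cplx"))
    expect_equal(grp$l, 300)
    expect_identical(grp$k, 8L)
    expect_error(testGenes(co$CT1, fx$models, c("GA", "NOPE"), m = 1),
                 "NOPE")
    # zero-count genes are never candidates
    res0 <- testGenes(co$CT1, fx$models, "GB", m = 1)
    expect_identical(res0$k, 0L)
    expect_false(res0$candidate)
})

test_that("patient coverage counts covered patients out of all patients", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    # DB covers P4, P5, P6 of CT2's four patients
    expect_equal(patientCoverage("DB", co$CT2), 75)
    expect_equal(patientCoverage("DA", co$CT2), 0)
    expect_equal(patientCoverage("DA", co$CT1), 100 * 2 / 3)
    # gene-level coverage counts any coding mutation in the gene
    expect_equal(patientCoverage("GB", co$CT2, type = "gene"), 100)
    # a patient table with uncovered patients lowers the denominator base
    pt <- rbind(unique(fx$recs[c("patient_id", "cancer_type")]),
                data.frame(patient_id = "P8", cancer_type = "CT1"))
    co2 <- buildCohorts(fx$recs, fx$models, fx$ann, patientTable = pt)
    expect_equal(patientCoverage("DA", co2$CT1), 50)
})

test_that("cumulative coverage is a union, bounded by single coverages", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    expect_equal(cumulativeCoverage(character(0), co$CT2), 0)
    both <- cumulativeCoverage(c("DA", "DB"), co$CT2)
    expect_gte(both, patientCoverage("DB", co$CT2))
    expect_lte(both, patientCoverage("DA", co$CT2) +
                     patientCoverage("DB", co$CT2))
    expect_equal(both, 75)  # union over CT2: still P4, P5, P6
})

test_that("specific regions are candidates in exactly one individual
           cancer type, disjoint across types", {
    mk <- function(ct, ids, cand) {
        res <- data.frame(region_id = ids, l = 1, L = 10, n = 5,
                          k = 1, p = 0.1, p_upper = 0.01, m = 1,
                          alpha = 0.05, candidate = cand)
        methods::new("CandidateProfile", cancerType = ct, source = "PFAM",
                     results = res, coverage = numeric(0),
                     specificRegions = character(0),
                     specificProteins = character(0))
    }
    profs <- list(
        CT1 = mk("CT1", c("D1", "D2"), c(TRUE, TRUE)),
        CT2 = mk("CT2", c("D2", "D3"), c(TRUE, TRUE)),
        "pan-cancer" = mk("pan-cancer", c("D1", "D2", "D3"),
                          c(TRUE, TRUE, TRUE)))
    out <- specificRegions(profs)
    expect_identical(out$CT1@specificRegions, "D1")
    expect_identical(out$CT2@specificRegions, "D3")
    expect_identical(out[["pan-cancer"]]@specificRegions, character(0))
    # pairwise disjoint, exhaustively
    sets <- lapply(out, function(p) p@specificRegions)
    for (a in seq_along(sets))
        for (b in seq_along(sets))
            if (a != b)
                expect_length(intersect(sets[[a]], sets[[b]]), 0)
})

test_that("specific proteins require all candidate domains specific and
           at least one mutated", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    res <- testDomains(co$CT2, fx$ann, "PFAM", m = 1)
    res$candidate <- res$region_id %in% c("DA", "DB")  # force for fixture
    prof <- candidateProfile(co$CT2, res, "PFAM")
    prof@specificRegions <- "DB"
    # GB carries only DB (specific, mutated in CT2) -> qualifies
    # GA carries DA, not specific -> excluded
    prof <- specificProteins(prof, fx$ann, co$CT2)
    expect_identical(prof@specificProteins, "GB")
    # shared candidate on the same gene disqualifies it
    ann2 <- rbind(fx$ann, data.frame(domain_id = "DA", source = "PFAM",
                                     gene = "GB", start_res = 150L,
                                     end_res = 160L))
    co2 <- buildCohorts(fx$recs, fx$models, ann2)
    prof2 <- candidateProfile(co2$CT2, res, "PFAM")
    prof2@specificRegions <- "DB"
    prof2 <- specificProteins(prof2, ann2, co2$CT2)
    expect_identical(prof2@specificProteins, character(0))
})

test_that("candidate genes are restricted to those holding a candidate
           domain", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    gres <- testGenes(co[["pan-cancer"]], fx$models, m = 6)
    gres$candidate <- TRUE  # fixture: treat both as candidates
    dres <- testDomains(co[["pan-cancer"]], fx$ann, "PFAM", m = 6)
    dres$candidate <- dres$region_id == "DB"  # only GB's domain
    dprof <- candidateProfile(co[["pan-cancer"]], dres, "PFAM")
    kept <- restrictGeneCandidates(gres, dprof, fx$ann)
    expect_identical(kept$region_id, "GB")
    # monotone: output is a subset of the candidate genes
    expect_true(all(kept$region_id %in% gres$region_id[gres$candidate]))
    dres$candidate <- FALSE
    dprof0 <- candidateProfile(co[["pan-cancer"]], dres, "PFAM")
    expect_identical(nrow(restrictGeneCandidates(gres, dprof0, fx$ann)), 0L)
})

test_that("causal-list comparison counts domains, mutations and
           candidates per type", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    mkProf <- function(ct) {
        res <- testDomains(co[[ct]], fx$ann, "PFAM", m = 1)
        res$candidate <- res$region_id == "DB"
        candidateProfile(co[[ct]], res, "PFAM")
    }
    profs <- stats::setNames(lapply(names(co), mkProf), names(co))
    causal <- data.frame(gene = c("GA", "GB", "GZ"),
                         cancer_type = c("CT1", "CT2", "CT2"))
    tab <- compareCausalList(profs, co, fx$ann, causal)
    ct2 <- tab[tab$cancer_type == "CT2", ]
    expect_identical(ct2$n_causal, 2L)          # GB, GZ
    expect_identical(ct2$with_domain, 1L)       # GB annotated
    expect_identical(ct2$with_mutated_domain, 1L)
    expect_identical(ct2$with_candidate_domain, 1L)
    expect_equal(ct2$pct_with_candidate_domain, 50)
    # empty causal list -> zero rows of zeros
    tab0 <- compareCausalList(profs, co, fx$ann,
                              causal[0, , drop = FALSE])
    expect_true(all(tab0$n_causal == 0L))
    expect_true(all(tab0$pct_with_domain == 0))
})

test_that("bipartite export has one edge per candidate with deterministic
           order and round-trips", {
    fx <- analysisFixture()
    co <- buildCohorts(fx$recs, fx$models, fx$ann)
    profs <- lapply(names(co), function(ct) {
        res <- testDomains(co[[ct]], fx$ann, "PFAM", m = 1)
        res$candidate <- res$k > 0
        candidateProfile(co[[ct]], res, "PFAM")
    })
    edges <- exportBipartite(profs)
    expect_identical(nrow(edges), sum(vapply(profs, function(p)
        length(candidateRegions(p)), integer(1))))
    expect_identical(edges, exportBipartite(rev(profs)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeTable(edges, f)
    back <- utils::read.delim(f, stringsAsFactors = FALSE)
    expect_identical(back$region_id, edges$region_id)
    expect_identical(back$specific, edges$specific)
})
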