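specTree <- function() GeneTree(ape::read.tree(text = paste0(
    "((Hydra@g1@t1:0.0001,Hydra@g2@t2:0.0001):0.5,",
    "(Hydra@g3@t3:0.3,Nanomia@g1@t9:0.3):0.2);")), id = "T1")

test_that("subtree total lengths are clade edge sums", {
    cherry <- GeneTree(ape::read.tree(text = "(a@g1@t1:0.1,a@g2@t2:0.2);"))
    expect_equal(subtreeLengths(cherry)$totalLength, 0.3)

    g <- GeneTree(ape::read.tree(
        text = "((a@g1@t1:0.1,a@g2@t2:0.2):0.3,b@g1@t3:0.4);"))
    recs <- subtreeLengths(g)
    expect_equal(sort(recs$totalLength), c(0.3, 1.0))

    # stem convention is switchable; the root has no stem
    recsS <- subtreeLengths(g, includeStem = TRUE)
    expect_equal(sort(recsS$totalLength), c(0.6, 1.0))
})

test_that("subtree lengths match the clade-extraction oracle on random trees", {
    withr::local_seed(42)
    for (k in seq_len(10L)) {
        g <- randGeneTree(50L)
        phy <- phyloTree(g)
        recs <- subtreeLengths(g)
        expect_equal(nrow(recs), phy$Nnode)
        for (i in seq_len(nrow(recs))) {
            expect_equal(recs$totalLength[i],
                         oracleSubtreeLength(phy, recs$node[i]))
        }
        # monotone under containment: parent >= child
        st <- stats::setNames(recs$totalLength, recs$node)
        internal <- phy$edge[, 2L] > length(phy$tip.label)
        expect_true(all(st[as.character(phy$edge[internal, 1L])] >=
                        st[as.character(phy$edge[internal, 2L])]))
    }
})

test_that("flagging groups same-species genes under the length threshold", {
    plan <- flagCandidates(list(specTree()), threshold = 0.0005)
    pt <- planTable(plan)
    expect_equal(sort(pt$gene), c("g1", "g2"))
    expect_equal(unique(pt$species), "Hydra")
    expect_equal(length(unique(pt$groupId)), 1L)
    expect_equal(unique(pt$triggerLength), 0.0002)

    expect_equal(nrow(planTable(flagCandidates(list(specTree()),
                                               threshold = 1e-6))), 0L)
})

test_that("merge groups union transitively across trees", {
    t1 <- GeneTree(ape::read.tree(text =
        "((A@g1@t1:1e-5,A@g2@t2:1e-5):0.5,B@g9@t3:0.5);"), id = "T1")
    t2 <- GeneTree(ape::read.tree(text =
        "((A@g2@t2:1e-5,A@g3@t4:1e-5):0.5,B@g9@t5:0.5);"), id = "T2")
    plan <- flagCandidates(list(t1, t2), threshold = 1e-3)
    expect_true(sameGroupSets(planGroups(plan),
                              list(c("A|g1", "A|g2", "A|g3"))))
    expect_true(sameGroupSets(planGroups(plan),
                              oracleFlag(list(t1, t2), 1e-3)))
})

test_that("flagging is monotone in the threshold and never crosses species", {
    withr::local_seed(17)
    for (k in seq_len(20L)) {
        g <- randGeneTree(20L, nspecies = 2L,
                          lengths = stats::runif(38L, 0, 0.01))
        p1 <- flagCandidates(list(g), threshold = 0.003)
        p2 <- flagCandidates(list(g), threshold = 0.01)
        expect_true(validObject(p1, complete = TRUE))  # incl. species safety
        # every pair merged at the smaller threshold is merged at the larger
        mergedPairs <- function(plan) {
            grp <- planGroups(plan)
            unlist(lapply(grp, function(v)
                apply(utils::combn(v, 2L), 2L, paste, collapse = "+")))
        }
        expect_true(all(mergedPairs(p1) %in% mergedPairs(p2)))
    }
})

test_that("applying a plan merges transcripts and is idempotent", {
    cat0 <- TranscriptCatalog(sprintf("t%d", 1:6),
                              c("g1", "g1", "g2", "g2", "g2", "g3"),
                              rep("Hydra", 6))
    plan <- flagCandidates(list(GeneTree(ape::read.tree(text =
        "((Hydra@g1@t1:1e-5,Hydra@g2@t3:1e-5):0.5,Hydra@g3@t6:0.5);"))),
        threshold = 1e-3)
    out <- applyPlan(cat0, plan)
    tb <- catalogTable(out)
    expect_equal(sum(tb$gene == "g1"), 5L)       # 2 + 3 transcripts merged
    expect_setequal(tb$transcript, sprintf("t%d", 1:6))  # conservation
    expect_equal(tb$gene[tb$transcript == "t6"], "g3")   # untouched row

    # idempotence and empty-plan identity
    expect_equal(catalogTable(applyPlan(out, plan)), tb)
    empty <- flagCandidates(list(GeneTree(ape::read.tree(text =
        "(Hydra@g1@t1:0.5,Hydra@g2@t3:0.5);"))), threshold = 1e-6)
    expect_identical(catalogTable(applyPlan(cat0, empty)),
                     catalogTable(cat0))

    # unknown gene in the plan is an error naming the gene
    catX <- TranscriptCatalog("t1", "gX", "Hydra")
    expect_error(applyPlan(catX, plan), "g1|g2")
})

test_that("plan application conserves transcripts on random inputs", {
    withr::local_seed(23)
    for (k in seq_len(10L)) {
        genes <- sprintf("g%02d", 1:12)
        cat0 <- TranscriptCatalog(sprintf("t%03d", 1:40),
                                  sample(genes, 40, replace = TRUE),
                                  "spA")
        present <- unique(catalogTable(cat0)$gene)
        pick <- sample(present, min(4L, length(present)))
        tb <- data.frame(groupId = "m0001", species = "spA", gene = pick,
                         triggerTree = "T1", triggerLength = 1e-5)
        plan <- methods::new("ReassignmentPlan", table = tb, threshold = 1e-4)
        out <- applyPlan(cat0, plan)
        expect_setequal(catalogTable(out)$transcript,
                        catalogTable(cat0)$transcript)
        expect_equal(catalogTable(applyPlan(out, plan)), catalogTable(out))
        merged <- catalogTable(out)$gene[catalogTable(cat0)$gene %in% pick]
        expect_equal(unique(merged), min(pick))
    }
})

test_that("exemplar selection returns the longest transcript", {
    cat0 <- TranscriptCatalog(c("t1", "t2", "t9"), c("g1", "g1", "g1"),
                              rep("A", 3), c(300, 500, 300))
    expect_equal(selectExemplar(cat0, "g1"), "t2")
    catT <- TranscriptCatalog(c("t1", "t9"), c("g1", "g1"), c("A", "A"),
                              c(300, 300))
    expect_equal(selectExemplar(catT, "g1"), "t1")   # tie -> smallest id
    catN <- TranscriptCatalog("t1", "g1", "A")
    expect_error(selectExemplar(catN, "g1"), "length")

    withr::local_seed(3)
    for (k in seq_len(20L)) {
        cat1 <- randCatalog(30L)
        tb <- catalogTable(cat1)
        g <- sample(unique(tb$gene), 1L)
        ex <- selectExemplar(cat1, g)
        expect_equal(tb$length[tb$transcript == ex],
                     max(tb$length[tb$gene == g]))
    }
})

test_that("the default pipeline threshold is 0.0005", {
    expect_equal(formals(flagCandidates)$threshold, 5e-4)
    expect_equal(formals(reviseTranscriptAssignments)$threshold, 5e-4)
})
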