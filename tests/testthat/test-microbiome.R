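test_that("rarefaction subsamples exactly to depth without inflating taxa", {
  counts <- c(a = 1200, b = 900, c = 500, d = 47)
  r <- rarefy(counts, depth = 2447, seed = 5)
  expect_identical(sum(r), 2447L)
  expect_true(all(r <= counts))
  expect_identical(names(r), names(counts))
  # exhaustive subsample returned unchanged
  expect_identical(rarefy(counts, depth = sum(counts)),
                   setNames(as.integer(counts), names(counts)))
  # reproducible under a fixed seed, different under another
  expect_identical(rarefy(counts, 2447, seed = 5), r)
  expect_false(identical(rarefy(counts, 2447, seed = 6), r))
  expect_error(rarefy(c(10, 10), 2447), "fewer than")
  expect_error(rarefy(c(-1, 3000), 100), "non-negative")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- c(5000, 3000, 1500, 500)
  prop <- counts / sum(counts)
  depth <- 2447
  means <- rowMeans(vapply(1:300, function(s) as.numeric(rarefy(counts, depth,
                                                                seed = s)),
                           numeric(4)))
  expect_equal(means, depth * prop, tolerance = 0.02)
})

test_that("rarefaction distribution is consistent with the vegan reference", {
  counts <- c(a = 4000, b = 2500, c = 900, d = 100)
  depth <- 2447
  mine <- vapply(1:200, function(s) rarefy(counts, depth, seed = s)[["a"]],
                 integer(1))
  ref <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    suppressWarnings(as.numeric(vegan::rrarefy(counts, depth))[1])
  }, numeric(1))
  expect_lt(abs(mean(mine) - mean(ref)), 3 * sqrt(var(ref) / 200) + 3)
  expect_lt(abs(sd(mine) - sd(ref)) / sd(ref), 0.5)
})

test_that("classification takes the finest matching rank and is order-stable", {
  rules <- classificationRules()
  # class-level rule with nothing finer
  expect_identical(classifyTaxa("phylum:Proteobacteria;class:Alphaproteobacteria",
                                rules), "copiotroph")
  # genus rule overrides a conflicting phylum rule
  expect_identical(classifyTaxa(
    "phylum:Acidobacteria;genus:Pseudomonas", rules), "copiotroph")
  expect_identical(classifyTaxa(
    "phylum:Bacteroidetes;genus:Mycobacterium", rules), "oligotroph")
  # no match -> unassigned
  expect_identical(classifyTaxa("phylum:Nitrospirae", rules), "unassigned")
  expect_error(classifyTaxa("kingdom:Bacteria", rules), "malformed")
  expect_error(classifyTaxa("phylum", rules), "malformed")
  # rule-row order is irrelevant
  shuffled <- rules[rev(seq_len(nrow(rules))), ]
  lineages <- c("phylum:Acidobacteria;genus:Pseudomonas",
                "class:Gammaproteobacteria", "phylum:Verrucomicrobia",
                "phylum:NoSuch")
  expect_identical(classifyTaxa(lineages, rules),
                   classifyTaxa(lineages, shuffled))
})

test_that("conflicting duplicate rules are dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rank\tname\tgroup",
               "phylum\tAcidobacteria\toligotroph",
               "phylum\tAcidobacteria\tcopiotroph",
               "genus\tBacillus\tcopiotroph"), f)
  expect_warning(rules <- classificationRules(f), "conflicting")
  expect_identical(classifyTaxa("phylum:Acidobacteria", rules), "unassigned")
  expect_identical(classifyTaxa("genus:Bacillus", rules), "copiotroph")
})

test_that("the ratio sums counts by group and excludes unassigned reads", {
  counts <- c(10, 15, 5, 8, 2, 60)
  groups <- c("copiotroph", "oligotroph", "copiotroph", "unassigned",
              "oligotroph", "unassigned")
  # manual tally: copiotrophs 10 + 5, oligotrophs 15 + 2
  expect_equal(copiotrophOligotrophRatio(counts, groups), 15 / 17)
  expect_equal(copiotrophOligotrophRatio(c(10, 5), c("copiotroph",
                                                     "oligotroph")), 2)
  expect_equal(copiotrophOligotrophRatio(c(0, 5), c("copiotroph",
                                                    "oligotroph")), 0)
  expect_error(copiotrophOligotrophRatio(c(10, 0), c("copiotroph",
                                                     "oligotroph")),
               "no oligotroph")
})

test_that("unassigned-allocation sweep is monotone with exact endpoints", {
  counts <- c(30, 20, 50)
  groups <- c("copiotroph", "oligotroph", "unassigned")
  sw <- unassignedSensitivity(counts, groups)
  expect_equal(sw$ratio[sw$fraction == 1], (30 + 50) / 20)
  expect_equal(sw$ratio[sw$fraction == 0], 30 / (20 + 50))
  expect_true(all(diff(sw$ratio[order(sw$fraction)]) >= 0))
  # no unassigned reads -> flat sweep
  sw0 <- unassignedSensitivity(c(30, 20), c("copiotroph", "oligotroph"))
  expect_true(all(abs(sw0$ratio - 1.5) < 1e-12))
})

test_that("the sample pipeline rarefies, classifies, and flags shallow samples", {
  gen <- generateAsvTable(n_samples = 8, n_taxa = 40, seed = 3,
                          depth_range = c(3000, 8000))
  # force one shallow sample
  gen$asv$counts[, 3] <- as.integer(round(gen$asv$counts[, 3] * 0.2))
  res <- sampleRatios(gen$asv, gen$rules, depth = 2447, seed = 9)
  expect_identical(res$dropped, "S3")
  expect_identical(nrow(res$ratios), 7L)
  expect_true(all(res$ratios$depth == 2447))
  expect_true(all(res$ratios$ratio >= 0))
  # sweep covers every retained sample and is monotone within each
  for (s in res$ratios$sample) {
    sw <- res$sensitivity[res$sensitivity$sample == s, ]
    expect_true(all(diff(sw$ratio[order(sw$fraction)]) >= 0))
  }
})

test_that("round-trip through the TSV reader preserves counts and lineages", {
  gen <- generateAsvTable(n_samples = 4, n_taxa = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(taxon_id = rownames(gen$asv$counts),
                    lineage = gen$asv$lineage, gen$asv$counts,
                    check.names = FALSE)
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readAsvTable(f)
  expect_equal(unname(back$counts), unname(gen$asv$counts))
  expect_identical(back$lineage, gen$asv$lineage)
  expect_identical(ruleCountsByRank(gen$rules)[["phylum"]],
                   sum(gen$rules$rank == "phylum"))
})
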