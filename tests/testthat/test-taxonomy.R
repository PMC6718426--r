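test_that("event matrix applies per-gene mutation and copy-number rules", {
  seg9 <- call_segments(data.frame(chrom = "chr9", start = 21.9e6,
                                   end = 22.1e6, log2 = -1.4, loh = TRUE))
  seg17 <- call_segments(data.frame(chrom = "chr17", start = 37.8e6,
                                    end = 38e6, log2 = 1.5, loh = FALSE))
  cases <- list(
    # KRAS synonymous only: does not count (missense-only rule)
    quick_case("c1", variants = passing_variant(gene = "KRAS",
                                                effect = "synonymous")),
    quick_case("c2", variants = passing_variant(gene = "KRAS",
                                                effect = "missense")),
    # CDKN2A homozygous deletion spanning the gene counts
    quick_case("c3", segments = seg9),
    # CDKN2A missense does NOT count (inactivating-only rule)
    quick_case("c4", variants = passing_variant(gene = "CDKN2A",
                                                effect = "missense")),
    quick_case("c5", variants = passing_variant(gene = "CDKN2A",
                                                effect = "nonsense")),
    # ERBB2 amplification counts; an ERBB2 gain would not
    quick_case("c6", segments = seg17),
    quick_case("c7", variants = passing_variant(gene = "TP53",
                                                effect = "missense")))
  M <- build_event_matrix(cases)
  expect_equal(unname(M["KRAS", ]), c(0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(M["CDKN2A", ]), c(0, 0, 1, 0, 1, 0, 0))
  expect_equal(unname(M["ERBB2", ]), c(0, 0, 0, 0, 0, 1, 0))
  expect_equal(unname(M["TP53", ]), c(0, 0, 0, 0, 0, 0, 1))
  expect_true(all(M %in% 0:1))

  # low-level gain over ERBB2 is not an event
  gain17 <- call_segments(data.frame(chrom = "chr17", start = 37.8e6,
                                     end = 38e6, log2 = 0.4, loh = FALSE))
  M2 <- build_event_matrix(list(quick_case("g", segments = gain17)))
  expect_equal(unname(M2["ERBB2", ]), 0)
})

test_that("frequencies are exact and clustering behaves canonically", {
  genes <- c("CDKN2A", "KRAS", "TP53", "ERBB2", "SMAD4", "APC")
  freq <- cbind(
    MOC      = c(0.76, 0.64, 0.64, 0.26, 0.02, 0.05),
    Pancreas = c(0.60, 0.90, 0.60, 0.03, 0.55, 0.05),
    CRC      = c(0.05, 0.40, 0.60, 0.03, 0.10, 0.80),
    HGSC     = c(0.05, 0.01, 0.95, 0.10, 0.02, 0.02))
  rownames(freq) <- genes
  cl <- cluster_tumor_types(freq)
  # MOC joins pancreas before any other type
  merge_height <- cl$cophenetic
  m <- as.matrix(merge_height)
  expect_lt(m["MOC", "Pancreas"], m["MOC", "CRC"])
  expect_lt(m["MOC", "Pancreas"], m["MOC", "HGSC"])
  # leaf adjacency in the display order
  lo <- cl$leaf_order
  expect_equal(abs(which(lo == "MOC") - which(lo == "Pancreas")), 1)
  # distances equal a direct computation
  expect_equal(as.matrix(cl$distance)["MOC", "CRC"],
               sqrt(sum((freq[, "MOC"] - freq[, "CRC"])^2)))

  # identical columns merge first at height 0
  freq2 <- cbind(freq, MOC2 = freq[, "MOC"])
  cl2 <- cluster_tumor_types(freq2)
  expect_equal(as.matrix(cl2$cophenetic)["MOC", "MOC2"], 0)

  # three types where two share high frequencies cluster together
  f3 <- cbind(A = c(0.9, 0.9, 0.9, 0.9, 0.9),
              B = c(0.9, 0.88, 0.9, 0.92, 0.9),
              C = c(0, 0, 0, 0, 0))
  cl3 <- cluster_tumor_types(f3)
  m3 <- as.matrix(cl3$cophenetic)
  expect_lt(m3["A", "B"], m3["A", "C"])

  expect_warning(cluster_tumor_types(cbind(a = c(.5, .5), b = c(.5, .5))),
                 "degenerate")
})

test_that("frequency recomputation and column permutation are consistent", {
  set.seed(61)
  co <- simulate_cohort(cohort_spec(n_per_group = c(BEN = 3, MBT = 4,
                                                    G1 = 6, G2 = 6, G3 = 4,
                                                    EOM = 3), seed = 61))
  kept <- filter_cohort(co)$cohort
  M <- build_event_matrix(kept$cases)
  md <- cohort_metadata(kept)
  ef <- event_frequencies(M, md$classification)
  for (t in colnames(ef$freq)) {
    idx <- md$classification == t
    expect_equal(ef$freq[, t], rowSums(M[, idx, drop = FALSE]) / sum(idx))
  }
  # gene row order does not affect the tree
  freq <- ef$freq + matrix(runif(length(ef$freq), 0, 1e-6),
                           nrow(ef$freq))
  cl_a <- cluster_tumor_types(freq)
  cl_b <- cluster_tumor_types(freq[sample(nrow(freq)), ])
  expect_equal(cl_a$leaf_order, cl_b$leaf_order)
  expect_equal(as.matrix(cl_a$cophenetic), as.matrix(cl_b$cophenetic))
})

test_that("dendrograms export to Newick", {
  freq <- cbind(A = c(0.9, 0.1), B = c(0.8, 0.2), C = c(0.1, 0.9))
  cl <- cluster_tumor_types(freq)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})
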