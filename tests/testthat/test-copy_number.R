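seg_row <- function(chrom, start, end, log2, loh = FALSE)
  data.frame(chrom = chrom, start = start, end = end, log2 = log2,
             loh = loh, stringsAsFactors = FALSE)

test_that("log2 thresholds map to discrete calls with documented boundaries", {
  seg <- call_segments(rbind(
    seg_row("chrA", 0, 10, -1.2), seg_row("chrA", 10, 20, -1.0),
    seg_row("chrA", 20, 30, -0.2), seg_row("chrA", 30, 40, 0.0),
    seg_row("chrA", 40, 50, 0.2), seg_row("chrA", 50, 60, 0.6),
    seg_row("chrA", 60, 70, 0.7)))
  expect_equal(seg$call, c("homdel", "loss", "loss", "neutral", "gain",
                           "gain", "amp"))
})

test_that("FGA follows its definition and a per-base counting oracle", {
  b <- toy_build()
  none <- call_segments(seg_row("chrA", 0, 50, 0.0))
  expect_equal(fraction_genome_altered(none, b), 0)

  # chrA (100 bp) fully lost, chrB untouched: (1 + 0) / 2
  lost <- call_segments(seg_row("chrA", 0, 100, -0.5))
  expect_equal(fraction_genome_altered(lost, b), 0.5)

  ob <- oracle_build()
  set.seed(77)
  for (i in 1:40) {
    prof <- random_profile(ob)
    expect_equal(fraction_genome_altered(prof, ob),
                 fga_brute_force(prof, ob), tolerance = 1e-12)
  }

  over <- call_segments(seg_row("chrA", 0, 150, 0.5))
  expect_error(fraction_genome_altered(over, b), "beyond")
})

test_that("altering a neutral segment never decreases FGA", {
  ob <- oracle_build()
  set.seed(78)
  for (i in 1:10) {
    prof <- random_profile(ob)
    neu <- which(prof$call == "neutral")
    if (!length(neu)) next
    f0 <- fraction_genome_altered(prof, ob)
    prof$call[neu[1]] <- "gain"
    expect_gte(fraction_genome_altered(prof, ob), f0)
  }
})

test_that("profile classification follows the documented rules", {
  b <- load_genome_build("hg19")
  expect_equal(classify_profile(call_segments(seg_row("chr1", 0, 10, 0))[0, ],
                                b), "simple")
  quiet <- call_segments(seg_row("chr1", 0, 1e6, 0.05))
  expect_equal(classify_profile(quiet, b), "simple")

  few <- call_segments(rbind(seg_row("chr1", 0, 1e6, 0.4),
                             seg_row("chr2", 0, 1e6, -0.5)))
  expect_equal(classify_profile(few, b), "simple")

  one_amp <- call_segments(rbind(seg_row("chr1", 0, 1e6, 0.4),
                                 seg_row("chr17", 0, 2e6, 1.2)))
  expect_equal(classify_profile(one_amp, b), "simple_one_amp")

  # amps on several chromosomes dominate even a sparse profile
  multi <- call_segments(rbind(seg_row("chr1", 0, 1e6, 0.4),
                               seg_row("chr2", 0, 1e6, -0.5),
                               seg_row("chr8", 0, 2e6, 1.0),
                               seg_row("chr17", 0, 2e6, 1.2),
                               seg_row("chr20", 0, 2e6, 0.9)))
  expect_equal(classify_profile(multi, b), "complex_multi_amp")

  many <- call_segments(do.call(rbind, lapply(1:12, function(i)
    seg_row(paste0("chr", i), 0, 5e6, 0.4))))
  expect_equal(classify_profile(many, b), "complex")

  whole <- call_segments(do.call(rbind, lapply(1:12, function(i)
    seg_row(paste0("chr", i), 0,
            chrom_length(b, paste0("chr", i)), -0.5))))
  expect_equal(classify_profile(whole, b), "complex_whole_chr")
})

test_that("classification is invariant to order and equal-call splitting", {
  b <- load_genome_build("hg19")
  base <- do.call(rbind, lapply(1:11, function(i)
    seg_row(paste0("chr", i), 0, 5e6, 0.4)))
  base <- call_segments(base)
  lab <- classify_profile(base, b)

  shuffled <- base[sample(nrow(base)), ]
  expect_equal(classify_profile(shuffled, b), lab)

  # split one event into adjacent equal-call pieces
  split <- rbind(base[-1, ],
                 call_segments(rbind(seg_row("chr1", 0, 2e6, 0.4),
                                     seg_row("chr1", 2e6, 5e6, 0.4))))
  expect_equal(classify_profile(split, b), lab)
})

test_that("group comparison matches an exact hypergeometric oracle", {
  b <- toy_build()
  make_group <- function(n_aber, n_total, id0) {
    lapply(seq_len(n_total), function(i) {
      seg <- if (i <= n_aber)
        call_segments(seg_row("chrA", 10, 60, 0.5)) else
        call_segments(seg_row("chrA", 10, 60, 0.0))
      quick_case(paste0(id0, i), segments = seg)
    })
  }
  ga <- make_group(18, 20, "A")
  gb <- make_group(2, 20, "B")
  res <- compare_group_frequencies(ga, gb, b)
  row <- res[res$direction == "gain" & res$start == 10, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$freq_group1, 0.9)
  expect_equal(row$diff, 0.8)
  oracle_p <- fisher_brute_force(matrix(c(18, 2, 2, 18), 2))
  expect_equal(row$p_value, oracle_p, tolerance = 1e-9)
  # 2 * (C(20,2)^2 + 20^2 + 1) / C(40,20) by direct enumeration
  expect_equal(row$p_value, 73002 / 137846528820, tolerance = 1e-9)
  expect_true(row$significant)

  # all-quiet interval: p = 1, not significant
  res0 <- compare_group_frequencies(make_group(0, 5, "C"),
                                    make_group(0, 5, "D"), b,
                                    drop_empty = FALSE)
  expect_true(all(res0$p_value == 1))
  expect_false(any(res0$significant))

  # >90% polymorphism overlap excludes an otherwise significant region
  cnp <- data.frame(chrom = "chrA", start = 8, end = 60)
  res_cnp <- compare_group_frequencies(ga, gb, b, cnp_track = cnp)
  row2 <- res_cnp[res_cnp$direction == "gain" & res_cnp$start == 10, ]
  expect_gt(row2$cnp_frac, 0.9)
  expect_false(row2$significant)

  # swapping groups preserves p-values
  res_sw <- compare_group_frequencies(gb, ga, b)
  row_sw <- res_sw[res_sw$direction == "gain" & res_sw$start == 10, ]
  expect_equal(row_sw$p_value, row$p_value)
  expect_error(compare_group_frequencies(ga, list(), b), "at least 2")
})

test_that("minimal region of overlap is the intersection of amp unions", {
  b <- load_genome_build("hg19")
  amp_case <- function(id, start, end)
    quick_case(id, segments = call_segments(seg_row("chr9", start, end, 1.2)))
  mro <- minimal_overlap_region(list(amp_case("a", 10, 50),
                                     amp_case("b", 30, 70)), "chr9")
  expect_equal(mro$start, 30)
  expect_equal(mro$end, 50)

  same <- minimal_overlap_region(list(amp_case("a", 10, 50),
                                      amp_case("b", 10, 50)), "chr9")
  expect_equal(c(same$start, same$end), c(10, 50))

  # planted common core recovered from 17 cases with random flanks:
  # two cases bound the core exactly, the rest extend beyond it
  set.seed(41)
  core <- c(33.785e6, 35.159e6)
  cases <- c(
    list(amp_case("p1", core[1], core[2] + runif(1, 1e5, 4e6)),
         amp_case("p2", core[1] - runif(1, 1e5, 3e6), core[2])),
    lapply(3:17, function(i)
      amp_case(paste0("p", i), core[1] - runif(1, 0, 3e6),
               core[2] + runif(1, 0, 4e6))))
  mro <- minimal_overlap_region(cases, "chr9")
  expect_equal(c(mro$start, mro$end), core)

  no_amp <- quick_case("z", segments = call_segments(seg_row("chr9", 0,
                                                             1e6, 0)))
  expect_error(minimal_overlap_region(list(amp_case("a", 10, 50), no_amp),
                                      "chr9"), "case z")

  # disjoint amps: empty intersection reported explicitly
  empty <- minimal_overlap_region(list(amp_case("a", 10, 20),
                                       amp_case("b", 30, 40)), "chr9")
  expect_equal(nrow(empty), 0)
})
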