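test_that("single-variant cascade decisions match the rule set", {
  cfg <- moc_thresholds()

  # all rules satisfied
  d <- classify_variant(passing_variant(), "exome_paired")
  expect_true(d$keep)
  expect_identical(d$reasons, "")

  # VarScan-only calls are rejected on every platform
  d <- classify_variant(passing_variant(callers = "VarScan"),
                        "exome_paired")
  expect_false(d$keep)
  expect_identical(d$reasons, "caller_concordance")

  # UnifiedGenotyper-only is rejected only without a matched normal
  ug <- passing_variant(callers = "UnifiedGenotyper")
  expect_true(classify_variant(ug, "exome_paired")$keep)
  expect_false(classify_variant(ug, "exome_unpaired")$keep)

  # panel depth floor is 20 reads with 10 supporting the variant
  pv <- passing_variant(depth = 19L, alt_depth = 10L, vaf_tumor = 10 / 19,
                        vaf_normal = NA_real_)
  d <- classify_variant(pv, "panel")
  expect_false(d$keep)
  expect_identical(d$reasons, "depth")
  pv$depth <- 40L; pv$vaf_tumor <- 0.25
  expect_true(classify_variant(pv, "panel")$keep)

  # hotspots are exempt from the cohort-recurrence rule
  hot <- passing_variant(gene = "KRAS", is_hotspot = TRUE)
  ctx <- filter_context(cohort_fraction = setNames(0.35, variant_key(hot)))
  expect_true(classify_variant(hot, "exome_paired", ctx)$keep)
  cold <- passing_variant(is_hotspot = FALSE)
  ctx <- filter_context(cohort_fraction = setNames(0.35, variant_key(cold)))
  expect_false(classify_variant(cold, "exome_paired", ctx)$keep)

  # population-frequency rule with the ClinVar rescue
  com <- passing_variant(pop_af = 0.01)
  expect_false(classify_variant(com, "exome_paired")$keep)
  expect_true(classify_variant(
    passing_variant(pop_af = 0.01, clinvar_pathogenic = TRUE),
    "exome_paired")$keep)

  # absent quality evidence fails, never passes silently
  expect_false(classify_variant(passing_variant(qual = NA_real_),
                                "exome_paired")$keep)

  # paired mode requires a normal VAF
  expect_error(classify_variant(passing_variant(vaf_normal = NA_real_),
                                "exome_paired"), "normal VAF")

  # multiple violations are all reported, in cascade order
  d <- classify_variant(passing_variant(qual = 10, callers = "VarScan"),
                        "exome_paired")
  expect_identical(d$reasons, "qual;caller_concordance")
})

test_that("keep is true exactly when no reasons are reported", {
  set.seed(14)
  ref <- toy_reference(seed = 14)
  v <- simulate_case_variants("G2", "exome_unpaired", cohort_spec(),
                              ref)$variants
  d <- classify_variant(v, "exome_unpaired")
  expect_identical(d$keep, d$reasons == "")
})

test_that("raising a minimum threshold never grows the kept set", {
  set.seed(15)
  ref <- toy_reference(seed = 15)
  v <- simulate_case_variants("G2", "exome_paired", cohort_spec(),
                              ref)$variants
  base_keep <- classify_variant(v, "exome_paired")$keep
  for (arg in list(list(qual_min = 50), list(depth_min = 30),
                   list(alt_depth_min = 5), list(vaf_min = 0.2),
                   list(cohort_recurrence_max = 0))) {
    cfg <- do.call(moc_thresholds, arg)
    strict_keep <- classify_variant(v, "exome_paired", cfg = cfg)$keep
    expect_true(all(base_keep | !strict_keep))
  }
})

test_that("cohort recurrence uses identity across cases and is idempotent", {
  # one non-hotspot variant shared by 3/10 cases: rejected in all three
  shared <- passing_variant(pos = 777L)
  cases <- lapply(1:10, function(i) {
    v <- passing_variant(pos = 1000L + i)
    if (i <= 3) v <- rbind(v, shared)
    quick_case(paste0("C", i), variants = v)
  })
  co <- moc_cohort(cases)
  fr <- filter_cohort(co)
  expect_equal(fr$ledger$rejected[fr$ledger$rule == "cohort_recurrence"], 3)
  kept_pos <- unlist(lapply(fr$cohort$cases, function(cs) cs$variants$pos))
  expect_false(777L %in% kept_pos)

  # idempotence: filtering the filtered cohort changes nothing
  fr2 <- filter_cohort(fr$cohort)
  expect_equal(fr2$n_input, fr2$n_kept)
  expect_identical(
    lapply(fr2$cohort$cases, function(cs) cs$variants$pos),
    lapply(fr$cohort$cases, function(cs) cs$variants$pos))
})

test_that("the cascade is a perfect oracle on a labelled cohort", {
  spec <- cohort_spec(n_per_group = c(BEN = 5, MBT = 8, G1 = 15, G2 = 15,
                                      G3 = 8, EOM = 5), seed = 19)
  co <- simulate_cohort(spec)
  fr <- filter_cohort(co)
  for (id in names(co$cases)) {
    v <- co$cases[[id]]$variants
    if (!nrow(v)) next
    d <- fr$decisions[[id]]
    expect_identical(d$keep, v$truth == "somatic")
  }
})

test_that("mutation burden counts panel coding/splice variants per Mb", {
  panel <- c("KRAS", "TP53")
  none <- passing_variant()[0, ]
  expect_equal(variants_per_mb(none, panel), 0)

  v207 <- do.call(rbind, lapply(1:207, function(i)
    passing_variant(pos = i + 1L, gene = "KRAS")))
  expect_equal(variants_per_mb(v207, panel), 100)

  mixed <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      passing_variant(pos = i, gene = "KRAS", consequence = "coding"))),
    passing_variant(pos = 11L, gene = "ZZZ1", consequence = "coding"),
    passing_variant(pos = 12L, gene = "ZZZ2", consequence = "coding"),
    passing_variant(pos = 13L, gene = "KRAS", consequence = "other"))
  expect_equal(variants_per_mb(mixed, panel), 4 / 2.07)
  expect_error(variants_per_mb(mixed, panel, target_mb = 0), "positive")
})
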