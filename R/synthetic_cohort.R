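#' Cohort simulation specification
#'
#' Defines the statistical structure of a simulated mucinous ovarian
#' tumor cohort: per-group sizes, per-group driver-event probabilities,
#' the grade-wise gradient of the fraction of genome altered (FGA),
#' artifact injection rates for the filtering cascade, profile-archetype
#' weights and the FGA-survival link. Defaults follow the observed
#' cohort structure: group sizes (BEN 22, MBT 39, G1 87, G2 79, G3 24,
#' EOM 23), carcinoma driver frequencies (CDKN2A inactivation 0.76, KRAS
#' and TP53 0.64, ERBB2 amplification 0.26, RNF43/BRAF/PIK3CA/ARID1A
#' 0.08-0.12), TP53 at 0.18 in borderline tumors, and a strictly
#' increasing FGA gradient from benign through grade 3.
#'
#' @param n_per_group named counts for BEN, MBT, G1, G2, G3, EOM.
#' @param event_freqs gene x group matrix of driver-event probabilities.
#' @param fga_means named per-group mean FGA; must increase strictly
#'   across BEN, MBT, G1, G2, G3.
#' @param fga_cv coefficient of variation of per-case FGA around its
#'   group mean (Gamma-distributed, so group means are recovered
#'   exactly in expectation).
#' @param passenger_mean Poisson mean of true somatic passenger
#'   mutations per case.
#' @param artifact_rates named Poisson means per case for each artifact
#'   class injected for the cascade (see Details).
#' @param recurrent_sites number of cohort-recurrent artifact sites.
#' @param platform_probs probabilities of the four platform modes.
#' @param profile_weights group x archetype matrix of profile-type
#'   weights (simple, simple_one_amp, complex, complex_whole_chr,
#'   complex_multi_amp).
#' @param amp9p13_probs per-group probability of the 9p13 amplicon.
#' @param survival_link log-hazard multiplier per unit FGA (0 = no
#'   association).
#' @param base_hazard monthly disease-specific death hazard at FGA 0.
#' @param other_cause_rate monthly hazard of death from other causes
#'   (censored in disease-specific survival).
#' @param admin_censor administrative censoring time in months.
#' @param seed RNG seed; simulation is byte-reproducible given it.
#'
#' @details Artifact classes each violate exactly one cascade rule:
#' `popaf` (common population variant), `qual`, `depth`, `alt_depth`,
#' `vaf` (subclonal fraction at or below 0.05), `varscan_only`,
#' `ug_only` (platforms without a matched normal), `germline` (normal
#' VAF above 0.05; paired platforms), `caller_filters`, `blacklist`,
#' `pon` (panel-of-normals recurrent) and `batch_normal` (panel
#' platform). Cohort-recurrent non-hotspot artifacts are injected at
#' shared sites into more than 20% of cases.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_per_group = c(BEN = 22, MBT = 39, G1 = 87, G2 = 79, G3 = 24, EOM = 23),
    event_freqs = default_event_freqs(),
    fga_means = c(BEN = 0.01, MBT = 0.04, G1 = 0.10, G2 = 0.15,
                  G3 = 0.25, EOM = 0.20),
    fga_cv = 0.35,
    passenger_mean = 12,
    artifact_rates = c(popaf = 1, qual = 1, depth = 1, alt_depth = 0.5,
                       vaf = 0.5, varscan_only = 1, ug_only = 1,
                       germline = 1, caller_filters = 0.5, blacklist = 0.3,
                       pon = 0.5, batch_normal = 0.5),
    recurrent_sites = 2,
    platform_probs = c(exome_paired = 0.3, exome_unpaired = 0.1,
                       wgs = 0.05, panel = 0.55),
    profile_weights = default_profile_weights(),
    amp9p13_probs = c(BEN = 0, MBT = 0, G1 = 0.02, G2 = 0.08, G3 = 0.3,
                      EOM = 0.05),
    survival_link = 5,
    base_hazard = 0.01,
    other_cause_rate = 0.002,
    admin_censor = 120,
    seed = 1) {
  groups <- c("BEN", "MBT", "G1", "G2", "G3", "EOM")
  stopifnot(all(groups %in% names(n_per_group)),
            all(groups %in% colnames(event_freqs)),
            all(groups %in% names(fga_means)))
  if (any(event_freqs < 0 | event_freqs > 1))
    stop("event probabilities must lie in [0, 1]")
  grad <- fga_means[c("BEN", "MBT", "G1", "G2", "G3")]
  if (any(diff(grad) <= 0))
    stop("fga_means must increase strictly from BEN to G3")
  if (any(fga_means <= 0) || any(fga_means >= 1))
    stop("fga_means must lie in (0, 1)")
  structure(list(
    n_per_group = n_per_group[groups], event_freqs = event_freqs,
    fga_means = fga_means[groups], fga_cv = fga_cv,
    passenger_mean = passenger_mean, artifact_rates = artifact_rates,
    recurrent_sites = recurrent_sites, platform_probs = platform_probs,
    profile_weights = profile_weights, amp9p13_probs = amp9p13_probs,
    survival_link = survival_link, base_hazard = base_hazard,
    other_cause_rate = other_cause_rate, admin_censor = admin_censor,
    seed = seed), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_event_freqs <- function() {
  genes <- c("CDKN2A", "KRAS", "TP53", "ERBB2", "RNF43", "BRAF",
             "PIK3CA", "ARID1A")
  moc <- c(0.76, 0.64, 0.64, 0.26, 0.12, 0.10, 0.10, 0.08)
  m <- cbind(
    BEN = c(0.30, 0.55, 0.02, 0.00, 0.02, 0.15, 0.02, 0.02),
    MBT = c(0.60, 0.70, 0.18, 0.03, 0.05, 0.30, 0.05, 0.05),
    G1 = moc, G2 = moc, G3 = moc,
    EOM = c(0.40, 0.50, 0.50, 0.10, 0.05, 0.05, 0.10, 0.05))
  rownames(m) <- genes
  m
}

#' @rdname cohort_spec
#' @export
default_profile_weights <- function() {
  arche <- c("simple", "simple_one_amp", "complex", "complex_whole_chr",
             "complex_multi_amp")
  m <- rbind(
    BEN = c(0.95, 0.00, 0.05, 0.00, 0.00),
    MBT = c(0.82, 0.026, 0.128, 0.026, 0.00),
    G1  = c(0.40, 0.12, 0.25, 0.08, 0.15),
    G2  = c(0.25, 0.10, 0.25, 0.05, 0.35),
    G3  = c(0.10, 0.08, 0.25, 0.07, 0.50),
    EOM = c(0.25, 0.10, 0.25, 0.05, 0.35))
  colnames(m) <- arche
  m / rowSums(m)
}

#' Toy reference genome for trinucleotide-context lookup
#'
#' A small multi-chromosome random nucleotide sequence; every simulated
#' SNV's reference allele is drawn from it, so catalogs built from
#' simulated variants are exact.
#'
#' @param seed RNG seed.
#' @param n_chrom number of toy contigs.
#' @param chrom_len contig length in bp.
#' @return A named `DNAStringSet`.
#' @export
toy_reference <- function(seed = 1, n_chrom = 6, chrom_len = 10000) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), "")
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("toy", seq_len(n_chrom))
  ref
}

# deterministic driver-gene windows on the toy reference
.toy_gene_windows <- function(reference) {
  genes <- c(rownames(default_event_freqs()), "HYDIN")
  n_chrom <- length(reference)
  len <- Biostrings::width(reference)[1]
  w <- 200L
  slots <- ceiling(length(genes) / n_chrom)
  data.frame(
    gene = genes,
    chrom = names(reference)[((seq_along(genes) - 1) %% n_chrom) + 1],
    start = 50L + ((seq_along(genes) - 1) %/% n_chrom) * (w + 50L),
    stringsAsFactors = FALSE
  ) |> transform(end = start + w)
}

.base_at <- function(reference, chrom, pos)
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos))

# Disjoint position zones on each toy contig keep variant identities from
# colliding across simulation roles: gene windows at the start, free
# positions for passengers and per-case artifacts in the middle, and
# reserved bands for identity-keyed artifact classes at the end (variants
# whose chrom:pos:ref:alt identity must recur across cases).
.zone_free <- function(len) c(2601L, len - 1001L)
.zone_pon <- function(len) c(len - 999L, len - 700L)
.zone_batch <- function(len) c(len - 699L, len - 400L)
.zone_recurrent <- function(len) c(len - 399L, len - 100L)

# positions in the free zone whose base is C followed by G, per contig
.cpg_sites <- function(reference) {
  len <- Biostrings::width(reference)[1]
  zone <- .zone_free(len)
  lapply(as.list(as.character(reference)), function(s) {
    pos <- gregexpr("CG", s, fixed = TRUE)[[1]]
    pos <- pos[pos >= zone[1] & pos <= zone[2]]
    as.integer(pos)
  }) |> stats::setNames(names(reference))
}

.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

.passenger_genes <- paste0("PSG", 1:30)

#' Panel gene set of the simulator
#'
#' Driver genes plus the simulated passenger genes; the footprint used
#' by [variants_per_mb()] on simulated cohorts.
#' @return Character vector of gene symbols.
#' @export
simulated_panel_genes <- function()
  c(rownames(default_event_freqs()), .passenger_genes)

# one passing-variant template at a random reference position
.base_variant <- function(reference, cpg, mode, gene = NA_character_,
                          effect = "missense", consequence = "coding",
                          sig1 = FALSE, chrom = NULL, pos = NULL) {
  if (is.null(chrom)) {
    chrom <- sample(names(reference), 1)
    zone <- .zone_free(length(reference[[chrom]]))
    if (sig1 && stats::runif(1) < 0.7 && length(cpg[[chrom]]))
      pos <- sample(cpg[[chrom]], 1)
    else
      pos <- sample(zone[1]:zone[2], 1)
  }
  ref <- .base_at(reference, chrom, pos)
  alt <- if (sig1 && ref == "C") "T" else if (sig1 && ref == "G") "A"
         else .other_base(ref)
  depth_min <- if (mode == "panel") 20L else 10L
  alt_min <- if (mode == "panel") 10L else 2L
  depth <- depth_min + 30L + stats::rpois(1, 60)
  vaf_true <- stats::runif(1, 0.15, 0.6)
  repeat {
    alt_depth <- stats::rbinom(1, depth, vaf_true)
    if (alt_depth >= alt_min && alt_depth / depth > 0.051) break
  }
  callers <- c("VarDict", "MuTect2", "Platypus",
               sample(c("VarScan", "UnifiedGenotyper"),
                      stats::rbinom(1, 2, 0.5)))
  callers <- paste(sample(callers, max(2, length(callers))), collapse = ",")
  vaf_normal <- if (mode %in% c("exome_paired", "wgs"))
    min(stats::rbinom(1, 100, 0.005) / 100, 0.05) else NA_real_
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = round(stats::runif(1, 35, 90), 1),
    depth = depth, alt_depth = alt_depth,
    vaf_tumor = alt_depth / depth, vaf_normal = vaf_normal,
    callers = callers, passes_caller_filters = TRUE,
    consequence = consequence, effect = effect, gene = gene,
    pop_af = if (stats::runif(1) < 0.2)
      stats::runif(1, 0, 9e-5) else NA_real_,
    clinvar_pathogenic = FALSE, is_hotspot = FALSE,
    truth = "somatic", stringsAsFactors = FALSE)
}

#' Simulate the variant calls of one case
#'
#' Injects (a) true somatic driver and passenger mutations with allele
#' fractions above the detection floor, full multi-caller support and
#' passing annotations, and (b) artifact variants, each violating
#' exactly one rule of the filtering cascade, carrying a `truth` label
#' naming the violated rule. KRAS drivers sit at a fixed codon-12-like
#' hotspot site shared across cases (testing the hotspot exemption from
#' the recurrence filter). Returns the variant table plus the gene-level
#' copy-number events (CDKN2A homozygous deletion, ERBB2 amplification)
#' to be realised as segments.
#'
#' @param classification group label (BEN...EOM).
#' @param mode platform mode.
#' @param spec a [cohort_spec()].
#' @param reference toy reference (`DNAStringSet`).
#' @return List with `variants` (a [variant_calls()] table with `truth`
#'   column), `cn_events` (character vector like `"CDKN2A_homdel"`), and
#'   `registry` (keys for panel-of-normals / batch-normal bookkeeping).
#' @export
simulate_case_variants <- function(classification, mode, spec, reference) {
  windows <- .toy_gene_windows(reference)
  cpg <- .cpg_sites(reference)
  rows <- list()
  cn_events <- character()
  registry <- list(pon = character(), batch = character())
  gene_pos <- function(g) {
    w <- windows[windows$gene == g, ]
    list(chrom = w$chrom, pos = sample((w$start + 1):(w$end - 1), 1))
  }

  # drivers
  freqs <- spec$event_freqs[, classification]
  for (g in names(freqs)) {
    if (stats::runif(1) >= freqs[g]) next
    if (g == "ERBB2") { cn_events <- c(cn_events, "ERBB2_amp"); next }
    if (g == "CDKN2A" && stats::runif(1) < 0.5) {
      cn_events <- c(cn_events, "CDKN2A_homdel"); next
    }
    effect <- switch(g,
      KRAS = "missense", BRAF = "missense", PIK3CA = "missense",
      TP53 = sample(c("missense", "nonsense"), 1, prob = c(0.7, 0.3)),
      CDKN2A = sample(c("nonsense", "frameshift", "splice"), 1),
      RNF43 = "frameshift", ARID1A = "nonsense", "missense")
    if (g == "KRAS") {
      w <- windows[windows$gene == g, ]
      loc <- list(chrom = w$chrom, pos = w$start + 12L)  # shared hotspot site
    } else loc <- gene_pos(g)
    v <- .base_variant(reference, cpg, mode, gene = g, effect = effect,
                       consequence = if (effect == "splice") "splice"
                                     else "coding",
                       chrom = loc$chrom, pos = loc$pos)
    if (g == "KRAS") {
      v$alt <- if (v$ref %in% c("C", "T")) "A" else "T"  # fixed alt allele
      v$is_hotspot <- TRUE
    }
    rows[[length(rows) + 1L]] <- v
  }

  # passengers (age-related flavor: C>T at CpG with probability 0.7)
  n_pass <- stats::rpois(1, spec$passenger_mean)
  for (i in seq_len(n_pass)) {
    eff <- sample(c("missense", "synonymous", "nonsense"), 1,
                  prob = c(0.6, 0.3, 0.1))
    v <- .base_variant(reference, cpg, mode,
                       gene = sample(.passenger_genes, 1), effect = eff,
                       consequence = sample(c("coding", "splice", "other"),
                                            1, prob = c(0.8, 0.1, 0.1)),
                       sig1 = TRUE)
    rows[[length(rows) + 1L]] <- v
  }

  # artifacts: each violates exactly one cascade rule
  paired <- mode %in% c("exome_paired", "wgs")
  rates <- spec$artifact_rates
  add_artifact <- function(class) {
    if (class %in% c("pon", "batch_normal")) {
      chrom <- sample(names(reference), 1)
      zone <- if (class == "pon") .zone_pon(length(reference[[chrom]]))
              else .zone_batch(length(reference[[chrom]]))
      v <- .base_variant(reference, cpg, mode, chrom = chrom,
                         pos = sample(zone[1]:zone[2], 1))
    } else {
      v <- .base_variant(reference, cpg, mode)
    }
    v$gene <- sample(.passenger_genes, 1)
    switch(class,
      popaf = { v$pop_af <- 10^stats::runif(1, -3.5, -1.5) },
      qual = { v$qual <- round(stats::runif(1, 5, 29), 1) },
      depth = {
        if (mode == "panel") { v$depth <- 15L; v$alt_depth <- 10L }
        else { v$depth <- 8L; v$alt_depth <- 3L }
        v$vaf_tumor <- v$alt_depth / v$depth
      },
      alt_depth = {
        if (mode == "panel") { v$depth <- 60L; v$alt_depth <- 5L }
        else { v$depth <- 12L; v$alt_depth <- 1L }
        v$vaf_tumor <- v$alt_depth / v$depth
      },
      vaf = {
        if (mode == "panel") { v$depth <- 300L; v$alt_depth <- 10L }
        else { v$depth <- 100L; v$alt_depth <- 3L }
        v$vaf_tumor <- v$alt_depth / v$depth
      },
      varscan_only = { v$callers <- "VarScan" },
      ug_only = { v$callers <- "UnifiedGenotyper" },
      germline = { v$vaf_normal <- stats::runif(1, 0.15, 0.45) },
      caller_filters = { v$passes_caller_filters <- FALSE },
      blacklist = { v$gene <- "HYDIN" },
      pon = { registry$pon <<- c(registry$pon, variant_key(v)) },
      batch_normal = { registry$batch <<- c(registry$batch, variant_key(v)) })
    v$truth <- paste0("artifact_", class)
    rows[[length(rows) + 1L]] <<- v
  }
  for (class in names(rates)) {
    if (class == "germline" && !paired) next
    if (class == "ug_only" && paired) next
    if (class == "batch_normal" && mode != "panel") next
    for (k in seq_len(stats::rpois(1, rates[class]))) add_artifact(class)
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    .base_variant(reference, cpg, mode)[0, ]
  # drop accidental duplicate identities within the case
  variants <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variant_calls(variants), cn_events = cn_events,
       registry = registry)
}

# split a per-chromosome altered fraction into n non-overlapping segments
.place_segments <- function(chrom, chrom_len, frac, n_seg) {
  total <- frac * chrom_len
  if (frac >= 0.999) {
    return(data.frame(chrom = chrom, start = 0, end = chrom_len,
                      stringsAsFactors = FALSE))
  }
  n_seg <- max(1L, n_seg)
  parts <- stats::runif(n_seg)
  widths <- pmax(round(total * parts / sum(parts)), 1)
  gap_total <- chrom_len - sum(widths)
  gaps <- stats::runif(n_seg + 1)
  gaps <- floor(gap_total * gaps / sum(gaps))
  starts <- cumsum(c(gaps[1], widths[-n_seg] + gaps[2:n_seg]))
  data.frame(chrom = chrom, start = starts, end = starts + widths,
             stringsAsFactors = FALSE)
}

.trim_overlaps <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    last_end <- -Inf
    for (i in seq_len(nrow(s))) {
      if (s$start[i] < last_end) s$start[i] <- last_end
      if (s$start[i] < s$end[i]) {
        last_end <- s$end[i]
        out[[length(out) + 1L]] <- s[i, , drop = FALSE]
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate copy-number segments, structural variants and survival
#'
#' Draws a target FGA around the group mean, samples a profile archetype
#' with grade-dependent weights, lays out altered segments matching the
#' target, adds driver copy-number events (CDKN2A homozygous deletion,
#' ERBB2 amplification, the 9p13 amplicon with its fixed common core),
#' attaches a structural-variant set (fold-back-sized inversions
#' enriched in amplified cases) and draws a disease-specific survival
#' time from an exponential model with hazard proportional to
#' `exp(survival_link * FGA)`.
#'
#' @param classification group label.
#' @param spec a [cohort_spec()].
#' @param build a [genome_build()] (hg19 scale).
#' @param cn_events gene-level events from [simulate_case_variants()].
#' @param with_svs generate the structural-variant set (disable for
#'   large survival simulations where only FGA and outcome are needed).
#' @return List with `segments` (log2 + loh), `svs`, `time`, `event`,
#'   `stage`, and `truth` (target FGA, archetype, planted SV classes).
#' @export
simulate_case_cn_sv <- function(classification, spec, build,
                                cn_events = character(), with_svs = TRUE) {
  m <- spec$fga_means[classification]
  shape <- 1 / spec$fga_cv^2
  f_target <- min(stats::rgamma(1, shape = shape, rate = shape / m), 0.9)
  if (f_target > 1) stop("FGA target exceeds 1")
  arche <- sample(colnames(spec$profile_weights), 1,
                  prob = spec$profile_weights[classification, ])
  n_chrom <- nrow(build)
  budget <- f_target * n_chrom          # sum of per-chromosome fractions

  segs <- list()
  add <- function(df) segs[[length(segs) + 1L]] <<- df

  whole_first <- arche == "complex_whole_chr"
  # chr9 and chr17 are reserved for driver events (CDKN2A, 9p13, ERBB2,
  # TP53 region) so random background never clips them
  pool <- sample(setdiff(build$chrom, c("chr9", "chr17")))
  used <- character()
  if (whole_first) {
    n_whole <- max(1, floor(budget))
    whole <- pool[seq_len(min(n_whole, length(pool) - 2))]
    for (ch in whole)
      add(data.frame(chrom = ch, start = 0,
                     end = chrom_length(build, ch)))
    used <- whole
    budget <- budget - length(whole)
  }
  if (budget > 0.004) {
    n_ev <- switch(arche,
      simple = sample(2:6, 1), simple_one_amp = sample(2:6, 1),
      complex = sample(12:22, 1), complex_whole_chr = sample(3:5, 1),
      complex_multi_amp = sample(12:20, 1))
    avail <- setdiff(pool, used)
    n_ch <- min(length(avail),
                max(1L, ceiling(budget / 0.9),
                    min(n_ev, ceiling(budget / 0.6))))
    chroms <- avail[seq_len(n_ch)]
    fr <- stats::runif(n_ch)
    fr <- budget * fr / sum(fr)
    # redistribute mass above the per-chromosome cap so the target is kept
    for (it in 1:10) {
      over <- fr > 0.95
      if (!any(over) || all(over)) break
      excess <- sum(fr[over] - 0.95)
      fr[over] <- 0.95
      head_room <- which(fr < 0.95)
      fr[head_room] <- fr[head_room] + excess / length(head_room)
    }
    fr <- pmin(fr, 0.95)
    per_seg <- pmax(1L, round(n_ev / n_ch))
    for (i in seq_len(n_ch))
      add(.place_segments(chroms[i], chrom_length(build, chroms[i]),
                          fr[i], per_seg))
  }
  seg <- do.call(rbind, segs)
  seg$log2 <- ifelse(stats::runif(nrow(seg)) < 0.5,
                     stats::runif(nrow(seg), -0.9, -0.25),
                     stats::runif(nrow(seg), 0.25, 0.55))
  seg$loh <- seg$log2 < 0

  amp_seg <- function(chrom, start, end)
    data.frame(chrom = chrom, start = start, end = end,
               log2 = stats::runif(1, 0.8, 2.5), loh = FALSE,
               stringsAsFactors = FALSE)
  n_amp_chrom <- switch(arche, simple_one_amp = 1L,
                        complex_multi_amp = sample(2:4, 1), 0L)
  amp_chroms <- character()
  if (n_amp_chrom > 0) {
    free <- setdiff(pool, unique(seg$chrom))
    if (length(free) < n_amp_chrom) free <- pool
    amp_chroms <- sample(free, n_amp_chrom)
    for (ch in amp_chroms) {
      len <- chrom_length(build, ch)
      st <- stats::runif(1, 0, len - 3e6)
      seg <- rbind(seg, amp_seg(ch, st, st + stats::runif(1, 1e6, 3e6)))
    }
  }
  if ("CDKN2A_homdel" %in% cn_events)
    seg <- rbind(seg, data.frame(chrom = "chr9", start = 2.19e7,
                                 end = 2.21e7, log2 = -1.4, loh = TRUE))
  if ("ERBB2_amp" %in% cn_events)
    seg <- rbind(seg, data.frame(chrom = "chr17", start = 3.78e7,
                                 end = 3.80e7, log2 = 1.6, loh = FALSE))
  has_9p13 <- stats::runif(1) < spec$amp9p13_probs[classification]
  if (has_9p13)
    seg <- rbind(seg, data.frame(
      chrom = "chr9",
      start = 33.785e6 - stats::runif(1, 0, 2e6),
      end = 35.159e6 + stats::runif(1, 0, 3e6),
      log2 = stats::runif(1, 0.8, 2), loh = FALSE))
  seg <- .trim_overlaps(seg[order(seg$chrom, seg$start), , drop = FALSE])
  seg <- cn_segments(seg, build)

  amped <- n_amp_chrom > 0 || has_9p13 || "ERBB2_amp" %in% cn_events
  svs <- NULL
  if (with_svs) {
    n_sv <- stats::rpois(1, switch(arche, simple = 3, simple_one_amp = 8,
                                   complex = 15, complex_whole_chr = 12,
                                   complex_multi_amp = 25))
    probs <- c(small_deletion = 0.20, large_deletion = 0.10,
               small_duplication = 0.15, large_duplication = 0.10,
               foldback_inversion = if (amped) 0.20 else 0.04,
               small_inversion = 0.10, large_inversion = 0.05,
               interchromosomal_translocation = if (amped) 0.10 else 0.26)
    svs <- simulate_sv_set(n_sv, probs / sum(probs), build)
  }

  fga <- fraction_genome_altered(call_segments(seg), build)
  hazard <- spec$base_hazard * exp(spec$survival_link * fga)
  t_dod <- stats::rexp(1, hazard)
  t_other <- stats::rexp(1, spec$other_cause_rate)
  time <- round(min(t_dod, t_other, spec$admin_censor), 1)
  event <- if (t_dod <= t_other && t_dod < spec$admin_censor)
    "death-of-disease" else "censored"
  stage <- sample(c("I", "II", "III", "IV"), 1,
                  prob = switch(classification,
                                G3 = c(0.3, 0.2, 0.3, 0.2),
                                G2 = c(0.5, 0.2, 0.2, 0.1),
                                c(0.7, 0.15, 0.1, 0.05)))
  list(segments = seg, svs = svs, time = time, event = event, stage = stage,
       truth = list(fga_target = f_target, fga_realized = fga,
                    archetype = arche,
                    sv_classes = if (with_svs) attr(svs, "truth_classes")))
}

#' Simulate a structural-variant set with given class proportions
#'
#' @param n number of breakend pairs.
#' @param class_probs named probabilities over the eight SV classes
#'   (see [classify_sv()]).
#' @param build a [genome_build()].
#' @param cfg a [moc_thresholds()] (size boundaries).
#' @return An [sv_pairs()] table with a `truth_classes` attribute.
#' @export
simulate_sv_set <- function(n, class_probs, build, cfg = moc_thresholds()) {
  classes <- sample(names(class_probs), n, replace = TRUE,
                    prob = class_probs)
  rows <- lapply(classes, function(cl) {
    if (cl == "interchromosomal_translocation") {
      chs <- sample(build$chrom, 2)
      return(data.frame(chrom_a = chs[1],
                        pos_a = round(stats::runif(1, 1, chrom_length(build, chs[1]))),
                        chrom_b = chs[2],
                        pos_b = round(stats::runif(1, 1, chrom_length(build, chs[2]))),
                        sv_type = "translocation", stringsAsFactors = FALSE))
    }
    size <- switch(cl,
      foldback_inversion = stats::runif(1, 500, cfg$foldback_bp - 1),
      small_inversion = stats::runif(1, cfg$foldback_bp, cfg$sv_small_bp - 1),
      small_deletion = , small_duplication =
        stats::runif(1, 500, cfg$sv_small_bp - 1),
      stats::runif(1, cfg$sv_small_bp, 2e7))
    ty <- if (grepl("deletion", cl)) "deletion"
          else if (grepl("duplication", cl)) "duplication" else "inversion"
    ch <- sample(build$chrom, 1)
    pos <- round(stats::runif(1, 1, chrom_length(build, ch) - size - 1))
    data.frame(chrom_a = ch, pos_a = pos, chrom_b = ch,
               pos_b = pos + round(size), sv_type = ty,
               stringsAsFactors = FALSE)
  })
  out <- if (n > 0) sv_pairs(do.call(rbind, rows)) else
    sv_pairs(data.frame(chrom_a = character(), pos_a = numeric(),
                        chrom_b = character(), pos_b = numeric(),
                        sv_type = character()))
  attr(out, "truth_classes") <- classes
  out
}

#' Simulate a full cohort
#'
#' Generates cases group by group with [simulate_case_variants()] and
#' [simulate_case_cn_sv()], then injects cohort-level artifacts: shared
#' recurrent non-hotspot variants placed in more than 20% of cases, the
#' panel-of-normals hit table and the panel batch-normal key list.
#' Reproducible: the same spec (including seed) yields an identical
#' cohort.
#'
#' @param spec a [cohort_spec()].
#' @param build a [genome_build()] (default hg19).
#' @return A [moc_cohort()] whose variant tables carry `truth` labels
#'   (invisible to the analysis functions) and whose `truth` element
#'   holds per-case archetypes and FGA targets.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            build = load_genome_build("hg19")) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  reference <- toy_reference(seed = spec$seed + 1000L)
  cpg <- .cpg_sites(reference)

  cases <- list()
  pon_keys <- character()
  batch_keys <- character()
  truth <- list()
  idx <- 0L
  for (grp in names(spec$n_per_group)) {
    for (i in seq_len(spec$n_per_group[[grp]])) {
      idx <- idx + 1L
      id <- sprintf("SIM%04d", idx)
      mode <- sample(names(spec$platform_probs), 1,
                     prob = spec$platform_probs)
      sv <- simulate_case_variants(grp, mode, spec, reference)
      cn <- simulate_case_cn_sv(grp, spec, build, sv$cn_events)
      pon_keys <- c(pon_keys, sv$registry$pon)
      batch_keys <- c(batch_keys, sv$registry$batch)
      cases[[id]] <- case_record(
        id, grp, mode, stage = cn$stage, time = cn$time, event = cn$event,
        variants = sv$variants, segments = cn$segments, svs = cn$svs)
      truth[[id]] <- c(cn$truth, list(cn_events = sv$cn_events))
    }
  }

  # cohort-recurrent artifact sites: same identity in > 20% of cases
  n_cases <- length(cases)
  n_rec <- max(ceiling(0.21 * n_cases) + 1L, 2L)
  for (s in seq_len(spec$recurrent_sites)) {
    chrom <- sample(names(reference), 1)
    zone <- .zone_recurrent(Biostrings::width(reference)[1])
    pos <- sample(zone[1]:zone[2], 1)
    ref <- .base_at(reference, chrom, pos)
    alt <- .other_base(ref)
    carriers <- sample(names(cases), min(n_rec, n_cases))
    for (id in carriers) {
      mode <- cases[[id]]$platform_mode
      v <- .base_variant(reference, cpg, mode, gene = "PSG1",
                         chrom = chrom, pos = pos)
      v$alt <- alt
      v$truth <- "artifact_recurrent"
      vt <- cases[[id]]$variants
      if (v$pos %in% vt$pos[vt$chrom == v$chrom]) next
      cases[[id]]$variants <- variant_calls(rbind(vt, v))
    }
  }

  pon <- if (length(pon_keys))
    data.frame(key = pon_keys, hits = 2L + stats::rpois(length(pon_keys), 1),
               stringsAsFactors = FALSE)
  else data.frame(key = character(), hits = integer())

  moc_cohort(cases, build = build, pon = pon,
             batch_normals = unique(batch_keys),
             blacklist = "HYDIN", reference = reference, truth = truth)
}
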