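test_that("site counts apply the quality rule and match a naive tally", {
  # 10 bases at one site, 2 below Q30 -> depth 8
  obs <- data.table(chrom = "chr1", pos = 100L, ref_base = "C",
                    obs_base = c(rep("C", 7), "T", "A", "G"),
                    base_quality = c(rep(37L, 8), 25L, 10L),
                    read_id = paste0("r", 1:10), mate = 1L, umi = "AAAA",
                    fragment_start = 1L, fragment_end = 200L,
                    fragment_strand = "+", dist_from_breakpoint = 1L)
  ct <- build_site_counts(obs, filter_config())
  expect_equal(ct$depth, 8L)
  expect_equal(ct$C, 7L)
  expect_equal(ct$T, 1L)
  expect_equal(ct$A + ct$G, 0L)
  # random observation sets equal the brute-force per-site tally
  for (seed in 1:3) {
    robs <- random_observations(500, n_pos = 25, seed = seed)
    got <- build_site_counts(robs, filter_config())
    want <- naive_site_counts(robs, 30L)
    expect_equal(got, want)
  }
  # N observed bases are excluded from numerator and denominator alike
  obsN <- copy(obs)[1, obs_base := "N"]
  expect_equal(build_site_counts(obsN, filter_config())$depth, 7L)
  expect_equal(nrow(build_site_counts(obs[0], filter_config())), 0)
})

pair_counts_fixture <- function(af_cf, af_g, depth = 1000L) {
  mk <- function(af) {
    alt <- as.integer(round(af * depth))
    data.table(chrom = "chr1", pos = 1L, ref_base = "C", depth = depth,
               A = 0L, C = depth - alt, G = 0L, T = alt, key = c("chrom", "pos"))
  }
  list(cf = mk(af_cf), g = mk(af_g))
}

test_that("an allele above 1% in either pair member is masked in both", {
  fc <- filter_config()
  x <- pair_counts_fixture(0.0, 0.30)
  mask <- apply_pairwise_variant_exclusion(x$cf, x$g, fc)
  expect_equal(mask[, .(chrom, pos, alt)],
               data.table(chrom = "chr1", pos = 1L, alt = "T",
                          key = c("chrom", "pos")))
  # masked allele is excluded from the error counts of both members
  p_cf <- compute_error_profile(x$cf, mask, fc, pair_counts = x$g)
  p_g <- compute_error_profile(x$g, mask, fc, pair_counts = x$cf)
  expect_equal(p_cf$error_counts[["C>T"]], 0)
  expect_equal(p_g$error_counts[["C>T"]], 0)
  # below threshold in both -> retained
  y <- pair_counts_fixture(0.009, 0.009)
  expect_equal(nrow(apply_pairwise_variant_exclusion(y$cf, y$g, fc)), 0)
  # other alt alleles at a masked site remain countable
  z <- pair_counts_fixture(0.0, 0.30)
  z$cf[1, `:=`(G = 2L, C = C - 2L)]
  mask_z <- apply_pairwise_variant_exclusion(z$cf, z$g, fc)
  p_z <- compute_error_profile(z$cf, mask_z, fc, pair_counts = z$g)
  expect_equal(p_z$error_counts[["C>G"]], 2)
  expect_equal(p_z$error_counts[["C>T"]], 0)
})

test_that("blacklisted variants are masked like germline alleles", {
  fc <- filter_config(variant_blacklist = data.frame(
    chrom = "chr1", pos = 1L, alt = "G"))
  x <- pair_counts_fixture(0.0, 0.0)
  x$cf[1, `:=`(G = 3L, C = C - 3L)]
  mask <- apply_pairwise_variant_exclusion(x$cf, x$g, fc)
  expect_true("blacklist" %in% mask$source)
  p <- compute_error_profile(x$cf, mask, fc, pair_counts = x$g)
  expect_equal(p$error_counts[["C>G"]], 0)
})

test_that("planted germline variants are exactly the masked alleles", {
  cfg <- sim_config(mode = "counts", seed = 17, panel_bp = 8000,
                    depth = 1000, n_pairs = 2, germline_n_het = 60,
                    germline_n_hom = 15)
  sim <- simulate_counts(cfg)
  fc <- filter_config()
  mask <- apply_pairwise_variant_exclusion(sim$counts$cf_1, sim$counts$g_1, fc)
  planted <- sim$ledger$germline[, .(chrom, pos, alt)]
  expect_equal(nrow(mask), 75)
  expect_equal(merge(mask, planted, by = c("chrom", "pos", "alt"))[, .N], 75)
})

test_that("error profiles follow the single-site arithmetic examples", {
  fc <- filter_config()
  ct <- data.table(chrom = "chr1", pos = 1L, ref_base = "C", depth = 1000L,
                   A = 0L, C = 999L, G = 0L, T = 1L, key = c("chrom", "pos"))
  p <- compute_error_profile(ct, NULL, fc, sample_id = "s")
  expect_equal(p$rates[["C>T"]], 1e-3)
  expect_equal(p$total_rate, 1e-3)
  expect_equal(p$eligible_bases[["C"]], 1000)
  # all-reference table: all 12 rates zero where defined, total zero
  ct0 <- data.table(chrom = "chr1", pos = 1:4, ref_base = c("A", "C", "G", "T"),
                    depth = 1000L, A = c(1000L, 0L, 0L, 0L),
                    C = c(0L, 1000L, 0L, 0L), G = c(0L, 0L, 1000L, 0L),
                    T = c(0L, 0L, 0L, 1000L), key = c("chrom", "pos"))
  p0 <- compute_error_profile(ct0, NULL, fc)
  expect_true(all(p0$rates == 0))
  expect_equal(p0$total_rate, 0)
  # a 499x site is present in counts but ineligible for profiling
  ct499 <- copy(ct)[1, `:=`(depth = 499L, C = 498L)]
  p499 <- compute_error_profile(ct499, NULL, fc)
  expect_equal(sum(p499$eligible_bases), 0)
  expect_true(is.na(p499$total_rate))
})

test_that("depth eligibility is evaluated jointly across the pair", {
  fc <- filter_config(min_depth = 500L)
  ct_a <- data.table(chrom = "chr1", pos = 1:2, ref_base = "C",
                     depth = c(600L, 600L), A = 0L, C = c(599L, 600L),
                     G = 0L, T = c(1L, 0L), key = c("chrom", "pos"))
  ct_b <- copy(ct_a)[2, depth := 450L]
  p <- compute_error_profile(ct_a, NULL, fc, pair_counts = ct_b)
  expect_equal(sum(p$eligible_bases), 600)  # position 2 dropped jointly
  expect_equal(p$error_counts[["C>T"]], 1)
})

test_that("planted class rates are recovered within 3 binomial SE", {
  cfg <- sim_config(mode = "counts", seed = 5, panel_bp = 30000,
                    depth = 1000, n_pairs = 3)
  sim <- simulate_counts(cfg)
  fc <- filter_config()
  for (grp in c("cfDNA", "gDNA")) {
    ids <- sim$meta[sample_type == grp]$sample_id
    profs <- lapply(ids, function(sid)
      compute_error_profile(sim$counts[[sid]], NULL, fc, sample_id = sid))
    rates <- sim$ledger$class_rates[[grp]]
    pooled_counts <- Reduce(`+`, lapply(profs, `[[`, "error_counts"))
    pooled_elig <- Reduce(`+`, lapply(profs, `[[`, "eligible_bases"))
    for (cls in SUBSTITUTION_CLASSES) {
      n <- pooled_elig[[substr(cls, 1, 1)]]
      se <- sqrt(rates[cls] * (1 - rates[cls]) / n)
      expect_lt(abs(pooled_counts[[cls]] / n - rates[cls]), 3 * se + 1e-12)
    }
  }
})

test_that("error-free fraction follows the toy and analytic expectations", {
  fc <- filter_config()
  ct0 <- data.table(chrom = "chr1", pos = 1:4, ref_base = "C", depth = 1000L,
                    A = 0L, C = 1000L, G = 0L, T = 0L, key = c("chrom", "pos"))
  expect_equal(error_free_fraction(ct0, NULL, fc), 100)
  ct1 <- copy(ct0)[2, `:=`(T = 1L, C = 999L)]
  expect_equal(error_free_fraction(ct1, NULL, fc), 75)
  expect_true(is.na(error_free_fraction(ct0[0], NULL, fc)))
  # simulated fraction near the binomial-thinning expectation
  cfg <- sim_config(mode = "counts", seed = 9, panel_bp = 20000,
                    depth = 1000, n_pairs = 1)
  sim <- simulate_counts(cfg)
  eff <- error_free_fraction(sim$counts$g_1, NULL, fc)
  # per position: P(no error) = prod over 3 classes of (1-r)^depth
  p_free <- (1 - 9e-6)^(3 * 1000)
  se <- sqrt(p_free * (1 - p_free) / 20000)
  expect_lt(abs(eff / 100 - p_free), 3 * se)
})

test_that("position tables share one eligibility mask and reconcile totals", {
  fc <- filter_config()
  ct1 <- data.table(chrom = "chr1", pos = 1:3, ref_base = "C",
                    depth = c(1000L, 1000L, 1000L), A = 0L,
                    C = c(999L, 1000L, 998L), G = 0L, T = c(1L, 0L, 2L),
                    key = c("chrom", "pos"))
  ct2 <- copy(ct1)[3, depth := 400L]
  tab <- position_error_table(list(s1 = ct1, s2 = ct2), NULL, fc)
  # position 3 ineligible in s2 -> absent for all samples
  expect_false(3L %in% tab$pos)
  expect_equal(tab[sample_id == "s1" & pos == 1L & class == "C>T"]$rate, 1e-3)
  expect_equal(tab[sample_id == "s1" & pos == 1L & class == "total"]$rate, 1e-3)
  # row sums reconcile with compute_error_profile on the same mask
  prof <- compute_error_profile(ct1, NULL, fc, pair_counts = ct2)
  expect_equal(sum(tab[sample_id == "s1" & class != "total"]$errors),
               sum(prof$error_counts))
})

test_that("single-sample, single-site position table equals the site rate", {
  fc <- filter_config(min_depth = 10L)
  ct <- data.table(chrom = "chr1", pos = 7L, ref_base = "G", depth = 100L,
                   A = 5L, C = 0L, G = 95L, T = 0L, key = c("chrom", "pos"))
  tab <- position_error_table(list(only = ct), NULL, fc)
  expect_equal(tab[class == "G>A"]$rate, 0.05)
  expect_equal(nrow(tab[class %in% c("G>C", "G>T")][rate != 0]), 0)
})

test_that("fragment-bin profiles put planted end errors in bin 1", {
  set.seed(3)
  n <- 4000
  obs <- data.table(chrom = "chr1",
                    pos = rep(1:80, length.out = n),
                    ref_base = "C", obs_base = "C", base_quality = 37L,
                    read_id = paste0("r", seq_len(n)), mate = 1L,
                    umi = "AAAA", fragment_start = 1L, fragment_end = 200L,
                    fragment_strand = "+",
                    dist_from_breakpoint = sample.int(60L, n, replace = TRUE))
  # plant all errors at breakpoint distances 1-5
  err_rows <- which(obs$dist_from_breakpoint <= 5)[1:30]
  obs[err_rows, obs_base := "A"]
  fc <- filter_config(min_depth = 10L)
  bp <- fragment_bin_profile(obs, NULL, fc, sample_id = "s")
  expect_equal(sum(bp$bin_counts[1, "C>A"]), 30)
  expect_equal(sum(bp$bin_counts[2:10, ]), 0)
  # bases beyond 50 bp are outside the bins
  expect_equal(sum(bp$bin_eligible_bases),
               nrow(obs[dist_from_breakpoint <= 50]))
  # rates recompute exactly from counts / eligible bases
  expect_equal(bp$bin_rates[1, "C>A"],
               bp$bin_counts[1, "C>A"] / bp$bin_eligible_bases[1, "C"])
})

test_that("uniform error rates give statistically flat bins", {
  cfg <- sim_config(mode = "reads", seed = 13, panel_bp = 2000, n_pairs = 1,
                    n_fragments = 8000, umi_mean_progeny = 1,
                    rates_cfdna = setNames(rep(4e-4, 12), SUBSTITUTION_CLASSES),
                    end_effect = NULL)
  sim <- simulate_reads(cfg, tempfile("flatbins"))
  panel <- load_panel(sim$panel_bed)
  obs <- stream_observations(sim$samples$bam[1], panel, sim$reference)
  fc <- filter_config()
  bp <- fragment_bin_profile(obs, NULL, fc, sample_id = "cf_1")
  tot_rate <- rowSums(bp$bin_counts) / rowSums(bp$bin_eligible_bases)
  overall <- sum(bp$bin_counts) / sum(bp$bin_eligible_bases)
  se <- sqrt(overall / rowSums(bp$bin_eligible_bases))
  expect_true(all(abs(tot_rate - overall) < 4 * se))
  unlink(sim$dir, recursive = TRUE)
})

test_that("conservation: errors + reference + masked depth add up", {
  cfg <- sim_config(mode = "counts", seed = 23, panel_bp = 5000,
                    depth = 800, n_pairs = 1, germline_n_het = 25)
  sim <- simulate_counts(cfg)
  fc <- filter_config(min_depth = 500L)
  mask <- apply_pairwise_variant_exclusion(sim$counts$cf_1, sim$counts$g_1, fc)
  prof <- compute_error_profile(sim$counts$cf_1, mask, fc,
                                pair_counts = sim$counts$g_1)
  ct <- sim$counts$cf_1
  refd <- sum(as.matrix(ct[, .(A, C, G, T)])[
    cbind(seq_len(nrow(ct)), match(ct$ref_base, c("A", "C", "G", "T")))])
  masked_depth <- sum(apply(merge(ct, mask, by = c("chrom", "pos")), 1,
                            function(r) as.integer(r[[r[["alt"]]]])))
  expect_equal(sum(prof$error_counts) + refd + masked_depth,
               sum(as.numeric(ct$depth)))
})

test_that("raising quality or depth thresholds never gains eligible bases", {
  cfg <- sim_config(mode = "reads", seed = 29, panel_bp = 1500, n_pairs = 1,
                    n_fragments = 2500, seq_error_rate = 2e-4)
  sim <- simulate_reads(cfg, tempfile("mono"))
  panel <- load_panel(sim$panel_bed)
  obs <- stream_observations(sim$samples$bam[1], panel, sim$reference)
  elig_at <- function(minq, mind) {
    fc <- filter_config(min_base_quality = minq, min_depth = mind)
    sum(compute_error_profile(build_site_counts(obs, fc), NULL, fc)$eligible_bases)
  }
  base <- elig_at(30L, 500L)
  expect_lte(elig_at(40L, 500L), base)
  expect_lte(elig_at(30L, 1000L), base)
  expect_lte(elig_at(40L, 1000L), min(elig_at(40L, 500L), elig_at(30L, 1000L)))
  unlink(sim$dir, recursive = TRUE)
})

test_that("excluding positions never changes rates at untouched positions", {
  cfg <- sim_config(mode = "counts", seed = 37, panel_bp = 4000,
                    depth = 1000, n_pairs = 1)
  sim <- simulate_counts(cfg)
  fc <- filter_config()
  drop <- data.table(chrom = "panel1", pos = sample(4000, 200))
  p_all <- compute_error_profile(sim$counts$cf_1, NULL, fc)
  p_excl <- compute_error_profile(sim$counts$cf_1, NULL, fc,
                                  exclude_positions = drop)
  # counts on the complement equal full counts minus the dropped sites
  ct <- sim$counts$cf_1
  dropped <- ct[drop, on = c("chrom", "pos"), nomatch = 0L]
  for (cls in SUBSTITUTION_CLASSES) {
    dsub <- dropped[ref_base == substr(cls, 1, 1)]
    expect_equal(p_excl$error_counts[[cls]],
                 p_all$error_counts[[cls]] - sum(dsub[[substr(cls, 3, 3)]]))
  }
})
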