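make_sites <- function(ids, positions, residue = "K") {
  structure(data.frame(protein_id = ids, position = as.integer(positions),
                       residue = residue, modification = "ac-K"),
            class = c("AcetylationSiteTable", "data.frame"))
}

test_that("sites map into regions; non-lysines are quarantined, not dropped", {
  # lysine at 324 inside the MIR, arginine at 100, lysine at 450 beyond the
  # domain, lysine at 40 in the NBR
  ch <- rep("A", 500)
  ch[c(324, 40, 450)] <- "K"; ch[100] <- "R"
  rec <- domain_record("EHD2", paste(ch, collapse = ""), "EHD", c(20, 440))
  ann <- region_annotation(c(20, 440), intervals(300, 360))
  sites <- make_sites("EHD2", c(324, 100, 450, 40),
                      residue = c("K", "R", "K", "K"))
  flags <- map_sites_to_domain(rec, ann, sites)
  expect_equal(flags$acetyl_pos, c(40L, 324L))
  expect_equal(flags$outside_pos, 450L)
  expect_equal(flags$quarantined$position, 100L)
  expect_match(flags$quarantined$reason, "non-lysine")
  expect_equal(flags$n_input, 4L)

  counts <- count_regions(rec, ann, flags)
  expect_equal(counts["MIR", "n_ack"], 1L)
  expect_equal(counts["NBR", "n_ack"], 1L)

  # a site whose stated residue disagrees with the sequence is quarantined
  bad <- make_sites("EHD2", 100, residue = "K")  # sequence holds R
  fb <- map_sites_to_domain(rec, ann, bad)
  expect_match(fb$quarantined$reason, "mismatch")

  # conservation: in-domain + outside + quarantined = input rows
  expect_equal(length(flags$acetyl_pos) + length(flags$outside_pos) +
                 nrow(flags$quarantined), flags$n_input)
})

test_that("region counts conserve the domain partition", {
  set.seed(81)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:20) {
    n <- sample(50:150, 1)
    seqs <- random_aa(n, aa20)
    rec <- domain_record(paste0("P", k), seqs, "PX")
    a <- sort(sample(n, 2))
    ann <- region_annotation(c(1, n), intervals(a[1], a[2]))
    kpos <- which(strsplit(seqs, "")[[1]] == "K")
    hit <- if (length(kpos))
      sort(kpos[sample.int(length(kpos), min(3, length(kpos)))])
    else integer()
    sites <- if (length(hit)) make_sites(paste0("P", k), hit) else
      make_sites(character(), integer())
    flags <- map_sites_to_domain(rec, ann, sites)
    cts <- count_regions(rec, ann, flags)
    expect_equal(sum(cts$n_residues), n)
    expect_equal(sum(cts$n_lysines), length(kpos))
    expect_equal(sum(cts$n_ack), length(hit))
    # naive per-residue recomputation agrees
    lab <- ifelse(seq_len(n) %in% a[1]:a[2], "MIR", "NBR")
    for (rg in c("MIR", "NBR")) {
      expect_equal(cts[rg, "n_lysines"],
                   sum(lab == rg & strsplit(seqs, "")[[1]] == "K"))
      expect_equal(cts[rg, "n_ack"], sum(lab[hit] == rg))
    }
  }
})

test_that("frequencies follow the two normalizations; zero denominators flag ratios", {
  cts <- mirenrich:::region_counts(c(100, 10, 3), c(200, 20, 2))
  st <- frequency_stats(cts)
  expect_equal(st$pct_kac_mir, 3)
  expect_equal(st$pct_kac_per_k_mir, 30)
  expect_equal(st$pct_kac_nbr, 1)
  expect_equal(st$pct_kac_per_k_nbr, 10)
  expect_equal(st$ratio_kac, 3)
  expect_equal(st$ratio_kac_per_k, 3)
  expect_false(st$ratio_kac_undefined)

  zero_nbr <- mirenrich:::region_counts(c(100, 10, 3), c(200, 20, 0))
  st0 <- frequency_stats(zero_nbr)
  expect_true(st0$ratio_kac_undefined)
  expect_true(is.na(st0$ratio_kac))

  empty <- mirenrich:::region_counts(c(100, 10, 3), c(0, 0, 0))
  ste <- frequency_stats(empty)
  expect_true(is.na(ste$pct_kac_nbr))
  expect_true(ste$ratio_kac_undefined)
})

test_that("rounding goes half away from zero at the printed precision", {
  expect_equal(round_half_up(2.0918, 1), 2.1)
  expect_equal(round_half_up(4.6478, 2), 4.65)
  expect_equal(round_half_up(1.0, 1), 1.0)
  expect_equal(round_half_up(2.05, 1), 2.1)   # banker's rounding would give 2.0
  expect_equal(round_half_up(-2.05, 1), -2.1)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("domain classification uses raw counts for majority and exclusivity", {
  cls <- function(m, n)
    classify_domain(mirenrich:::region_counts(c(50, 5, m), c(50, 5, n)))
  expect_equal(cls(3, 0), list_of <- structure(
    list(majority = "MIR_majority", exclusivity = "MIR_only"),
    class = "DomainClass"))
  expect_equal(cls(2, 2)$majority, "tie")
  expect_equal(cls(2, 2)$exclusivity, "mixed")
  expect_equal(cls(1, 2)$majority, "NBR_majority")
  expect_equal(cls(1, 2)$exclusivity, "mixed")
  expect_equal(cls(0, 0)$majority, "tie")
  expect_equal(cls(0, 0)$exclusivity, "none")
  expect_equal(cls(0, 4)$exclusivity, "NBR_only")
})

test_that("family aggregation pools counts before normalizing", {
  d1 <- counts_fixture(c(100, 10, 3), c(200, 20, 2))
  fs <- aggregate_family(list(d1, d1), "BAR")
  st <- fs$pooled_stats
  # pooling two identical domains leaves frequencies unchanged
  expect_equal(st$pct_kac_mir, 3)
  expect_equal(st$pct_kac_per_k_mir, 30)

  # 4 domains: 3 MIR-majority, 1 tie (with sites)
  maj <- counts_fixture(c(50, 5, 2), c(50, 5, 0))
  tie <- counts_fixture(c(50, 5, 1), c(50, 5, 1))
  fs2 <- aggregate_family(list(maj, maj, maj, tie), "PX")
  expect_equal(fs2$fraction_mir_majority, 0.75)
  expect_equal(fs2$n_ties, 1L)

  # pooled grand summary weights by counts, not by family means:
  # a big family at low enrichment and a tiny one at high enrichment
  big <- counts_fixture(c(1000, 100, 10), c(1000, 100, 10))   # ratio 1
  small <- counts_fixture(c(10, 5, 4), c(10, 5, 1))           # ratio 4
  pooled <- aggregate_family(list(big, small), "Average")
  mean_of_ratios <- mean(c(1, 4))
  pooled_ratio <- pooled$pooled_stats$ratio_kac
  expect_equal(pooled_ratio, ((10 + 4) / 1010) / ((10 + 1) / 1010))
  expect_false(isTRUE(all.equal(pooled_ratio, mean_of_ratios)))
})

test_that("adding a MIR site never decreases the enrichment ratio", {
  set.seed(91)
  for (k in 1:30) {
    nk_m <- sample(3:10, 1); nk_n <- sample(3:10, 1)
    ack_m <- sample(0:(nk_m - 1), 1); ack_n <- sample(1:nk_n, 1)
    st0 <- frequency_stats(mirenrich:::region_counts(
      c(50, nk_m, ack_m), c(60, nk_n, ack_n)))
    st1 <- frequency_stats(mirenrich:::region_counts(
      c(50, nk_m, ack_m + 1), c(60, nk_n, ack_n)))
    expect_gte(st1$ratio_kac, st0$ratio_kac)
    expect_gte(st1$ratio_kac_per_k, st0$ratio_kac_per_k)
  }
})

test_that("the sensitivity sweep reproduces the base run at delta 0", {
  spec <- synthetic_family_spec(n_domains = 8, domain_length = 120,
                                mir_intervals = intervals(c(20, 70),
                                                          c(40, 95)),
                                rho = 5, seed = 95)
  fam <- generate_family(spec)
  domains <- lapply(fam$members, function(m)
    list(record = m$record, annotation = m$annotation, family = "SYN"))
  sw <- sensitivity_sweep(domains, fam$sites, deltas = -2:2)
  base <- aggregate_family(lapply(fam$members, function(m)
    mirenrich:::analyze_domain(m$record, m$annotation, fam$sites)), "SYN")
  row0 <- sw[sw$delta == 0 & sw$family == "SYN", ]
  expect_identical(row0$mir_ack, base$pooled_counts["MIR", "n_ack"])
  expect_identical(row0$ratio_kac, base$pooled_stats$ratio_kac)
  expect_identical(row0$pct_kac_per_k_mir,
                   base$pooled_stats$pct_kac_per_k_mir)
  # planted enrichment persists across every delta
  expect_true(all(sw$ratio_kac[sw$family == "SYN"] > 1))

  # an all-MIR annotation cannot grow: positive deltas identical
  all_mir <- lapply(fam$members[1:2], function(m) list(
    record = m$record,
    annotation = region_annotation(m$record$domain_range,
                                   intervals(m$record$domain_range[1],
                                             m$record$domain_range[2])),
    family = "SYN"))
  sw2 <- sensitivity_sweep(all_mir, fam$sites, deltas = 0:2)
  syn <- sw2[sw2$family == "SYN", ]
  syn$delta <- NULL
  for (col in names(syn)) {
    expect_identical(syn[[col]][1], syn[[col]][2], label = col)
    expect_identical(syn[[col]][1], syn[[col]][3], label = col)
  }
})

test_that("permutation p-values match the exact hypergeometric tail", {
  # all lysines acetylated: statistic constant, p = 1
  allk <- mirenrich:::region_counts(c(10, 4, 4), c(10, 6, 6))
  expect_equal(permutation_enrichment_test(allk, 500, seed = 3)$p_value, 1)

  # MIR 2/2, NBR 0/8: exact tail P(X >= 2), X ~ Hypergeom(2 of 10 drawn 2)
  cts <- mirenrich:::region_counts(c(10, 2, 2), c(40, 8, 0))
  exact <- phyper(1, 2, 8, 2, lower.tail = FALSE)
  p <- permutation_enrichment_test(cts, 20000, seed = 11)$p_value
  expect_equal(p, exact, tolerance = 0.25)

  # random two-region toys with <= 12 lysines
  set.seed(13)
  for (k in 1:8) {
    km <- sample(1:6, 1); kn <- sample(1:6, 1)
    am <- sample(0:km, 1); an <- sample(0:kn, 1)
    if (am + an == 0) am <- 1
    cts <- mirenrich:::region_counts(c(20, km, am), c(20, kn, an))
    exact <- phyper(am - 1, km, kn, am + an, lower.tail = FALSE)
    p <- permutation_enrichment_test(cts, 4000, seed = k)$p_value
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(p - exact), 4 * se + 2 / 4000)
  }

  # determinism and guards
  p1 <- permutation_enrichment_test(cts, 500, seed = 21)$p_value
  p2 <- permutation_enrichment_test(cts, 500, seed = 21)$p_value
  expect_identical(p1, p2)
  nolys <- mirenrich:::region_counts(c(10, 0, 0), c(10, 0, 0))
  expect_error(permutation_enrichment_test(nolys, 500), "no lysines")
  expect_error(permutation_enrichment_test(cts, 50), "n_perm")
})
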