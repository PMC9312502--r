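one_taxon_scores <- bip_scores(data.frame(
  taxon = "Arenicola marina",
  ft_diff = 2, bt_diff = 2, l_diff = 3,
  ft_adv = 3, bt_adv = 1, l_adv = 2,
  m_bpc = 3, r_bpc = 3))

one_taxon_sample <- function(a, b, depth = NA_real_) {
  community_sample("S1", "2018-04-01",
                   data.frame(taxon = "Arenicola marina", abundance = a,
                              biomass_afdw = b, depth_measured = depth))
}

test_that("BIPc evaluates the index formula directly", {
  res <- bipc(one_taxon_sample(100, 2), one_taxon_scores, "diffusive")
  expect_equal(res$bipc, (2 / 100) * 100 * 2 * 2 * 3)  # = 24
  expect_equal(res$bipc, 24)
  # advective scores switch the score product
  expect_equal(bipc(one_taxon_sample(100, 2), one_taxon_scores,
                    "advective")$bipc, 2 * 3 * 1 * 2)
  expect_error(bipc(one_taxon_sample(100, 2), one_taxon_scores, "muddy"),
               "unknown system")
})

test_that("BPc evaluates its square-root-weighted formula directly", {
  out <- bpc(one_taxon_sample(100, 4), one_taxon_scores)
  expect_equal(out$value, sqrt(4 / 100) * 100 * 3 * 3)  # = 180
  expect_equal(out$value, 180)
  sc0 <- one_taxon_scores
  sc0$m_bpc <- 0
  expect_equal(bpc(one_taxon_sample(100, 4), sc0)$value, 0)
})

test_that("a zero trait score forces a zero contribution regardless of biomass", {
  sc <- one_taxon_scores
  sc$bt_diff <- 0  # epifauna
  expect_equal(bipc(one_taxon_sample(100, 500), sc, "diffusive")$bipc, 0)
  expect_gt(bipc(one_taxon_sample(100, 500), sc, "advective")$bipc, 0)
})

test_that("the index is additive over taxa", {
  scores <- random_scores(10, seed = 42, zero_frac = 0)
  rec <- data.frame(taxon = scores$taxon[1:2], abundance = c(50, 80),
                    biomass_afdw = c(1.5, 0.4))
  both <- community_sample("S", "2020-01-01", rec)
  s1 <- community_sample("S", "2020-01-01", rec[1, ])
  s2 <- community_sample("S", "2020-01-01", rec[2, ])
  expect_equal(bipc(both, scores, "diffusive")$bipc,
               bipc(s1, scores, "diffusive")$bipc +
                 bipc(s2, scores, "diffusive")$bipc)
})

test_that("zero-abundance records contribute zero without 0/0", {
  rec <- data.frame(taxon = "Arenicola marina", abundance = 0,
                    biomass_afdw = 0)
  res <- bipc(community_sample("S", "2020-01-01", rec),
              one_taxon_scores, "diffusive")
  expect_identical(res$bipc, 0)
  expect_false(anyNA(res$contributions))
})

test_that("unscored taxa are excluded and diagnosed, never imputed", {
  rec <- data.frame(taxon = c("Arenicola marina", "Nobody knowsii"),
                    abundance = c(10, 10), biomass_afdw = c(1, 1))
  res <- bipc(community_sample("S", "2020-01-01", rec),
              one_taxon_scores, "diffusive")
  expect_equal(res$unscored_taxa, "Nobody knowsii")
  expect_equal(res$coverage_abundance_pct, 50)
  expect_equal(res$coverage_biomass_pct, 50)
  # all-unscored sample: zero with a warning, not an error
  rec2 <- data.frame(taxon = "Nobody knowsii", abundance = 5,
                     biomass_afdw = 1)
  expect_warning(res2 <- bipc(community_sample("S", "2020-01-01", rec2),
                              one_taxon_scores, "diffusive"),
                 "score table")
  expect_identical(res2$bipc, 0)
})

test_that("vectorized engine equals the brute-force loop oracle", {
  scores <- random_scores(60, seed = 1)
  for (seed in 1:25) {
    s <- random_sample(scores, seed = seed)
    res <- suppressWarnings(bipc(s, scores, "diffusive"))
    expect_equal(res$bipc, oracle_bipc(s, scores, "diffusive"),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(bipc(s, scores, "advective"))$bipc,
                 oracle_bipc(s, scores, "advective"), tolerance = 1e-12)
    expect_equal(bpc(s, scores)$value, oracle_bpc(s, scores),
                 tolerance = 1e-12)
    expect_equal(sum(res$contributions), res$bipc)
  }
})

test_that("abundance cancels algebraically and the index is linear in biomass", {
  scores <- random_scores(40, seed = 7, zero_frac = 0.2)
  for (seed in 1:10) {
    s <- random_sample(scores, seed = 100 + seed, zero_abundance_frac = 0)
    res <- suppressWarnings(bipc(s, scores, "diffusive"))
    idx <- match(normalize_taxon(s$records$taxon),
                 normalize_taxon(scores$taxon))
    keep <- !is.na(idx)
    direct <- sum(s$records$biomass_afdw[keep] * scores$ft_diff[idx[keep]] *
                    scores$bt_diff[idx[keep]] * scores$l_diff[idx[keep]])
    expect_equal(res$bipc, direct, tolerance = 1e-12)
    # biomass homogeneity: scaling all B by c scales BIPc by c
    s2 <- s
    s2$records$biomass_afdw <- s$records$biomass_afdw * 3.7
    expect_equal(suppressWarnings(bipc(s2, scores, "diffusive"))$bipc,
                 3.7 * res$bipc, tolerance = 1e-12)
    # abundance at fixed biomass leaves BIPc unchanged, scales BPc by
    # the square-root law
    s3 <- s
    pos <- s$records$abundance > 0
    s3$records$abundance[pos] <- s$records$abundance[pos] * 4
    expect_equal(suppressWarnings(bipc(s3, scores, "diffusive"))$bipc,
                 res$bipc, tolerance = 1e-12)
    expect_equal(bpc(s3, scores)$value, 2 * bpc(s, scores)$value,
                 tolerance = 1e-12)
  }
})

test_that("system switching matters iff a present taxon has differing products", {
  sc <- random_scores(10, seed = 3, zero_frac = 0)
  # force identical products for taxon 1, different for taxon 2
  sc$ft_adv[1] <- sc$ft_diff[1]; sc$bt_adv[1] <- sc$bt_diff[1]
  sc$l_adv[1] <- sc$l_diff[1]
  sc$ft_adv[2] <- sc$ft_diff[2] + 1
  same <- community_sample("S", "2020-01-01",
                           data.frame(taxon = sc$taxon[1], abundance = 10,
                                      biomass_afdw = 1))
  diff <- community_sample("S", "2020-01-01",
                           data.frame(taxon = sc$taxon[2], abundance = 10,
                                      biomass_afdw = 1))
  expect_equal(bipc(same, sc, "diffusive")$bipc,
               bipc(same, sc, "advective")$bipc)
  expect_false(bipc(diff, sc, "diffusive")$bipc ==
                 bipc(diff, sc, "advective")$bipc)
})

test_that("aggregate coverage matches direct summation and complements to 100", {
  scores <- random_scores(120, seed = 11)
  samples <- lapply(1:6, function(k) random_sample(scores, seed = 200 + k,
                                                   unscored_frac = 0.25))
  cov <- coverage(samples, scores)
  tot_a <- sc_a <- tot_b <- sc_b <- 0
  for (s in samples) {
    for (i in seq_len(nrow(s$records))) {
      hit <- any(norm_name(scores$taxon) == norm_name(s$records$taxon[i]))
      tot_a <- tot_a + s$records$abundance[i]
      tot_b <- tot_b + s$records$biomass_afdw[i]
      if (hit) {
        sc_a <- sc_a + s$records$abundance[i]
        sc_b <- sc_b + s$records$biomass_afdw[i]
      }
    }
  }
  expect_equal(cov$coverage_abundance_pct, 100 * sc_a / tot_a)
  expect_equal(cov$coverage_biomass_pct, 100 * sc_b / tot_b)
  # scored + unscored = 100 exactly
  unsc_a <- 100 * (tot_a - sc_a) / tot_a
  expect_equal(cov$coverage_abundance_pct + unsc_a, 100)
  # all scored -> (100, 100); empty biomass -> undefined, not 0
  all_scored <- lapply(1:2, function(k)
    random_sample(scores, seed = 300 + k, unscored_frac = 0))
  cov2 <- coverage(all_scored, scores)
  expect_equal(cov2$coverage_abundance_pct, 100)
  expect_equal(cov2$coverage_biomass_pct, 100)
  empty <- community_sample("E", "2020-01-01", data.frame())
  expect_true(is.na(coverage(list(empty), scores)$coverage_biomass_pct))
})

test_that("key-species shares sum to 100 per group with alphabetical ties", {
  scores <- random_scores(20, seed = 5, zero_frac = 0)
  single <- community_sample("S", "2020-01-01",
                             data.frame(taxon = scores$taxon[1],
                                        abundance = 10, biomass_afdw = 1))
  ks <- key_species(list(single), scores, "diffusive")
  expect_equal(ks$share_pct, 100)
  # equal contributions tie -> alphabetical order, 50/50
  sc2 <- bip_scores(data.frame(taxon = c("Zeta sp", "Alpha sp"),
                               ft_diff = 1, bt_diff = 1, l_diff = 1,
                               ft_adv = 1, bt_adv = 1, l_adv = 1,
                               m_bpc = 1, r_bpc = 1))
  s2 <- community_sample("S", "2020-01-01",
                         data.frame(taxon = c("Zeta sp", "Alpha sp"),
                                    abundance = c(10, 10),
                                    biomass_afdw = c(1, 1)))
  ks2 <- key_species(list(s2), sc2, "diffusive")
  expect_equal(ks2$taxon, c("Alpha sp", "Zeta sp"))
  expect_equal(ks2$share_pct, c(50, 50))
  # grouped ranking equals brute-force group sums
  samples <- lapply(1:8, function(k) random_sample(scores, seed = 400 + k,
                                                   unscored_frac = 0))
  groups <- rep(c("mud", "fine sand"), each = 4)
  ks3 <- key_species(samples, scores, "diffusive", groups = groups)
  for (g in c("mud", "fine sand", "overall")) {
    sub <- ks3[ks3$group == g, ]
    expect_equal(sum(sub$share_pct), 100, tolerance = 1e-9)
    expect_true(all(diff(sub$share_pct) <= 1e-12))
    keep <- if (g == "overall") seq_along(samples) else which(groups == g)
    manual <- numeric(0)
    for (k in keep) {
      cb <- bipc(samples[[k]], scores, "diffusive")$contributions
      for (tx in names(cb)) {
        manual[tx] <- (if (tx %in% names(manual)) manual[[tx]] else 0) +
          cb[[tx]]
      }
    }
    expect_setequal(sub$taxon, names(manual))
    expect_equal(sub$contribution, unname(manual[sub$taxon]),
                 tolerance = 1e-9)
  }
})

test_that("layer restriction uses the closed-lower half-open-upper convention", {
  sc <- one_taxon_scores
  mk <- function(depth) one_taxon_sample(100, 2, depth = depth)
  expect_equal(layer_index(mk(5), sc, "diffusive", c(2, 10))$bipc, 24)
  expect_equal(layer_index(mk(1), sc, "diffusive", c(2, 10))$bipc, 0)
  expect_equal(layer_index(mk(2), sc, "diffusive", c(2, 10))$bipc, 24)
  expect_equal(layer_index(mk(10), sc, "diffusive", c(2, 10))$bipc, 0)
  expect_error(layer_index(mk(NA), sc, "diffusive", c(2, 10)),
               "whole-core")
})

test_that("depth-profile slices conserve the whole-core index", {
  sc <- one_taxon_scores
  sc$lit_depth_cm <- 20
  all3 <- one_taxon_sample(100, 2, depth = 3)
  prof <- depth_profile(all3, sc, "diffusive", slice_cm = 2)
  expect_equal(prof$slices$bipc[prof$slices$top == 2], 24)
  expect_equal(sum(prof$slices$bipc), prof$whole_core)
  scores <- random_scores(40, seed = 9)
  for (seed in 1:10) {
    s <- random_sample(scores, seed = 500 + seed, unscored_frac = 0)
    for (mode in c("measured", "theoretical")) {
      p <- depth_profile(s, scores, "diffusive", slice_cm = 2, mode = mode)
      expect_equal(sum(p$slices$bipc) + p$excluded_contribution,
                   p$whole_core, tolerance = 1e-12)
      expect_equal(p$excluded_contribution, 0)
      expect_true(all(diff(p$slices$top) > 0))
    }
  }
})

test_that("theoretical depths place contribution at or below measured depths", {
  scores <- random_scores(40, seed = 13, zero_frac = 0)
  # measured depths drawn strictly above the sediment surface but below
  # each taxon's literature depth
  for (seed in 1:5) {
    s <- random_sample(scores, seed = 600 + seed, unscored_frac = 0)
    idx <- match(normalize_taxon(s$records$taxon),
                 normalize_taxon(scores$taxon))
    lit <- scores$lit_depth_cm[idx]
    s$records$depth_measured <- runif(nrow(s$records), 0, lit)
    pm <- depth_profile(s, scores, "diffusive", 2, mode = "measured")
    pt <- depth_profile(s, scores, "diffusive", 2, mode = "theoretical")
    # per-taxon: slice of the theoretical depth is >= slice of measured
    km <- floor(s$records$depth_measured / 2)
    kt <- floor(lit / 2)
    expect_true(all(kt >= km))
    # cumulative mass of the theoretical profile lags the measured one
    n <- max(nrow(pm$slices), nrow(pt$slices))
    cm <- cumsum(c(pm$slices$bipc, rep(0, n - nrow(pm$slices))))
    ct <- cumsum(c(pt$slices$bipc, rep(0, n - nrow(pt$slices))))
    expect_true(all(ct <= cm + 1e-9))
  }
})

test_that("theoretical mode flags taxa lacking a literature depth", {
  sc <- random_scores(5, seed = 21, zero_frac = 0)
  sc$lit_depth_cm[2] <- NA
  s <- community_sample("S", "2020-01-01",
                        data.frame(taxon = sc$taxon[1:3],
                                   abundance = c(10, 10, 10),
                                   biomass_afdw = c(1, 1, 1)))
  p <- depth_profile(s, sc, "diffusive", 2, mode = "theoretical")
  expect_equal(p$excluded, sc$taxon[2])
  expect_gt(p$excluded_contribution, 0)
  expect_equal(sum(p$slices$bipc) + p$excluded_contribution, p$whole_core)
})
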