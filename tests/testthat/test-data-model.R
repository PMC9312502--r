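score_df <- function(n = 3) {
  data.frame(taxon = sprintf("Mya species%02d", seq_len(n)),
             ft_diff = 1:n, bt_diff = rep(2, n), l_diff = rep(3, n),
             ft_adv = rep(1, n), bt_adv = rep(1, n), l_adv = rep(2, n),
             m_bpc = rep(2, n), r_bpc = rep(2, n))
}

test_that("score table round-trips through CSV field-for-field", {
  path <- withr::local_tempfile(fileext = ".csv")
  orig <- bip_scores(score_df(3))
  write_score_table(orig, path)
  back <- read_score_table(path)
  expect_s3_class(back, "bip_scores")
  expect_equal(nrow(back), 3L)
  expect_equal(as.data.frame(back), as.data.frame(orig))
})

test_that("score table reader accepts tab delimiters", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- score_df(2)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_score_table(path)$taxon, df$taxon)
})

test_that("invalid score tables are rejected, naming the offender", {
  df <- score_df(3)
  df$ft_diff[2] <- -1
  expect_error(bip_scores(df), "negative score.*Mya species02")
  df <- score_df(3)
  df$taxon[3] <- df$taxon[1]
  expect_error(bip_scores(df), "duplicate taxon")
  df <- score_df(3)
  df$bt_adv <- NULL
  expect_error(bip_scores(df), "missing column.*bt_adv")
})

test_that("community reader groups rows by station and date, preserving totals", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(station = rep(c("A", "B"), each = 2),
                   date = "2019-05-01",
                   taxon = rep(c("Mya species01", "Mya species02"), 2),
                   abundance_ind_m2 = c(10, 20, 30, 40),
                   biomass_afdw_g_m2 = c(1, 2, 3, 4),
                   median_grain_um = rep(c(100, 200), each = 2))
  utils::write.csv(df, path, row.names = FALSE)
  samples <- read_community_table(path)
  expect_length(samples, 2L)
  expect_equal(vapply(samples, function(s) nrow(s$records), 1L), c(2L, 2L))
  expect_equal(sum(samples[[1]]$records$abundance), 30)
  expect_equal(sum(samples[[2]]$records$biomass_afdw), 7)
  expect_equal(samples[[2]]$median_grain_um, 200)
})

test_that("replicate pooling averages grabs onto per-m2 units", {
  path <- withr::local_tempfile(fileext = ".csv")
  # taxon X in 2 of 3 grabs of 0.1 m2: (5 + 7 + 0)/3 / 0.1 = 40 ind/m2
  df <- data.frame(station = "A", date = "2019-05-01",
                   replicate = c(1, 2, 3, 1),
                   taxon = c("X sp", "X sp", "Y sp", "Y sp"),
                   abundance_ind_m2 = c(5, 7, 3, 2),
                   biomass_afdw_g_m2 = c(0.5, 0.7, 0.3, 0.2))
  utils::write.csv(df, path, row.names = FALSE)
  samples <- read_community_table(path, pooling = "replicates",
                                  grab_area_m2 = 0.1)
  rec <- samples[[1]]$records
  expect_equal(rec$abundance[rec$taxon == "X sp"], (5 + 7) / 3 / 0.1)
  expect_equal(rec$biomass_afdw[rec$taxon == "Y sp"], (0.3 + 0.2) / 3 / 0.1)
})

test_that("record invariants are enforced, never silently dropped", {
  expect_error(community_sample("A", "2019-05-01",
                                data.frame(taxon = "X", abundance = 0,
                                           biomass_afdw = 0.5)),
               "biomass > 0 with abundance = 0")
  expect_error(community_sample("A", "2019-05-01",
                                data.frame(taxon = "X", abundance = -1,
                                           biomass_afdw = 0)),
               "negative abundance")
  expect_error(community_sample("A", "2019-05-01",
                                data.frame(taxon = c("X", " x "),
                                           abundance = c(1, 1),
                                           biomass_afdw = c(1, 1))),
               "duplicate taxon")
  expect_error(community_sample("A", "2019-05-01", data.frame(),
                                median_grain_um = -5),
               "median_grain_um")
})

test_that("a station present without fauna becomes an empty sample with index 0", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station,date,taxon,abundance_ind_m2,biomass_afdw_g_m2",
               "A,2019-05-01,,,"), path)
  samples <- read_community_table(path)
  expect_length(samples, 1L)
  expect_equal(nrow(samples[[1]]$records), 0L)
  res <- bipc(samples[[1]], bip_scores(score_df(2)), "diffusive")
  expect_identical(res$bipc, 0)
})

test_that("index table write/read round-trips and supports empty results", {
  scores <- bip_scores(score_df(2))
  s <- community_sample("A", "2019-05-01",
                        data.frame(taxon = "Mya species01", abundance = 100,
                                   biomass_afdw = 2),
                        median_grain_um = 100)
  res <- bipc(s, scores, "diffusive")
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_table(list(res), path)
  back <- read_index_table(path)
  expect_equal(nrow(back), 1L)
  expect_equal(back$bipc, res$bipc, tolerance = 1e-12)
  expect_equal(back$system, "diffusive")
  write_index_table(list(), path)
  expect_equal(nrow(read_index_table(path)), 0L)
})

test_that("measurement reader validates depth layers", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(core_id = "C1", quantity = "irrigation",
                              value = 1.5, layer_top_cm = 10,
                              layer_bottom_cm = 2),
                   path, row.names = FALSE)
  expect_error(read_measurement_table(path), "layer_top_cm")
})
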