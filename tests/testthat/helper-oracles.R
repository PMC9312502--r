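# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: everything is a literal loop or an exhaustive
# enumeration, slow but obviously correct on small inputs.

norm_name <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

oracle_bipc <- function(sample, scores, system) {
  skey <- norm_name(scores$taxon)
  total <- 0
  for (i in seq_len(nrow(sample$records))) {
    a <- sample$records$abundance[i]
    b <- sample$records$biomass_afdw[i]
    hit <- match(norm_name(sample$records$taxon[i]), skey)
    if (is.na(hit) || a <= 0) next
    if (system == "diffusive") {
      p <- scores$ft_diff[hit] * scores$bt_diff[hit] * scores$l_diff[hit]
    } else {
      p <- scores$ft_adv[hit] * scores$bt_adv[hit] * scores$l_adv[hit]
    }
    total <- total + (b / a) * a * p
  }
  total
}

oracle_bpc <- function(sample, scores) {
  skey <- norm_name(scores$taxon)
  total <- 0
  for (i in seq_len(nrow(sample$records))) {
    a <- sample$records$abundance[i]
    b <- sample$records$biomass_afdw[i]
    hit <- match(norm_name(sample$records$taxon[i]), skey)
    if (is.na(hit) || a <= 0) next
    total <- total + sqrt(b / a) * a * scores$m_bpc[hit] * scores$r_bpc[hit]
  }
  total
}

# all permutations of 1..n as a matrix (n! rows); recursive, for small n
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exact two-sided Spearman p by exhaustive permutation: P(|rho*| >= |rho|)
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- cor(rx, ry)
  pm <- all_perms(n)
  rhos <- apply(pm, 1L, function(p) cor(rx, ry[p]))
  list(rho = rho_obs,
       p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# Kendall tau by O(n^2) concordant/discordant pair counting (no ties)
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / choose(n, 2)
}

oracle_kendall_exact <- function(x, y) {
  n <- length(x)
  tau_obs <- oracle_kendall_tau(x, y)
  pm <- all_perms(n)
  taus <- apply(pm, 1L, function(p) oracle_kendall_tau(x, y[p]))
  list(tau = tau_obs,
       p = mean(abs(taus) >= abs(tau_obs) - 1e-12))
}

# per-cell reclassification loop mirroring the overlay rule
oracle_overlay_counts <- function(a, b, hot = 0.75, delta = 0.10) {
  va <- a[!is.na(a) & !is.na(b)]
  vb <- b[!is.na(a) & !is.na(b)]
  n <- length(va)
  counts <- c(a_higher = 0L, b_higher = 0L, both_hot = 0L, neither = 0L)
  for (k in seq_len(n)) {
    ra <- mean(va <= va[k]) - (mean(va == va[k]) - 1 / n) / 2  # midrank/n
    rb <- mean(vb <= vb[k]) - (mean(vb == vb[k]) - 1 / n) / 2
    d <- ra - rb
    cls <- if (d > delta) "a_higher"
    else if (d < -delta) "b_higher"
    else if (ra >= hot && rb >= hot) "both_hot"
    else "neither"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# random fixtures -----------------------------------------------------------

random_scores <- function(n_taxa, seed, max_score = 3, zero_frac = 0.15) {
  set.seed(seed)
  taxa <- sprintf("Genus%03d species%03d", seq_len(n_taxa), seq_len(n_taxa))
  rs <- function() sample(0:max_score, n_taxa, replace = TRUE,
                          prob = c(zero_frac, rep((1 - zero_frac) / max_score,
                                                  max_score)))
  bip_scores(data.frame(taxon = taxa,
                        ft_diff = rs(), bt_diff = rs(), l_diff = rs(),
                        ft_adv = rs(), bt_adv = rs(), l_adv = rs(),
                        m_bpc = rs(), r_bpc = rs(),
                        lit_depth_cm = sample(c(2, 5, 10, 20), n_taxa,
                                              replace = TRUE)))
}

random_sample <- function(scores, seed, n_records = NULL,
                          unscored_frac = 0.1, zero_abundance_frac = 0.05) {
  set.seed(seed)
  n_pool <- nrow(scores)
  if (is.null(n_records)) n_records <- sample(5:min(50, n_pool), 1L)
  picked <- sample(n_pool, min(n_records, n_pool))
  taxa <- scores$taxon[picked]
  extra <- round(unscored_frac * length(taxa))
  if (extra > 0L) taxa <- c(taxa, sprintf("Unlisted sp%02d", seq_len(extra)))
  a <- rlnorm(length(taxa), 3, 1)
  zero <- runif(length(taxa)) < zero_abundance_frac
  a[zero] <- 0
  b <- a * rlnorm(length(taxa), -3, 0.5)
  community_sample("RSTA", "2020-06-01",
                   data.frame(taxon = taxa, abundance = a, biomass_afdw = b,
                              depth_measured = runif(length(taxa), 0, 20)))
}
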