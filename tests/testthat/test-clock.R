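# rho/sigma, clock conversion, TN93+Gamma likelihood, clock-constrained ML,
# BIC model choice, consensus intervals.

star_tree_with <- function(muts) {
  profs <- lapply(seq_along(muts), function(i)
    make_profile(paste0("s", i),
                 if (muts[i] > 0) 1000L + 10L * i + seq_len(muts[i]) else
                   integer()))
  build_mp_tree(profs)
}

test_that("rho and sigma on a star tree match the direct summation", {
  tr <- star_tree_with(c(2, 2, 3, 1))
  r <- rho_sigma(tr)
  expect_equal(r$rho, 2.0)
  expect_equal(r$sigma^2, 0.5)
  expect_identical(r$n, 4L)
  # all tips identical to root
  tr0 <- build_mp_tree(lapply(1:3, function(i)
    variant_profile(paste0("t", i))))
  r0 <- rho_sigma(tr0)
  expect_equal(r0$rho, 0)
  expect_equal(r0$sigma, 0)
})

test_that("rho on the caterpillar matches the enumerated path lengths", {
  tr <- build_mp_tree(list(make_profile("s1", 1000),
                           make_profile("s2", c(1000, 2000)),
                           make_profile("s3", c(1000, 3000))))
  r <- rho_sigma(tr)
  expect_equal(r$rho, 5 / 3)
  expect_equal(r$sigma^2, 11 / 9)
})

test_that("rho equals the path-walking oracle on random trees (multiplicity honored)", {
  for (seed in 1:20) {
    profs <- random_profiles(sample(4:8, 1), 10, seed)
    # add duplicates so multiplicity matters
    profs <- c(profs, list(variant_profile("dup1",
                                           profs[[1L]]$variants)))
    tr <- build_mp_tree(profs)
    r <- rho_sigma(tr)
    expect_equal(r$rho, mean_root_tip_distance(tr), tolerance = 1e-12)
  }
})

test_that("star-genealogy identity sigma^2 = rho/n holds exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- star_tree_with(sample(0:6, sample(3:10, 1), replace = TRUE))
    r <- rho_sigma(tr)
    expect_equal(r$sigma^2, r$rho / r$n, tolerance = 1e-12)
  }
})

test_that("rho_age converts mutations to years through the clock", {
  one <- structure(list(clade_id = "c", n = 10L, rho = 1, sigma = 0),
                   class = "rho_result")
  expect_equal(rho_age(one)$age_years, 3624)

  zero <- structure(list(clade_id = "c", n = 10L, rho = 0, sigma = 0.5),
                    class = "rho_result")
  a0 <- rho_age(zero)
  expect_equal(a0$age_years, 0)
  expect_equal(a0$ci_low_years, 0)
  expect_equal(a0$ci_high_years, 1.96 * 0.5 * 3624)

  two <- structure(list(clade_id = "c", n = 10L, rho = 2, sigma = 0.5),
                   class = "rho_result")
  a2 <- rho_age(two)
  expect_equal(a2$age_years, 2 * 3624)
  expect_equal(a2$ci_low_years, (2 - 0.98) * 3624)
  expect_equal(a2$ci_high_years, (2 + 0.98) * 3624)
})

test_that("correction curves apply monotone interpolation anchored at zero", {
  curve <- data.frame(substitutions = c(1, 2, 4), years = c(4000, 7000, 12000))
  ck <- clock_model(correction_table = curve)
  expect_equal(ck$correction(0), 0)
  expect_equal(ck$correction(2), 7000)
  expect_equal(ck$correction(1.5), 5500)
  expect_equal(ck$correction(5), 12000 + 2500)   # linear extrapolation
  expect_error(clock_model(correction_table = data.frame(
    substitutions = c(1, 1), years = c(1, 2))), "increasing")

  r <- structure(list(clade_id = "c", n = 5L, rho = 2, sigma = 0),
                 class = "rho_result")
  expect_equal(rho_age(r, ck)$age_years, 7000)
})

test_that("tree_loglik matches JC69 closed forms", {
  jc <- substitution_model("JC69")
  t <- 0.17
  phy <- ape::read.tree(text = sprintf("(a:%f,b:0);", t))
  expect_equal(tree_loglik(c(a = "A", b = "A"), phy, jc),
               log(1 / 16 + 3 / 16 * exp(-4 * t / 3)))
  expect_equal(tree_loglik(c(a = "A", b = "G"), phy, jc),
               log(1 / 16 - 1 / 16 * exp(-4 * t / 3)))
  # identical sequences on a zero-length tree: sum of log base frequencies
  phy0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(tree_loglik(c(a = "ACGT", b = "ACGT"), phy0, jc),
               4 * log(0.25))
  # one gamma category reduces to the equal-rates likelihood
  jc_g1 <- substitution_model("JC69", gamma_shape = 0.5, n_categories = 1L)
  expect_equal(tree_loglik(c(a = "A", b = "A"), phy, jc_g1),
               tree_loglik(c(a = "A", b = "A"), phy, jc))
})

test_that("pruning equals brute-force ancestral-state summation (<= 4 tips)", {
  tn <- substitution_model("TN93",
                           base_frequencies = c(0.3, 0.3, 0.15, 0.25),
                           transition_rate_purines = 4,
                           transition_rate_pyrimidines = 8,
                           gamma_shape = 0.5, n_categories = 3L,
                           p_invariant = 0.2)
  phy4 <- ape::read.tree(text = "((a:0.1,b:0.25):0.12,(c:0.3,d:0.05):0.2);")
  aln <- c(a = "ACGTAN", b = "ACGTCC", c = "AAGTTC", d = "ACTTAC")
  expect_equal(tree_loglik(aln, phy4, tn),
               tree_loglik_bruteforce(aln, phy4, tn))
  # likelihood is invariant to tip reordering
  expect_equal(tree_loglik(aln[c(3, 1, 4, 2)], phy4, tn),
               tree_loglik(aln, phy4, tn))
  # partitioned: coding and control pieces add
  parts <- partition_scheme()
  positions <- c(600L, 601L, 602L, 16100L, 16101L, 16102L)
  models <- list(tn, substitution_model("HKY85",
                                        base_frequencies = c(0.3, 0.3, 0.15,
                                                             0.25),
                                        transition_rate_purines = 10))
  ll <- tree_loglik(aln, phy4, models, parts, positions)
  ll_split <- tree_loglik(substr(aln, 1, 3), phy4, tn) +
    tree_loglik(substr(aln, 4, 6), phy4, models[[2L]])
  names(ll_split) <- NULL
  expect_equal(ll, ll_split)
  expect_error(substitution_model("TN93", base_frequencies = c(1, 2, 3, 4)),
               "frequencies")
})

test_that("pruning agrees with phangorn on a TN93+G alignment", {
  library(phangorn)
  set.seed(21)
  tn <- substitution_model("TN93",
                           base_frequencies = c(0.35, 0.25, 0.15, 0.25),
                           transition_rate_purines = 6,
                           transition_rate_pyrimidines = 3,
                           gamma_shape = 0.7, n_categories = 4L)
  phy <- ape::rtree(6)
  m <- simulate_alignment(phy, tn, 80, seed = 21)
  chars <- matrix(c("a", "c", "g", "t")[m], nrow(m), dimnames =
                    list(rownames(m), NULL))
  dat <- phangorn::phyDat(chars)
  fit <- phangorn::pml(phy, dat, bf = tn$base_frequencies,
                       Q = c(1, 6, 1, 1, 3, 1), k = 4, shape = 0.7)
  expect_equal(tree_loglik(m, phy, tn), as.numeric(stats::logLik(fit)),
               tolerance = 1e-6)
})

test_that("clock fit recovers the closed-form two-sequence height", {
  set.seed(7)
  jc <- substitution_model("JC69")
  L <- 2000L; k <- 120L
  sa <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  v <- strsplit(sa, "")[[1L]]
  for (i in sample(L, k)) v[i] <- setdiff(c("A", "C", "G", "T"),
                                          v[i])[sample(3, 1)]
  sb <- paste(v, collapse = "")
  topo <- ape::read.tree(text = "(a:1,b:1);")
  fit <- fit_clock_heights(c(a = sa, b = sb), topo, jc)
  closed <- -3 / 4 * log(1 - 4 / 3 * (k / L)) / 2
  expect_equal(unname(fit$heights[fit$context$root]), closed,
               tolerance = 1e-4)
  expect_true(fit$converged)

  fit0 <- fit_clock_heights(c(a = sa, b = sa), topo, jc)
  expect_equal(unname(fit0$heights[fit0$context$root]), 0, tolerance = 1e-7)
  a0 <- ml_age(fit0)
  expect_equal(a0$age_years, 0)
})

test_that("ml_age maps one genome substitution to 3624 years and matches a
           grid-search profile CI", {
  set.seed(7)
  jc <- substitution_model("JC69")
  L <- 2000L; k <- 120L
  sa <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  v <- strsplit(sa, "")[[1L]]
  for (i in sample(L, k)) v[i] <- setdiff(c("A", "C", "G", "T"),
                                          v[i])[sample(3, 1)]
  sb <- paste(v, collapse = "")
  topo <- ape::read.tree(text = "(a:1,b:1);")
  fit <- fit_clock_heights(c(a = sa, b = sb), topo, jc)
  h <- unname(fit$heights[fit$context$root])
  a <- ml_age(fit, clade_id = "pair")
  expect_equal(a$age_years, h * 16569 * 3624)

  # grid-search oracle for the 1.92-unit profile interval
  gl <- function(hh) {
    tr <- topo; tr$edge.length <- c(hh, hh)
    tree_loglik(c(a = sa, b = sb), tr, jc)
  }
  hs <- seq(h * 0.6, h * 1.6, length.out = 2500)
  lls <- vapply(hs, gl, 0)
  keep <- hs[lls >= max(c(lls, fit$loglik)) - 1.92]
  expect_equal(a$ci_low_years, min(keep) * 16569 * 3624, tolerance = 0.01)
  expect_equal(a$ci_high_years, max(keep) * 16569 * 3624, tolerance = 0.01)
})

test_that("clock fit recovers simulated root heights without systematic bias", {
  jc <- substitution_model("JC69")
  true_h <- 0.004
  ref_len <- 16569L
  errs <- vapply(1:8, function(seed) {
    gen <- star_genealogy(8, true_h * ref_len * 3624)
    sc <- simulate_sequences(gen, REF, model = substitution_model("JC69"),
                             seed = seed)
    fit <- fit_clock_heights(sc$sequences, gen$phylo, jc)
    unname(fit$heights[fit$context$root]) - true_h
  }, 0)
  mc_se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 2 * mc_se + 1e-4)
})

test_that("BIC prefers the generating model and orders nested ties by k", {
  jc <- substitution_model("JC69")
  phy <- ape::read.tree(text = "((a:0.05,b:0.05):0.03,(c:0.04,d:0.06):0.02);")
  wins <- 0L
  n_rep <- 12L
  for (seed in seq_len(n_rep)) {
    m <- simulate_alignment(phy, jc, 300, seed)
    tab <- bic_select(m, phy, model_candidates(c("JC69", "TN93"), ""))
    if (tab$model[1L] == "JC69") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)

  # single candidate comes back as rank 1
  m <- simulate_alignment(phy, jc, 100, 1)
  single <- bic_select(m, phy, model_candidates("JC69", ""))
  expect_identical(single$rank, 1L)

  # identical log-likelihoods: the smaller-k model must win on penalty
  penal <- data.frame(k = c(6, 11), loglik = c(-100, -100))
  bics <- -2 * penal$loglik + penal$k * log(300)
  expect_lt(bics[1L], bics[2L])
})

test_that("consensus intervals intersect, flag disjoint inputs, and form a
           commutative idempotent semigroup", {
  e <- function(lo, hi) age_estimate("c", "rho", (lo + hi) / 2, lo, hi)
  ab <- consensus_interval(list(e(60, 70), e(63, 73)))
  expect_equal(c(ab$low, ab$high), c(63, 70))
  expect_false(ab$empty)

  same <- consensus_interval(list(e(10, 20), e(10, 20)))
  expect_equal(c(same$low, same$high), c(10, 20))

  disj <- consensus_interval(list(e(10, 20), e(30, 40)))
  expect_true(disj$empty)

  # commutativity and associativity on random triples
  set.seed(5)
  for (i in 1:20) {
    lows <- runif(3, 0, 50); his <- lows + runif(3, 0, 30)
    es <- Map(e, lows, his)
    c123 <- consensus_interval(es)
    c321 <- consensus_interval(rev(es))
    expect_identical(c123, c321)
    # fold left equals flat intersection when nonempty
    c12 <- consensus_interval(es[1:2])
    if (!c12$empty) {
      folded <- consensus_interval(list(e(c12$low, c12$high), es[[3L]]))
      expect_equal(folded, c123)
    }
  }
})
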