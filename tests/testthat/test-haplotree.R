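# Haplogroup classification and maximum-parsimony tree construction.

profile_from_motif <- function(id, tokens) {
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  variant_profile(id, variant_table(
    as.integer(vapply(m, `[`, "", 3L)),
    vapply(m, `[`, "", 2L), vapply(m, `[`, "", 4L)))
}

test_that("classify finds exact motif matches, the root for empty profiles", {
  ht <- toy_haplogroup_tree()
  call <- classify(profile_from_motif("a", c("A1000G", "C2000T", "G5000A")),
                   ht)
  expect_identical(call$best_label, "M1")
  expect_equal(call$score, 1.0)
  expect_identical(call$path_depth, 2L)

  root_call <- classify(variant_profile("b"), ht)
  expect_identical(root_call$best_label, "L3")
  expect_equal(root_call$score, 1.0)

  expect_error(classify(variant_profile("c"), list()), "empty|invalid")
})

test_that("classify agrees with exhaustive scoring over all nodes", {
  ht <- toy_haplogroup_tree()
  # shares 2 of 3 motif variants with N1's path and 2 with R's path
  profs <- list(
    profile_from_motif("x", c("A3000G", "C6000T")),
    profile_from_motif("y", c("A3000G", "T7000C")),
    profile_from_motif("z", c("A1000G", "C2000T", "A3000G")))
  for (p in profs) {
    have <- paste0(p$variants$position, ":", p$variants$alt)
    stats <- vapply(ht$labels, function(l) {
      ev <- expected_variants(ht, l)
      keys <- paste0(ev$position, ":", ev$alt)
      sum(keys %in% have) - sum(!keys %in% have)
    }, 0)
    best_stat <- max(stats)
    winners <- ht$labels[stats == best_stat]
    d <- ht$depth[winners]
    winners <- winners[d == max(d)]
    expect_identical(classify(p, ht)$best_label, sort(winners)[1L])
  }
})

test_that("classify is monotone: adding a child's defining variant deepens the call", {
  ht <- toy_haplogroup_tree()
  p <- profile_from_motif("m", c("A1000G", "C2000T"))
  expect_identical(classify(p, ht)$best_label, "M")
  p2 <- profile_from_motif("m", c("A1000G", "C2000T", "G5000A"))
  expect_identical(classify(p2, ht)$best_label, "M1")
})

test_that("back-mutation motifs cancel along the path", {
  ht <- haplogroup_tree(c("ROOT", "A", "A1"), c(NA, "ROOT", "A"),
                        c("", "T5000C C6000T", "T5000C! G7000A"))
  ev <- expected_variants(ht, "A1")
  expect_setequal(paste0(ev$position, ev$alt), c("6000T", "7000A"))
})

test_that("haplogroup tree TSV round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tparent\tmotif", "L3\t\t", "M\tL3\tA1000G C2000T"),
             path)
  ht <- read_haplogroup_tree(path)
  expect_identical(ht$root, "L3")
  expect_identical(nrow(ht$motifs$M), 2L)
})

test_that("build_mp_tree reproduces the perfect-phylogeny caterpillar", {
  profs <- list(make_profile("s1", 1000),
                make_profile("s2", c(1000, 2000)),
                make_profile("s3", c(1000, 3000)))
  tr <- build_mp_tree(profs)
  expect_identical(tr$score, 3L)
  # the edge carrying variant 1000 subtends all three samples
  below <- mp_tips_below(tr)
  m1 <- vapply(seq_along(tr$parent), function(v)
    any(tr$mutations[[v]]$position == 1000L), TRUE)
  expect_identical(below[which(m1)], 3L)
  # replaying edges reproduces each tip's profile
  for (tp in which(tr$is_tip)) {
    id <- tr$samples[[tp]][1L]
    p <- profs[[match(id, vapply(profs, function(x) x$sample_id, ""))]]
    expect_setequal(mp_replay(tr, tp), variant_tokens(p$variants))
  }
})

test_that("single profile and collapsed duplicates are handled", {
  single <- build_mp_tree(list(make_profile("only", c(100, 200, 300))))
  expect_identical(single$score, 3L)
  expect_identical(sum(single$is_tip), 1L)

  dup <- build_mp_tree(list(make_profile("a", 1000),
                            make_profile("b", 1000)))
  expect_identical(sum(dup$is_tip), 1L)
  expect_identical(sort(dup$samples[[which(dup$is_tip)]]), c("a", "b"))
  expect_identical(dup$score, 1L)
  expect_identical(parsimony_oracle(list(make_profile("a", 1000),
                                         make_profile("b", 1000))), 1L)
})

test_that("path replay reproduces every tip profile on random trees", {
  for (seed in 1:10) {
    profs <- random_profiles(6, 8, seed)
    tr <- build_mp_tree(profs)
    ids <- vapply(profs, function(p) p$sample_id, "")
    for (tp in which(tr$is_tip)) {
      p <- profs[[match(tr$samples[[tp]][1L], ids)]]
      expect_setequal(mp_replay(tr, tp), variant_tokens(p$variants))
    }
  }
})

test_that("greedy score equals the exhaustive Fitch minimum when homoplasy-free,
           and never beats it in general", {
  n_match <- 0L
  for (seed in 1:40) {
    inst <- random_homoplasy_free(sample(3:6, 1), seed)
    greedy <- build_mp_tree(inst$profiles)$score
    oracle <- parsimony_oracle(inst$profiles)
    expect_gte(greedy, oracle)
    expect_identical(oracle, inst$n_variants)
    if (greedy == oracle) n_match <- n_match + 1L
  }
  expect_gte(n_match / 40, 0.95)
  # homoplastic instances: greedy may exceed but never undercuts the oracle
  for (seed in 1:10) {
    profs <- random_profiles(5, 6, seed + 100)
    expect_gte(build_mp_tree(profs)$score, parsimony_oracle(profs))
  }
})

test_that("parsimony oracle refuses too many haplotypes", {
  profs <- lapply(1:9, function(i) make_profile(paste0("s", i), 1000 + i))
  expect_error(parsimony_oracle(profs), "refuses")
})

test_that("root profiles induce back-mutation tokens that cancel on replay", {
  root <- make_profile("root", c(1000, 2000))
  profs <- list(make_profile("a", 1000),            # lost 2000
                make_profile("b", c(1000, 2000, 3000)))
  tr <- build_mp_tree(profs, root_profile = root)
  ids <- vapply(profs, function(p) p$sample_id, "")
  for (tp in which(tr$is_tip)) {
    rel <- mitofounder:::relative_tokens
    expect_setequal(mp_replay(tr, tp),
                    rel(profs[[match(tr$samples[[tp]][1L], ids)]], root))
  }
})

test_that("propose_haplogroups enforces the five-sample/two-haplotype/coding rule", {
  # clade of 5 samples, 2 haplotypes, coding defining variant -> accepted
  profs <- c(lapply(1:3, function(i) make_profile(paste0("a", i), 769)),
             lapply(1:2, function(i) make_profile(paste0("b", i),
                                                  c(769, 2000))),
             list(make_profile("out", 9000)))
  tr <- build_mp_tree(profs)
  props <- propose_haplogroups(tr)
  accepted <- props[props$accepted, ]
  expect_identical(nrow(accepted), 1L)
  expect_identical(accepted$n_samples, 5L)
  expect_identical(accepted$n_haplotypes, 2L)

  # same clade defined by a control-region variant alone -> rejected
  profs2 <- c(lapply(1:3, function(i) make_profile(paste0("a", i), 16400)),
              lapply(1:2, function(i) make_profile(paste0("b", i),
                                                   c(16400, 2000))),
              list(make_profile("out", 9000)))
  tr2 <- build_mp_tree(profs2)
  props2 <- propose_haplogroups(tr2)
  big <- props2[props2$n_samples == 5L, ]
  expect_false(any(big$accepted))
  expect_true(any(big$reason == "control region mutation alone"))

  # only 4 samples -> rejected for size
  profs3 <- c(lapply(1:2, function(i) make_profile(paste0("a", i), 769)),
              lapply(1:2, function(i) make_profile(paste0("b", i),
                                                   c(769, 2000))),
              list(make_profile("out", 9000)))
  props3 <- propose_haplogroups(build_mp_tree(profs3))
  small <- props3[props3$n_samples == 4L, ]
  expect_false(any(small$accepted))
  expect_true(any(small$reason == "fewer than five samples"))
})

test_that("newick and edge-table exports are well formed", {
  profs <- list(make_profile("s1", 1000), make_profile("s2", c(1000, 2000)),
                make_profile("s3", c(1000, 3000)))
  tr <- build_mp_tree(profs)
  nwk <- mp_write_newick(tr)
  expect_match(nwk, "mutations=")
  expect_match(nwk, ";$")
  out <- withr::local_tempfile(fileext = ".tsv")
  tab <- mp_write_edge_table(tr, out)
  expect_true(all(c("child_node", "parent_node", "mutations",
                    "n_tips_below") %in% names(tab)))
  phy <- mp_as_phylo(tr)
  expect_s3_class(phy, "phylo")
  expect_identical(length(phy$tip.label), 3L)
})
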