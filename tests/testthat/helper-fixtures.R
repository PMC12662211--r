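# Shared fixtures: one synthetic reference for the whole suite, profile
# builders, and random-instance generators used by the property tests.

REF <- synthetic_rcrs(1)

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

ref_base <- function(pos) substr(REF$sequence, pos, pos)

# Substitution-only profile at given positions (transitions by default).
make_profile <- function(id, positions, region = NA_character_) {
  positions <- as.integer(positions)
  if (!length(positions)) return(variant_profile(id, region_label = region))
  rb <- vapply(positions, ref_base, "")
  variant_profile(id, variant_table(positions, rb,
                                    unname(transition_partner[rb])),
                  region_label = region)
}

# Random homoplasy-free instance: a random rooted tree shape over k
# haplotypes with one unique variant per pendant/internal edge; each tip's
# profile is the union along its root path. Returns profiles plus the
# number of distinct variants (= the perfect-phylogeny parsimony score).
random_homoplasy_free <- function(k, seed) {
  set.seed(seed)
  pool <- sample(setdiff(700:12000, 16182:16193), 60)
  nxt <- 0L
  take <- function(n) { out <- pool[nxt + seq_len(n)]; nxt <<- nxt + n; out }
  # sequential random attachment: tip i attaches below a random existing tip
  paths <- list(take(sample(1:2, 1)))
  for (i in seq_len(k - 1L)) {
    host <- sample(seq_along(paths), 1L)
    shared_len <- sample(0:length(paths[[host]]), 1L)
    paths[[length(paths) + 1L]] <-
      c(paths[[host]][seq_len(shared_len)], take(sample(1:2, 1)))
  }
  profiles <- lapply(seq_along(paths), function(i)
    make_profile(paste0("h", i), paths[[i]]))
  list(profiles = profiles, n_variants = length(unique(unlist(paths))))
}

# Arbitrary random profiles (homoplasy allowed) over a small variant pool.
random_profiles <- function(k, pool_size, seed) {
  set.seed(seed)
  pool <- sample(1000:15000, pool_size)
  lapply(seq_len(k), function(i)
    make_profile(paste0("r", i), sample(pool, sample(1:pool_size, 1L))))
}

# Simulate an alignment (integer-coded) down a fixed phylo under a model.
simulate_alignment <- function(phy, model, n_sites, seed) {
  set.seed(seed)
  phy <- reorder(phy)
  nnode <- max(phy$edge)
  root <- phy$edge[1L, 1L]
  states <- vector("list", nnode)
  states[[root]] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = model$base_frequencies)
  for (e in seq_len(nrow(phy$edge))) {
    P <- transition_probabilities(model, phy$edge.length[e])
    par <- states[[phy$edge[e, 1L]]]
    states[[phy$edge[e, 2L]]] <- vapply(par, function(b)
      sample.int(4L, 1L, prob = P[b, ]), 1L)
  }
  m <- do.call(rbind, states[seq_along(phy$tip.label)])
  rownames(m) <- phy$tip.label
  m
}

toy_haplogroup_tree <- function() {
  haplogroup_tree(
    labels = c("L3", "M", "N", "M1", "N1", "R"),
    parents = c(NA, "L3", "L3", "M", "N", "N"),
    motifs = c("", "A1000G C2000T", "A3000G T4000C", "G5000A",
               "C6000T", "T7000C G8000A"))
}
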