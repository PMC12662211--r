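## Coalescent simulation of clades with known node times and emitted
## sequences, for end-to-end validation of the dating estimators.

#' Construct a demography model
#'
#' @param kind `"constant"`, `"exponential_growth"` or
#'   `"piecewise_constant"`.
#' @param effective_size haploid effective size N (female effective size for
#'   mtDNA), in individuals.
#' @param growth_rate per-generation growth rate (forward in time) for
#'   `exponential_growth`.
#' @param change_points data.frame with columns `time` (generations before
#'   present, increasing) and `size`, for `piecewise_constant`; the size at
#'   time 0 is `effective_size`.
#' @param generation_years years per generation, default 25.
#' @return object of class `demography_model`.
#' @export
demography_model <- function(kind = c("constant", "exponential_growth",
                                      "piecewise_constant"),
                             effective_size, growth_rate = 0,
                             change_points = NULL, generation_years = 25) {
  kind <- match.arg(kind)
  stopifnot(effective_size > 0, generation_years > 0)
  if (kind == "piecewise_constant") {
    stopifnot(is.data.frame(change_points),
              all(c("time", "size") %in% names(change_points)))
    if (any(diff(change_points$time) <= 0) || any(change_points$size <= 0))
      stop("change points must increase in time with positive sizes")
  }
  structure(list(kind = kind, effective_size = effective_size,
                 growth_rate = growth_rate, change_points = change_points,
                 generation_years = generation_years),
            class = "demography_model")
}

## Waiting time (generations) to the next coalescence among k lineages,
## starting at backward time t0, under the demography.
coalescent_waiting_time <- function(k, t0, dem) {
  pair_rate <- k * (k - 1) / 2
  E <- stats::rexp(1L)
  switch(dem$kind,
    constant = E * dem$effective_size / pair_rate,
    exponential_growth = {
      g <- dem$growth_rate
      if (g == 0) return(E * dem$effective_size / pair_rate)
      ## backward population size N0 * exp(-g t)
      rate0 <- pair_rate / dem$effective_size
      log(exp(g * t0) + g * E / rate0) / g - t0
    },
    piecewise_constant = {
      cp <- dem$change_points
      bounds <- c(0, cp$time, Inf)
      sizes <- c(dem$effective_size, cp$size)
      t <- t0; remaining <- E
      repeat {
        i <- findInterval(t, bounds, rightmost.closed = FALSE)
        rate <- pair_rate / sizes[i]
        room <- bounds[i + 1L] - t
        if (remaining / rate <= room) return(t + remaining / rate - t0)
        remaining <- remaining - rate * room
        t <- bounds[i + 1L]
      }
    })
}

#' Simulate a coalescent genealogy with node times
#'
#' Standard n-coalescent: while k lineages remain, a waiting time is drawn
#' at pairwise rate k(k-1)/2 per N generations (scaled by the demography)
#' and a uniformly chosen pair coalesces. Times convert to years via the
#' demography's `generation_years`. Fully seeded and reproducible.
#'
#' @param n number of tips (>= 2).
#' @param demography a `demography_model`.
#' @param seed integer seed.
#' @return object of class `genealogy`: `phylo` (branch lengths in years),
#'   `node_times_years` (per phylo node id; tips at 0), `tmrca_years`,
#'   `seed`.
#' @export
simulate_genealogy <- function(n, demography, seed) {
  stopifnot(n >= 2L, inherits(demography, "demography_model"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- as.integer(n)
  active <- seq_len(n)
  times <- numeric(2L * n - 1L)            # generations, by provisional id
  parent <- rep(NA_integer_, 2L * n - 1L)
  t <- 0
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t <- t + coalescent_waiting_time(k, t, demography)
    pair <- sample(seq_len(k), 2L)
    a <- active[pair[1L]]; b <- active[pair[2L]]
    times[nxt] <- t
    parent[c(a, b)] <- nxt
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  genealogy_from_parent(parent, times * demography$generation_years, n,
                        seed)
}

#' Star genealogy: all tips coalesce at the root simultaneously
#' @param n number of tips (>= 2).
#' @param tmrca_years root age in years.
#' @return a `genealogy`.
#' @export
star_genealogy <- function(n, tmrca_years) {
  stopifnot(n >= 2L, tmrca_years >= 0)
  n <- as.integer(n)
  parent <- c(rep(n + 1L, n), NA_integer_)
  genealogy_from_parent(parent, c(rep(0, n), tmrca_years), n,
                        seed = NA_integer_)
}

## parent/time vectors (provisional ids: tips 1..n) -> ape phylo with
## internal nodes renumbered root-first (root = n + 1).
genealogy_from_parent <- function(parent, times_years, n, seed) {
  nn <- length(parent)
  internals <- (n + 1L):nn
  ord <- internals[order(times_years[internals], decreasing = TRUE)]
  id_map <- integer(nn)
  id_map[seq_len(n)] <- seq_len(n)
  id_map[ord] <- n + seq_along(ord)
  child <- which(!is.na(parent))
  edge <- cbind(id_map[parent[child]], id_map[child])
  node_times <- numeric(nn)
  node_times[id_map] <- times_years
  phy <- list(edge = edge,
              edge.length = node_times[edge[, 1L]] - node_times[edge[, 2L]],
              tip.label = paste0("t", seq_len(n)),
              Nnode = nn - n)
  class(phy) <- "phylo"
  phy <- stats::reorder(phy)
  structure(list(phylo = phy, node_times_years = node_times,
                 tmrca_years = max(node_times), seed = seed),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Genealogy: ", length(x$phylo$tip.label), " tips, TMRCA ",
      round(x$tmrca_years), " years\n", sep = "")
  invisible(x)
}

#' Simulate sequences down a genealogy
#'
#' Mutations are Poisson per branch with mean `branch_years /
#' years_per_substitution` (whole-genome clock; the default 3,624-year rate
#' gives one expected mutation per 3,624 branch-years). Mutation positions
#' are drawn proportional to per-site rates -- hotspot positions are
#' upweighted by `hotspot_multiplier`, and masked sites stay eligible so
#' masking is testable downstream. The substitution type is drawn from the
#' model's rate matrix given the current base. Sequences are emitted by
#' replaying mutations from the root haplotype tip-ward.
#'
#' @param genealogy a `genealogy` (node times in years).
#' @param reference a `mito_reference` providing the coordinate system and
#'   root sequence baseline.
#' @param model a `substitution_model` (mutation-type kernel).
#' @param clock a `clock_model`; its `years_per_substitution` drives the
#'   mutation rate.
#' @param root_profile optional `variant_profile` applied to the reference
#'   to form the clade root haplotype.
#' @param hotspot_positions integer positions with elevated rate.
#' @param hotspot_multiplier rate multiplier at hotspots, default 20.
#' @param seed integer seed.
#' @return object of class `simulated_clade`: `sequences` (named character
#'   vector by tip label), `true_profiles` (list of `variant_profile` vs the
#'   reference), `genealogy`, `true_tmrca_years`, `n_mutations`, `seed`.
#' @export
simulate_sequences <- function(genealogy, reference,
                               model = substitution_model("TN93",
                                 transition_rate_purines = 20,
                                 transition_rate_pyrimidines = 20),
                               clock = clock_model(),
                               root_profile = NULL,
                               hotspot_positions = integer(),
                               hotspot_multiplier = 20,
                               seed = 1L) {
  stopifnot(inherits(genealogy, "genealogy"),
            inherits(reference, "mito_reference"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  L <- reference$length
  w <- rep(1, L)
  if (length(hotspot_positions)) w[hotspot_positions] <- hotspot_multiplier
  w <- w / sum(w)
  Q <- model$Q

  root_chars <- if (is.null(root_profile)) reference$chars
    else strsplit(apply_variants(root_profile, reference), "")[[1L]]
  root_int <- match(root_chars, BASES)
  phy <- stats::reorder(genealogy$phylo)   # cladewise: parents before children
  nnode <- max(phy$edge)
  ntip <- length(phy$tip.label)
  seqs <- vector("list", nnode)
  root <- phy$edge[1L, 1L]
  seqs[[root]] <- root_int
  n_mut <- 0L
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1L]; child <- phy$edge[k, 2L]
    s <- seqs[[par]]
    nm <- stats::rpois(1L, phy$edge.length[k] / clock$years_per_substitution)
    if (nm > 0L) {
      pos <- sample.int(L, nm, replace = TRUE, prob = w)
      for (p in pos) {
        cur <- s[p]
        rates <- Q[cur, ]; rates[cur] <- 0
        s[p] <- sample.int(4L, 1L, prob = rates)
      }
      n_mut <- n_mut + nm
    }
    seqs[[child]] <- s
  }
  tips <- seq_len(ntip)
  sequences <- vapply(tips, function(tp)
    paste(BASES[seqs[[tp]]], collapse = ""), "")
  names(sequences) <- phy$tip.label
  ref_int <- match(reference$chars, BASES)
  profiles <- lapply(tips, function(tp) {
    diff <- which(seqs[[tp]] != ref_int)
    variant_profile(phy$tip.label[tp],
                    variant_table(diff, BASES[ref_int[diff]],
                                  BASES[seqs[[tp]][diff]]))
  })
  names(profiles) <- phy$tip.label
  structure(list(sequences = sequences, true_profiles = profiles,
                 genealogy = genealogy,
                 true_tmrca_years = genealogy$tmrca_years,
                 n_mutations = n_mut, seed = as.integer(seed)),
            class = "simulated_clade")
}

#' @export
print.simulated_clade <- function(x, ...) {
  cat("Simulated clade: ", length(x$sequences), " tips, true TMRCA ",
      round(x$true_tmrca_years), " years, ", x$n_mutations,
      " mutations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

write_fasta <- function(sequences, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(sequences))
    writeLines(c(paste0(">", nm), sequences[[nm]]), con)
  invisible(path)
}

#' Write a simulation fixture bundle to disk
#'
#' Generates a grid of scenarios -- a star expansion, a constant-size
#' coalescent clade, and a two-clade northern/southern mixture with a route
#' truth table -- and writes, per scenario, a FASTA, a sample sheet, the
#' true genealogy as Newick with ages in years, a true-TMRCA table, a
#' variant-profile truth table, and (for the mixture) route tables. The
#' reference sequence itself is written once. All randomness derives from
#' `seed`, which is recorded in the config file.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param config optional overrides: `star = list(n, tmrca_years)`,
#'   `constant = list(n, effective_size)`, `mixture = list(n_northern_aus,
#'   n_southern_aus, n_new_guinea, tmrca_years)`, `generation_years`.
#' @return invisible list of written paths and the truth objects.
#' @export
make_fixture_suite <- function(dir, seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    star = list(n = 20L, tmrca_years = 60000),
    constant = list(n = 20L, effective_size = 2000),
    mixture = list(n_northern_aus = 9L, n_southern_aus = 16L,
                   n_new_guinea = 10L, tmrca_years = 50000),
    generation_years = 25), config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- synthetic_rcrs(seed)
  write_fasta(stats::setNames(ref$sequence, "rCRS synthetic"),
              file.path(dir, "reference.fasta"))
  out <- list(reference = ref, config = cfg)

  scen <- function(name, clade, region) {
    write_fasta(clade$sequences, file.path(dir, paste0(name, ".fasta")))
    sheet <- data.frame(sample_id = names(clade$sequences),
                        region_label = region,
                        name = names(clade$sequences))
    utils::write.table(sheet, file.path(dir, paste0(name, "_samples.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(clade$genealogy$phylo,
                    file.path(dir, paste0(name, "_true_tree.nwk")))
    utils::write.table(
      data.frame(scenario = name, true_tmrca_years = clade$true_tmrca_years,
                 n = length(clade$sequences)),
      file.path(dir, paste0(name, "_truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_variant_profiles(clade$true_profiles,
                           file.path(dir, paste0(name, "_true_profiles.tsv")))
    clade
  }

  star <- simulate_sequences(
    star_genealogy(cfg$star$n, cfg$star$tmrca_years), ref,
    seed = seed + 1L)
  out$star <- scen("star", star, "StarLand")

  dem <- demography_model("constant",
                          effective_size = cfg$constant$effective_size,
                          generation_years = cfg$generation_years)
  const <- simulate_sequences(
    simulate_genealogy(cfg$constant$n, dem, seed = seed + 2L), ref,
    seed = seed + 3L)
  out$constant <- scen("constant", const, "ConstLand")

  ## two-clade mixture: distinct root haplotypes marked by coding variants
  mk_root <- function(pos) variant_profile("root", variant_table(
    pos, substr(ref$sequence, pos, pos),
    setdiff(c("A", "C", "G", "T"), substr(ref$sequence, pos, pos))[1L]))
  north_root <- mk_root(750L)
  south_root <- mk_root(8701L)
  mx <- cfg$mixture
  n_north <- mx$n_northern_aus + mx$n_new_guinea
  north <- simulate_sequences(star_genealogy(n_north, mx$tmrca_years), ref,
                              root_profile = north_root, seed = seed + 4L)
  south <- simulate_sequences(star_genealogy(mx$n_southern_aus,
                                             mx$tmrca_years), ref,
                              root_profile = south_root, seed = seed + 5L)
  names(north$sequences) <- paste0("N", seq_len(n_north))
  names(south$sequences) <- paste0("S", seq_len(mx$n_southern_aus))
  mix_seqs <- c(north$sequences, south$sequences)
  write_fasta(mix_seqs, file.path(dir, "mixture.fasta"))
  sheet <- data.frame(
    sample_id = names(mix_seqs),
    region_label = c(rep("Australia", mx$n_northern_aus),
                     rep("NewGuinea", mx$n_new_guinea),
                     rep("Australia", mx$n_southern_aus)),
    haplogroup = c(rep("Nclade", n_north), rep("Sclade", mx$n_southern_aus)),
    name = names(mix_seqs))
  utils::write.table(sheet, file.path(dir, "mixture_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(haplogroup = c("Nclade", "Sclade"),
                                route = c("northern", "southern")),
                     file.path(dir, "mixture_routes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$mixture <- list(samples = sheet, sequences = mix_seqs)

  cfg$seed <- as.integer(seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(out)
}
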