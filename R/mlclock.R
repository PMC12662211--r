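## Clock-constrained maximum-likelihood dating on a fixed topology, and BIC
## substitution-model selection.

#' Fit node heights under a strict molecular clock
#'
#' Maximizes the partitioned tree log-likelihood over internal node heights
#' with all tips at height 0 and every parent at least as high as its
#' children (ultrametric tree). Heights are in expected substitutions per
#' site, capped at `height_cap`. Optimization is coordinate-wise bounded
#' scalar search over node heights, swept until the log-likelihood improves
#' by less than `tol`, with optional random restarts from jittered starting
#' heights.
#'
#' @param alignment as in [tree_loglik()].
#' @param topology a rooted `phylo` or an `mp_tree` (converted with
#'   [mp_as_phylo()]); at least 2 tips.
#' @param model a `substitution_model` or list of one per partition.
#' @param parts optional `partition_scheme`.
#' @param positions rCRS coordinates of alignment columns.
#' @param tol convergence tolerance on the log-likelihood, default 1e-6.
#' @param max_sweeps maximum coordinate sweeps before flagging
#'   non-convergence.
#' @param restarts number of starts (1 = deterministic initialization only).
#' @param seed seed for restart jitter.
#' @param height_cap upper bound on the root height (substitutions/site).
#' @return object of class `clock_fit`: `tree` (phylo with fitted branch
#'   lengths), `heights` (per phylo node id), `loglik`, `converged`, plus
#'   the data needed for profile-likelihood intervals.
#' @export
fit_clock_heights <- function(alignment, topology, model, parts = NULL,
                              positions = NULL, tol = 1e-6,
                              max_sweeps = 100L, restarts = 1L, seed = NULL,
                              height_cap = 10) {
  phy <- if (inherits(topology, "mp_tree")) mp_as_phylo(topology) else topology
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("clock fit needs at least 2 tips")
  m <- alignment_matrix(alignment)
  if (is.null(positions)) positions <- seq_len(ncol(m))
  if (is.null(parts)) parts <- single_partition(positions)

  ctx <- clock_context(phy, m, model, parts, positions, height_cap)
  init <- clock_init_heights(ctx)
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }
  best <- NULL
  for (s in seq_len(max(1L, restarts))) {
    h0 <- if (s == 1L) init else jitter_heights(ctx, init)
    fit <- clock_sweep(ctx, h0, fixed = integer(), tol = tol,
                       max_sweeps = max_sweeps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  phy$edge.length <- edge_lengths_from_heights(ctx, best$heights)
  structure(list(tree = phy, heights = best$heights, loglik = best$loglik,
                 converged = best$converged, context = ctx),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  root <- x$context$root
  cat("Clock fit: ", length(x$tree$tip.label), " tips, root height ",
      signif(x$heights[root], 5), " subs/site, logLik ",
      signif(x$loglik, 8),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

clock_context <- function(phy, m, model, parts, positions, height_cap) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  root <- phy$edge[nrow(phy$edge), 1L]
  parent <- rep(NA_integer_, nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- lapply(seq_len(nnode), function(v) phy$edge[phy$edge[, 1L] == v, 2L])
  internals <- sort(setdiff(unique(phy$edge[, 1L]), seq_len(ntip)))
  list(phy = phy, m = m, model = model, parts = parts, positions = positions,
       ntip = ntip, nnode = nnode, root = root, parent = parent,
       children = children, internals = internals, height_cap = height_cap)
}

edge_lengths_from_heights <- function(ctx, h) {
  h[ctx$phy$edge[, 1L]] - h[ctx$phy$edge[, 2L]]
}

clock_loglik <- function(ctx, h) {
  phy <- ctx$phy
  phy$edge.length <- pmax(edge_lengths_from_heights(ctx, h), 0)
  tree_loglik(ctx$m, phy, ctx$model, ctx$parts, ctx$positions)
}

## Initialize heights from the mean pairwise mismatch fraction, spreading
## internal nodes by their depth below the root.
clock_init_heights <- function(ctx) {
  m <- ctx$m[ctx$phy$tip.label, , drop = FALSE]
  n <- nrow(m)
  d <- 0; np <- 0
  for (i in seq_len(min(n - 1, 10))) for (j in (i + 1):min(n, i + 5)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    if (any(ok)) { d <- d + mean(m[i, ok] != m[j, ok]); np <- np + 1 }
  }
  d <- if (np) max(d / np / 2, 1e-6) else 0.01
  depth <- node_depths(ctx)
  h <- numeric(ctx$nnode)
  below <- max(depth[ctx$internals]) + 1 - depth[ctx$internals]
  h[ctx$internals] <- d * below / max(below)
  h
}

node_depths <- function(ctx) {
  depth <- integer(ctx$nnode)
  for (v in seq_len(ctx$nnode)) {
    u <- v
    while (!is.na(ctx$parent[u])) { u <- ctx$parent[u]; depth[v] <- depth[v] + 1L }
  }
  depth
}

jitter_heights <- function(ctx, h) {
  h2 <- h
  h2[ctx$internals] <- h[ctx$internals] * stats::runif(length(ctx$internals),
                                                       0.5, 2)
  ## restore parent >= child by a root-down pass
  for (v in ctx$internals[order(node_depths(ctx)[ctx$internals])]) {
    p <- ctx$parent[v]
    if (!is.na(p)) h2[v] <- min(h2[v], h2[p])
  }
  h2
}

## Coordinate sweeps over internal node heights; `fixed` nodes are held.
clock_sweep <- function(ctx, h, fixed = integer(), tol = 1e-6,
                        max_sweeps = 100L) {
  free <- setdiff(ctx$internals, fixed)
  ll <- clock_loglik(ctx, h)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (v in free) {
      lb <- max(c(0, h[ctx$children[[v]]]))
      ub <- if (is.na(ctx$parent[v])) ctx$height_cap else h[ctx$parent[v]]
      if (ub - lb < 1e-12) { h[v] <- lb; next }
      opt <- stats::optimize(function(x) {
        h[v] <- x; clock_loglik(ctx, h)
      }, lower = lb, upper = ub, maximum = TRUE, tol = 1e-9)
      ## keep the boundary if it is at least as good
      for (b in c(lb, ub)) {
        h[v] <- b
        if (clock_loglik(ctx, h) > opt$objective) opt <- list(maximum = b,
          objective = clock_loglik(ctx, h))
      }
      h[v] <- opt$maximum
    }
    ll_new <- clock_loglik(ctx, h)
    if (abs(ll_new - ll) < tol * max(1, abs(ll_new))) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  if (!converged)
    warning("clock height optimization did not converge in ", max_sweeps,
            " sweeps")
  list(heights = h, loglik = ll, converged = converged)
}

#' Maximum-likelihood clade age with a profile-likelihood interval
#'
#' The age is the fitted clade-root height (substitutions per site) times
#' the genome length, mapped through the clock correction. The 95% CI comes
#' from the profile likelihood on the clade-root height: the heights where
#' the re-optimized log-likelihood drops 1.92 units below the maximum. If a
#' profile bracket cannot be found the curvature-based normal interval is
#' used and the estimate is flagged.
#'
#' @param fit a `clock_fit`.
#' @param clade_root phylo node id of the clade root (default the tree
#'   root).
#' @param clock a `clock_model`.
#' @param genome_length sites used for the substitutions conversion,
#'   default 16,569.
#' @param clade_id identifier stored in the estimate.
#' @param drop log-likelihood drop defining the interval, default 1.92
#'   (95%).
#' @return an `age_estimate` with method `"ml"`.
#' @export
ml_age <- function(fit, clade_root = fit$context$root,
                   clock = clock_model(), genome_length = MT_LENGTH,
                   clade_id = "clade", drop = 1.92) {
  stopifnot(inherits(fit, "clock_fit"), inherits(clock, "clock_model"))
  ctx <- fit$context
  h_hat <- fit$heights[clade_root]
  ll_max <- fit$loglik
  to_years <- function(h) clock$correction(h * genome_length)

  pl <- function(h0) {
    h <- fit$heights
    ## rescale the clade below and lift ancestors to keep feasibility
    desc <- phylo_descendants(ctx, clade_root)
    if (h_hat > 0) h[desc] <- h[desc] * (h0 / h_hat)
    h[clade_root] <- h0
    anc <- phylo_ancestors(ctx, clade_root)
    h[anc] <- pmax(h[anc], h0)
    clock_sweep(ctx, h, fixed = clade_root, tol = 1e-5,
                max_sweeps = 50L)$loglik
  }
  target <- ll_max - drop
  flag <- NA_character_
  ci <- tryCatch({
    lo <- profile_bound(pl, h_hat, target, side = "lower",
                        floor = max(fit$heights[ctx$children[[clade_root]]]))
    hi_cap <- if (is.na(ctx$parent[clade_root])) ctx$height_cap
              else fit$heights[ctx$parent[clade_root]]
    hi <- profile_bound(pl, h_hat, target, side = "upper", cap = hi_cap)
    c(lo, hi)
  }, error = function(e) NULL)
  if (is.null(ci)) {
    ## curvature fallback
    eps <- max(h_hat * 0.05, 1e-5)
    d2 <- (pl(h_hat + eps) - 2 * ll_max + pl(max(h_hat - eps, 0))) / eps^2
    se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else h_hat
    ci <- c(max(h_hat - 1.96 * se, 0), h_hat + 1.96 * se)
    flag <- "normal-approximation CI (profile bracket not found)"
  }
  age_estimate(clade_id, "ml", to_years(h_hat), to_years(ci[1L]),
               to_years(ci[2L]), flag = flag)
}

profile_bound <- function(pl, h_hat, target, side, floor = 0, cap = Inf) {
  if (side == "lower") {
    lo <- max(floor, 0)
    if (pl(lo) >= target) return(lo)
    stats::uniroot(function(h) pl(h) - target, lower = lo, upper = h_hat,
                   tol = max(h_hat, 1e-4) * 1e-4)$root
  } else {
    hi <- h_hat
    step <- max(h_hat, 1e-4)
    repeat {
      hi <- hi + step
      if (hi >= cap) { hi <- cap; break }
      if (pl(hi) < target) break
      step <- step * 2
    }
    if (pl(hi) >= target) return(hi)
    stats::uniroot(function(h) pl(h) - target, lower = h_hat, upper = hi,
                   tol = max(h_hat, 1e-4) * 1e-4)$root
  }
}

phylo_descendants <- function(ctx, node) {
  out <- integer(); queue <- ctx$children[[node]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(ctx$children[queue])
  }
  out
}

phylo_ancestors <- function(ctx, node) {
  out <- integer(); v <- ctx$parent[node]
  while (!is.na(v)) { out <- c(out, v); v <- ctx$parent[v] }
  out
}

#' Candidate model grid for BIC selection
#' @param kinds substitution model kinds.
#' @param rate_classes character flags among `""`, `"+I"`, `"+G"`, `"+I+G"`.
#' @param n_categories gamma categories used when `+G` is present.
#' @return list of candidate descriptors for [bic_select()].
#' @export
model_candidates <- function(kinds = c("JC69", "K80", "HKY85", "TN93"),
                             rate_classes = c("", "+G"),
                             n_categories = 6L) {
  out <- list()
  for (k in kinds) for (rc in rate_classes)
    out[[paste0(k, rc)]] <- list(kind = k,
                                 gamma = grepl("G", rc),
                                 invariant = grepl("I", rc),
                                 n_categories = n_categories)
  out
}

#' Rank substitution models by BIC on a fixed topology
#'
#' For each candidate, branch lengths and free model parameters are fitted
#' by maximum likelihood (base frequencies are the empirical alignment
#' frequencies, counted as free parameters for HKY85/TN93), then
#' `BIC = -2 logL + k log(n_sites)` with `k` the free model parameters plus
#' the branch lengths. Returns the table in ascending BIC order.
#'
#' @param alignment as in [tree_loglik()].
#' @param topology rooted `phylo` (or `mp_tree`).
#' @param candidates list from [model_candidates()] (>= 1 entry; with a
#'   single candidate the table has one row at rank 1).
#' @param parts optional `partition_scheme` (a single shared scheme; the
#'   same model family is fitted to each partition jointly here).
#' @param positions alignment column coordinates.
#' @return data.frame with columns `model`, `loglik`, `k`, `bic`, `rank`.
#' @export
bic_select <- function(alignment, topology, candidates, parts = NULL,
                       positions = NULL) {
  if (length(candidates) < 1L) stop("need at least one candidate model")
  phy <- if (inherits(topology, "mp_tree")) mp_as_phylo(topology) else topology
  m <- alignment_matrix(alignment)
  if (is.null(positions)) positions <- seq_len(ncol(m))
  n_sites <- ncol(m)
  counts <- table(factor(BASES[m], levels = BASES))
  emp_freq <- pmax(as.numeric(counts), 1) / sum(pmax(as.numeric(counts), 1))

  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    fit <- fit_model_branches(m, phy, cand, emp_freq, parts, positions)
    k_model <- switch(cand$kind, JC69 = 0L, K80 = 1L, HKY85 = 4L, TN93 = 5L) +
      cand$gamma + cand$invariant
    k <- k_model + nrow(phy$edge)
    data.frame(model = nm, loglik = fit$loglik, k = k,
               bic = -2 * fit$loglik + k * log(n_sites),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## Joint ML fit of branch lengths and model parameters by L-BFGS-B on
## transformed coordinates.
fit_model_branches <- function(m, phy, cand, emp_freq, parts, positions) {
  nb <- nrow(phy$edge)
  free_freq <- cand$kind %in% c("HKY85", "TN93")
  theta0 <- log(rep(0.05, nb))
  if (cand$kind != "JC69") theta0 <- c(theta0, log(2))        # kappa_R
  if (cand$kind == "TN93") theta0 <- c(theta0, log(2))        # kappa_Y
  if (cand$gamma) theta0 <- c(theta0, log(0.5))               # shape
  if (cand$invariant) theta0 <- c(theta0, stats::qlogis(0.2)) # pI

  build <- function(theta) {
    i <- nb
    kR <- 1; kY <- 1
    if (cand$kind != "JC69") { i <- i + 1L; kR <- exp(theta[i]); kY <- kR }
    if (cand$kind == "TN93") { i <- i + 1L; kY <- exp(theta[i]) }
    shape <- NULL; pI <- NULL
    if (cand$gamma) { i <- i + 1L; shape <- exp(theta[i]) }
    if (cand$invariant) { i <- i + 1L; pI <- stats::plogis(theta[i]) * 0.95 }
    substitution_model(cand$kind,
                       base_frequencies = if (free_freq) emp_freq
                                          else rep(0.25, 4),
                       transition_rate_purines = kR,
                       transition_rate_pyrimidines = kY,
                       transversion_rate = 1,
                       gamma_shape = shape,
                       n_categories = cand$n_categories,
                       p_invariant = pI)
  }
  negll <- function(theta) {
    tr <- phy
    tr$edge.length <- exp(theta[seq_len(nb)])
    mod <- build(theta)
    -tree_loglik(m, tr, mod, parts, positions)
  }
  opt <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = rep(-12, length(theta0)),
                      upper = rep(3, length(theta0)),
                      control = list(maxit = 300))
  list(loglik = -opt$value, theta = opt$par)
}
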