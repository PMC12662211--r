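## Partitioned TN93(+I)+Gamma likelihood machinery: reversible substitution
## models, discrete-gamma rates, and Felsenstein pruning on a fixed tree.

BASES <- c("A", "C", "G", "T")

#' Construct a reversible nucleotide substitution model
#'
#' The TN93 parameterization covers the nested family: JC69 (equal
#' frequencies and rates), K80 (equal frequencies, one transition/
#' transversion ratio), HKY85 (free frequencies, one ratio) and TN93 (free
#' frequencies, separate purine and pyrimidine transition rates). Rate
#' heterogeneity uses the discrete-gamma approximation with
#' equal-probability categories (category rate = within-category mean) and
#' an optional invariant-site class; rates are normalized so the expected
#' substitution rate is 1 and branch lengths are expected substitutions per
#' site.
#'
#' @param kind one of `"JC69"`, `"K80"`, `"HKY85"`, `"TN93"`.
#' @param base_frequencies length-4 vector (A, C, G, T) summing to 1;
#'   forced to 1/4 for JC69/K80.
#' @param transition_rate_purines,transition_rate_pyrimidines,transversion_rate
#'   exchange rates (only ratios matter); JC69 forces all equal, K80/HKY85
#'   force the two transition rates equal.
#' @param gamma_shape positive gamma shape, or `NULL` for equal rates.
#' @param n_categories number of discrete gamma categories, default 32.
#' @param p_invariant proportion of invariant sites in `[0, 1)`, or `NULL`.
#' @return object of class `substitution_model`.
#' @export
substitution_model <- function(kind = c("TN93", "HKY85", "K80", "JC69"),
                               base_frequencies = rep(0.25, 4),
                               transition_rate_purines = 1,
                               transition_rate_pyrimidines = 1,
                               transversion_rate = 1,
                               gamma_shape = NULL,
                               n_categories = 32L,
                               p_invariant = NULL) {
  kind <- match.arg(kind)
  pi <- as.numeric(base_frequencies)
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("base frequencies must be 4 positive numbers summing to 1")
  aR <- transition_rate_purines
  aY <- transition_rate_pyrimidines
  b <- transversion_rate
  if (any(c(aR, aY, b) <= 0)) stop("rates must be positive")
  if (kind %in% c("JC69", "K80")) pi <- rep(0.25, 4)
  if (kind == "JC69") { aR <- b; aY <- b }
  if (kind %in% c("K80", "HKY85")) aY <- aR
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  if (!is.null(p_invariant) && (p_invariant < 0 || p_invariant >= 1))
    stop("p_invariant must be in [0, 1)")

  ## rate matrix, order A C G T; transitions A<->G (purines), C<->T
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  R["A", "G"] <- R["G", "A"] <- aR
  R["C", "T"] <- R["T", "C"] <- aY
  R["A", "C"] <- R["C", "A"] <- b
  R["A", "T"] <- R["T", "A"] <- b
  R["C", "G"] <- R["G", "C"] <- b
  R["G", "T"] <- R["T", "G"] <- b
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu                         # mean rate 1

  ## symmetrized eigendecomposition (model is reversible)
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(kind = kind, base_frequencies = pi,
                 transition_rate_purines = aR,
                 transition_rate_pyrimidines = aY,
                 transversion_rate = b,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 p_invariant = p_invariant,
                 Q = Q, eigenvalues = eig$values,
                 U = diag(1 / sp) %*% eig$vectors,
                 Uinv = t(eig$vectors) %*% diag(sp)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(x$kind,
      if (!is.null(x$p_invariant)) "+I",
      if (!is.null(x$gamma_shape))
        paste0("+G", x$n_categories, " (shape ", signif(x$gamma_shape, 3), ")"),
      "\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#' @param model a `substitution_model`.
#' @param t branch length in expected substitutions per site (>= 0).
#' @param rate relative rate multiplier (e.g. a gamma category rate).
#' @return 4x4 matrix with rows summing to 1.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be nonnegative")
  P <- model$U %*% diag(exp(model$eigenvalues * t * rate)) %*% model$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma category rates
#'
#' Equal-probability categories with the category rate equal to the mean of
#' the gamma(shape, shape) density within the category, so the category
#' rates average 1.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return numeric vector of k rates.
#' @export
gamma_category_rates <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1L) return(1)
  b <- stats::qgamma((0:k) / k, shape = shape, rate = shape)
  r <- k * diff(stats::pgamma(b, shape = shape + 1, rate = shape))
  r / mean(r)
}

#' Default coding/control partition scheme
#'
#' Two partitions on the rCRS coordinate system: coding 577-16,023 and
#' control 16,024-16,569 plus 1-576 (wrapping the origin).
#'
#' @return object of class `partition_scheme`: named list of position sets.
#' @export
partition_scheme <- function() {
  structure(list(coding = CODING_START:CODING_END,
                 control = c(16024:16569, 1:576)),
            class = "partition_scheme")
}

#' Single-partition scheme covering given positions
#' @param positions integer positions (default full genome as one block).
#' @return a `partition_scheme` with one partition named `"all"`.
#' @export
single_partition <- function(positions = seq_len(MT_LENGTH)) {
  structure(list(all = as.integer(positions)), class = "partition_scheme")
}

## Map alignment column positions to partition index; 0 = not covered.
partition_index <- function(parts, positions) {
  idx <- integer(length(positions))
  for (i in seq_along(parts)) idx[positions %in% parts[[i]]] <- i
  idx
}

## Alignment coercion: accepts a character matrix (tips x sites, single
## characters), a named character vector of sequences, or a DNAStringSet.
## Returns an integer matrix (1..4, NA for ambiguous/unknown).
alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAStringSet") || inherits(alignment, "BStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (is.matrix(alignment) && is.numeric(alignment))
    return(alignment)                  # already encoded (1..4, NA unknown)
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (is.null(names(alignment))) stop("sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("sequences must be aligned (equal lengths)")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  stopifnot(is.matrix(alignment))
  m <- matrix(match(toupper(alignment), BASES), nrow(alignment),
              ncol(alignment))
  rownames(m) <- rownames(alignment)
  m
}

#' Partitioned log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning over the rooted tree, summing per site over the
#' discrete-gamma rate categories (equal weights) and, when `p_invariant`
#' is set, the invariant-site mixture with variable-class rates rescaled by
#' `1/(1 - p_invariant)` so the overall mean rate stays 1. Partition
#' log-likelihoods add; each partition has its own model instance.
#'
#' @param alignment tips-by-sites character matrix, named character vector
#'   of aligned sequences, or `DNAStringSet`; row/sequence names must match
#'   tip labels. Ambiguous bases (N, gaps) contribute no information.
#' @param tree rooted `phylo` with branch lengths in expected substitutions
#'   per site.
#' @param model a `substitution_model`, or list of one model per partition.
#' @param parts a `partition_scheme`; default one partition over all
#'   columns.
#' @param positions rCRS coordinates of the alignment columns (default
#'   1..ncol).
#' @return log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(alignment, tree, model, parts = NULL,
                        positions = NULL) {
  m <- alignment_matrix(alignment)
  if (is.null(positions)) positions <- seq_len(ncol(m))
  if (is.null(parts)) parts <- single_partition(positions)
  models <- if (inherits(model, "substitution_model"))
    rep(list(model), length(parts)) else model
  stopifnot(length(models) == length(parts))
  pidx <- partition_index(parts, positions)
  if (any(pidx == 0L))
    stop("alignment columns at positions ",
         paste(utils::head(positions[pidx == 0L]), collapse = ", "),
         " fall outside the partition scheme")
  ll <- 0
  for (i in seq_along(parts)) {
    cols <- which(pidx == i)
    if (!length(cols)) next
    ll <- ll + partition_loglik(m[, cols, drop = FALSE], tree, models[[i]])
  }
  ll
}

partition_loglik <- function(m, tree, model) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(rownames(m)) || !all(tree$tip.label %in% rownames(m)))
    stop("alignment rows must be named by the tree's tip labels")
  m <- m[tree$tip.label, , drop = FALSE]
  ## site-pattern compression
  key <- apply(m, 2L, paste, collapse = "\r")
  uq <- !duplicated(key)
  w <- as.vector(table(key)[key[uq]])
  pat <- m[, uq, drop = FALSE]
  npat <- ncol(pat)

  pI <- if (is.null(model$p_invariant)) 0 else model$p_invariant
  if (is.null(model$gamma_shape)) rates <- 1
  else rates <- gamma_category_rates(model$gamma_shape, model$n_categories)
  if (pI > 0) rates <- rates / (1 - pI)

  pruning <- prepare_pruning(tree)
  site_lik <- numeric(npat)
  pi <- model$base_frequencies
  for (r in rates) {
    Ps <- lapply(pruning$edge_lengths, transition_probabilities,
                 model = model, rate = r)
    root_part <- prune_partials(pat, pruning, Ps)
    site_lik <- site_lik + colSums(pi * root_part) / length(rates)
  }
  if (pI > 0) {
    inv <- invariant_site_lik(pat, pi)
    site_lik <- (1 - pI) * site_lik + pI * inv
  }
  sum(w * log(site_lik))
}

## Per-pattern likelihood of the invariant-site class: nonzero only when
## all unambiguous states agree; equals pi[state] (or 1 if no information).
invariant_site_lik <- function(pat, pi) {
  apply(pat, 2L, function(col) {
    st <- unique(col[!is.na(col)])
    if (length(st) == 0L) 1
    else if (length(st) == 1L) pi[st]
    else 0
  })
}

prepare_pruning <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(edge = tree$edge, edge_lengths = tree$edge.length,
       ntip = length(tree$tip.label),
       root = tree$edge[nrow(tree$edge), 1L],
       nnode = max(tree$edge))
}

## Conditional likelihood propagation; returns 4 x npat partials at root.
prune_partials <- function(pat, pruning, Ps) {
  npat <- ncol(pat)
  partials <- vector("list", pruning$nnode)
  for (tp in seq_len(pruning$ntip)) {
    P <- matrix(0, 4, npat)
    st <- pat[tp, ]
    known <- !is.na(st)
    P[, !known] <- 1
    P[cbind(st[known], which(known))] <- 1
    partials[[tp]] <- P
  }
  for (k in seq_len(nrow(pruning$edge))) {
    par <- pruning$edge[k, 1L]; child <- pruning$edge[k, 2L]
    msg <- Ps[[k]] %*% partials[[child]]
    if (is.null(partials[[par]])) partials[[par]] <- msg
    else partials[[par]] <- partials[[par]] * msg
  }
  partials[[pruning$root]]
}

#' Brute-force log-likelihood by ancestral-state enumeration
#'
#' Sums the joint probability over every assignment of states to internal
#' nodes, site by site; exponential in the node count, so restricted to
#' small trees. Independent oracle for [tree_loglik()].
#'
#' @inheritParams tree_loglik
#' @param max_internal refuse trees with more internal nodes than this.
#' @return log-likelihood.
#' @export
tree_loglik_bruteforce <- function(alignment, tree, model, parts = NULL,
                                   positions = NULL, max_internal = 6L) {
  m <- alignment_matrix(alignment)
  if (is.null(positions)) positions <- seq_len(ncol(m))
  if (is.null(parts)) parts <- single_partition(positions)
  models <- if (inherits(model, "substitution_model"))
    rep(list(model), length(parts)) else model
  pidx <- partition_index(parts, positions)
  ll <- 0
  for (i in seq_along(parts)) {
    cols <- which(pidx == i)
    if (!length(cols)) next
    ll <- ll + bf_partition(m[, cols, drop = FALSE], tree, models[[i]],
                            max_internal)
  }
  ll
}

bf_partition <- function(m, tree, model, max_internal) {
  tree <- stats::reorder(tree, "postorder")
  m <- m[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internals <- setdiff(seq_len(nnode), seq_len(ntip))
  if (length(internals) > max_internal)
    stop("brute-force oracle refuses > ", max_internal, " internal nodes")
  root <- tree$edge[nrow(tree$edge), 1L]
  pI <- if (is.null(model$p_invariant)) 0 else model$p_invariant
  rates <- if (is.null(model$gamma_shape)) 1
           else gamma_category_rates(model$gamma_shape, model$n_categories)
  if (pI > 0) rates <- rates / (1 - pI)
  pi <- model$base_frequencies

  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  total <- numeric(ncol(m))
  for (r in rates) {
    Ps <- lapply(tree$edge.length, transition_probabilities, model = model,
                 rate = r)
    for (s in seq_len(ncol(m))) {
      lik <- 0
      tipst <- m[, s]
      for (g in seq_len(nrow(grid))) {
        state <- integer(nnode)
        state[seq_len(ntip)] <- tipst
        state[internals] <- grid[g, ]
        p <- pi[state[root]]
        ok <- TRUE
        for (k in seq_len(nrow(tree$edge))) {
          a <- state[tree$edge[k, 1L]]; b <- state[tree$edge[k, 2L]]
          if (is.na(b)) next           # unknown tip: marginalize
          p <- p * Ps[[k]][a, b]
        }
        ## unknown tips: sum over their states
        unk <- which(is.na(tipst))
        if (length(unk)) {
          for (u in unk) {
            k <- which(tree$edge[, 2L] == u)
            p <- p * sum(Ps[[k]][state[tree$edge[k, 1L]], ])
          }
        }
        if (ok) lik <- lik + p
      }
      total[s] <- total[s] + lik / length(rates)
    }
  }
  if (pI > 0) {
    inv <- invariant_site_lik(m, pi)
    total <- (1 - pI) * total + pI * inv
  }
  sum(log(total))
}
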