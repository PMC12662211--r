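## Maximum-parsimony haplotype trees: greedy shared-variant agglomeration
## with an exhaustive Fitch oracle for small instances.

## Tokens relative to a clade root haplotype: gains are variants present in
## the profile but not the root; losses (back mutations toward the root
## haplotype) are root variants absent from the profile, suffixed "!".
relative_tokens <- function(profile, root_profile = NULL) {
  pt <- variant_tokens(profile$variants)
  rt <- if (is.null(root_profile)) character()
        else variant_tokens(root_profile$variants)
  gains <- setdiff(pt, rt)
  losses <- setdiff(rt, pt)
  sort(c(gains, if (length(losses)) paste0(losses, "!")))
}

token_position <- function(tokens) {
  as.integer(gsub("[^0-9]", "", sub("\\+.*$", "", sub("!$", "", tokens))))
}

## Lookup table token -> variant annotation row (position, ref, alt, vclass,
## region, back) built from the profiles that generated the tokens.
token_info_table <- function(profiles, root_profile = NULL) {
  all_p <- c(profiles, if (!is.null(root_profile)) list(root_profile))
  tabs <- lapply(all_p, function(p) {
    v <- p$variants
    if (!nrow(v)) return(NULL)
    cbind(token = variant_tokens(v), v, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(token = character(), position = integer(),
                      ref = character(), alt = character(),
                      vclass = character(), region = character(),
                      stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$token), , drop = FALSE]
  ## loss tokens share the annotation of the gained variant they revert
  loss <- tab
  if (nrow(loss)) loss$token <- paste0(loss$token, "!")
  tab$back <- rep(FALSE, nrow(tab))
  loss$back <- rep(TRUE, nrow(loss))
  out <- rbind(tab, loss)
  rownames(out) <- NULL
  out
}

#' Build a maximum-parsimony haplotype tree
#'
#' Greedy agglomerative construction: identical haplotypes collapse to one
#' tip with multiplicity, then an internal node is created for the variant
#' shared by the largest number of unplaced haplotypes (ties broken by
#' lowest position, then token), recursing until every haplotype is placed
#' as a tip. Unary internal chains are compacted so each edge may carry
#' several mutations. The tree's parsimony score is the total mutation count
#' over edges; a recurrent mutation counts once per edge it occurs on.
#'
#' @param profiles list of masked `variant_profile` objects.
#' @param root_profile the clade's ancestral haplotype as a
#'   `variant_profile` (NULL = identical to the reference).
#' @param root_label label stored at the root (e.g. the ancestral
#'   haplogroup).
#' @return object of class `mp_tree` with components `parent` (integer,
#'   `NA` at the root), `mutations` (list of per-edge variant tables),
#'   `samples` (list of tip sample ids), `is_tip`, `root`, `score`,
#'   `root_label`.
#' @export
build_mp_tree <- function(profiles, root_profile = NULL, root_label = "root") {
  stopifnot(length(profiles) >= 1L)
  rel <- lapply(profiles, relative_tokens, root_profile = root_profile)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample_id among profiles")
  key <- vapply(rel, paste, "", collapse = " ")
  haps <- lapply(split(seq_along(profiles), key), function(ix) {
    list(tokens = rel[[ix[1L]]], samples = sort(ids[ix]))
  })
  ## deterministic processing order
  haps <- haps[order(vapply(haps, function(h) h$samples[1L], ""))]

  env <- new.env(parent = emptyenv())
  env$parent <- NA_integer_
  env$edge_tokens <- list(character())
  env$samples <- list(character())
  new_node <- function(parent, tokens, samples = character()) {
    id <- length(env$parent) + 1L
    env$parent[id] <- parent
    env$edge_tokens[[id]] <- tokens
    env$samples[[id]] <- samples
    id
  }

  grow <- function(node, haps) {
    ## haplotypes identical to this node's haplotype become zero-edge tips
    empt <- vapply(haps, function(h) length(h$tokens) == 0L, TRUE)
    for (h in haps[empt]) new_node(node, character(), h$samples)
    haps <- haps[!empt]
    while (length(haps)) {
      tokens <- unlist(lapply(haps, `[[`, "tokens"))
      cnt <- table(tokens)
      mx <- max(cnt)
      if (mx >= 2L && length(haps) > 1L) {
        best <- names(cnt)[cnt == mx]
        best <- best[order(token_position(best), best)][1L]
        inset <- vapply(haps, function(h) best %in% h$tokens, TRUE)
        child <- new_node(node, best)
        sub <- lapply(haps[inset], function(h) {
          h$tokens <- setdiff(h$tokens, best); h
        })
        grow(child, sub)
        haps <- haps[!inset]
      } else {
        for (h in haps) new_node(node, h$tokens, h$samples)
        haps <- list()
      }
    }
  }
  grow(1L, haps)

  tree <- compact_mp(list(parent = env$parent,
                          edge_tokens = env$edge_tokens,
                          samples = env$samples, root = 1L))
  finalize_mp_tree(tree, profiles, root_profile, root_label)
}

## Merge unary internal (non-root, sample-free) nodes into their child edge.
compact_mp <- function(tree) {
  repeat {
    kids <- tabulate(tree$parent[!is.na(tree$parent)], length(tree$parent))
    unary <- which(kids == 1L & !vapply(tree$samples, length, 1L) &
                   !is.na(tree$parent))
    if (!length(unary)) break
    v <- unary[1L]
    c_id <- which(!is.na(tree$parent) & tree$parent == v)
    tree$edge_tokens[[c_id]] <- c(tree$edge_tokens[[v]],
                                  tree$edge_tokens[[c_id]])
    tree$parent[c_id] <- tree$parent[v]
    keep <- setdiff(seq_along(tree$parent), v)
    remap <- integer(length(tree$parent)); remap[keep] <- seq_along(keep)
    tree <- list(parent = remap[tree$parent[keep]],
                 edge_tokens = tree$edge_tokens[keep],
                 samples = tree$samples[keep],
                 root = remap[tree$root])
    tree$parent[tree$root] <- NA_integer_
  }
  tree
}

finalize_mp_tree <- function(tree, profiles, root_profile, root_label) {
  info <- token_info_table(profiles, root_profile)
  muts <- lapply(tree$edge_tokens, function(tk) {
    rows <- info[match(tk, info$token), , drop = FALSE]
    rows <- rows[order(rows$position, rows$token), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
  is_tip <- vapply(tree$samples, length, 1L) > 0L
  structure(list(parent = tree$parent, mutations = muts,
                 samples = tree$samples, is_tip = is_tip,
                 root = tree$root, root_label = root_label,
                 score = sum(vapply(muts, nrow, 1L))),
            class = "mp_tree")
}

#' @export
print.mp_tree <- function(x, ...) {
  cat("Maximum-parsimony tree: ", sum(x$is_tip), " haplotype tips, ",
      sum(lengths(x$samples)), " samples, score ", x$score, "\n", sep = "")
  invisible(x)
}

mp_children <- function(tree, node) {
  which(!is.na(tree$parent) & tree$parent == node)
}

#' Nodes of the clade subtended by a node
#' @param tree an `mp_tree`.
#' @param node internal node id (default the root).
#' @return integer vector of descendant node ids (excluding `node`).
#' @export
mp_descendants <- function(tree, node = tree$root) {
  out <- integer(); queue <- mp_children(tree, node)
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(lapply(queue, mp_children, tree = tree))
  }
  out
}

#' Tips subtended by each node, counting sample multiplicity
#' @param tree an `mp_tree`.
#' @return integer vector over nodes: number of samples at or below each
#'   node.
#' @export
mp_tips_below <- function(tree) {
  n <- length(tree$parent)
  below <- lengths(tree$samples)
  ## accumulate children into parents, deepest first
  depth <- integer(n)
  for (v in seq_len(n)) {
    d <- 0L; u <- v
    while (!is.na(tree$parent[u])) { u <- tree$parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  for (v in order(depth, decreasing = TRUE)) {
    p <- tree$parent[v]
    if (!is.na(p)) below[p] <- below[p] + below[v]
  }
  below
}

#' Replay edge mutations from the root to a node
#'
#' Gains accumulate along the path and back mutations cancel, reproducing
#' the haplotype (token set relative to the clade root) at the node.
#'
#' @param tree an `mp_tree`.
#' @param node node id.
#' @return sorted character vector of tokens.
#' @export
mp_replay <- function(tree, node) {
  path <- node
  while (!is.na(tree$parent[path[1L]]))
    path <- c(tree$parent[path[1L]], path)
  acc <- character()
  for (v in path) {
    tk <- tree$mutations[[v]]$token
    if (is.null(tk)) next
    for (t in tk) {
      if (endsWith(t, "!") && sub("!$", "", t) %in% acc)
        acc <- setdiff(acc, sub("!$", "", t))
      else if (paste0(t, "!") %in% acc)
        acc <- setdiff(acc, paste0(t, "!"))
      else acc <- c(acc, t)
    }
  }
  sort(acc)
}

#' Exhaustive small-parsimony oracle
#'
#' Enumerates every rooted binary topology over the distinct haplotypes,
#' scores each by Fitch counting on binary presence/absence characters with
#' the root fixed at the ancestral (all-absent) state, and returns the
#' minimum score. Refuses more than `max_haplotypes` distinct haplotypes.
#'
#' @param profiles list of `variant_profile`.
#' @param root_profile ancestral haplotype (NULL = reference).
#' @param max_haplotypes combinatorial guard, default 8.
#' @return integer minimum parsimony score.
#' @export
parsimony_oracle <- function(profiles, root_profile = NULL,
                             max_haplotypes = 8L) {
  rel <- lapply(profiles, relative_tokens, root_profile = root_profile)
  key <- vapply(rel, paste, "", collapse = " ")
  haps <- rel[!duplicated(key)]
  h <- length(haps)
  if (h > max_haplotypes)
    stop("parsimony_oracle refuses more than ", max_haplotypes,
         " distinct haplotypes (got ", h, ")")
  chars <- sort(unique(unlist(haps)))
  if (!length(chars)) return(0L)
  ## bitmask state per tip and character: 1 = absent, 2 = present
  states <- lapply(haps, function(tk)
    ifelse(chars %in% tk, 2L, 1L))
  if (h == 1L) return(length(states[[1L]][states[[1L]] == 2L]))
  best <- Inf
  for (tr in rooted_topologies(h)) {
    sc <- fitch_score(tr, states)
    if (sc < best) best <- sc
  }
  as.integer(best)
}

## Cache of rooted binary topologies (nested pair lists) per tip count.
.topo_cache <- new.env(parent = emptyenv())

rooted_topologies <- function(n) {
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  trees <- list(1L)
  if (n >= 2L) for (k in 2:n) {
    trees <- unlist(lapply(trees, insert_tip, k = k), recursive = FALSE)
  }
  .topo_cache[[key]] <- trees
  trees
}

insert_tip <- function(tr, k) {
  res <- list(list(tr, k))
  if (is.list(tr)) {
    for (L in insert_tip(tr[[1L]], k)) res <- c(res, list(list(L, tr[[2L]])))
    for (R in insert_tip(tr[[2L]], k)) res <- c(res, list(list(tr[[1L]], R)))
  }
  res
}

## Fitch small parsimony on bitmask vectors; root state fixed to "absent".
fitch_score <- function(tr, states) {
  rec <- function(node) {
    if (!is.list(node)) return(list(set = states[[node]], score = 0L))
    a <- rec(node[[1L]]); b <- rec(node[[2L]])
    inter <- bitwAnd(a$set, b$set)
    extra <- inter == 0L
    set <- ifelse(extra, bitwOr(a$set, b$set), inter)
    list(set = set, score = a$score + b$score + sum(extra))
  }
  r <- rec(tr)
  r$score + sum(bitwAnd(r$set, 1L) == 0L)
}

#' Propose new haplogroup labels from a parsimony tree
#'
#' A candidate internal node is accepted as a new haplogroup only when it
#' subtends at least five samples (counting multiplicity) and at least two
#' distinct haplotypes, and its defining edge carries at least one
#' coding-region mutation (a clade defined by control-region mutations alone
#' is rejected).
#'
#' @param tree an `mp_tree` with region-annotated edge mutations.
#' @return data.frame with columns `node`, `n_samples`, `n_haplotypes`,
#'   `accepted`, `reason`.
#' @export
propose_haplogroups <- function(tree) {
  stopifnot(inherits(tree, "mp_tree"))
  below <- mp_tips_below(tree)
  cands <- which(!tree$is_tip & !is.na(tree$parent))
  rows <- lapply(cands, function(v) {
    desc <- mp_descendants(tree, v)
    n_hap <- sum(tree$is_tip[desc])
    n_samp <- below[v]
    muts <- tree$mutations[[v]]
    reason <- "ok"
    accepted <- TRUE
    if (n_samp < 5L) { accepted <- FALSE; reason <- "fewer than five samples" }
    else if (n_hap < 2L) { accepted <- FALSE; reason <- "fewer than two haplotypes" }
    else if (!nrow(muts)) { accepted <- FALSE; reason <- "no defining mutation" }
    else if (!any(muts$region == "coding")) {
      accepted <- FALSE; reason <- "control region mutation alone"
    }
    data.frame(node = v, n_samples = n_samp, n_haplotypes = n_hap,
               accepted = accepted, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = integer(), n_samples = integer(),
                      n_haplotypes = integer(), accepted = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert a parsimony tree to an ape `phylo` object
#'
#' Tip labels are the collapsed sample ids joined with `|`; branch lengths
#' are edge mutation counts.
#'
#' @param tree an `mp_tree`.
#' @return a `phylo`.
#' @export
mp_as_phylo <- function(tree) {
  stopifnot(inherits(tree, "mp_tree"))
  tips <- which(tree$is_tip)
  internals <- which(!tree$is_tip)
  ntip <- length(tips)
  if (ntip < 2L) stop("phylo conversion needs at least 2 haplotype tips")
  id_map <- integer(length(tree$parent))
  id_map[tips] <- seq_len(ntip)
  id_map[internals] <- ntip + seq_along(internals)
  has_edge <- which(!is.na(tree$parent))
  edge <- cbind(id_map[tree$parent[has_edge]], id_map[has_edge])
  lens <- vapply(tree$mutations[has_edge], nrow, 1L)
  phy <- list(edge = edge,
              edge.length = as.numeric(lens),
              tip.label = vapply(tree$samples[tips], paste, "",
                                 collapse = "|"),
              Nnode = length(internals))
  class(phy) <- "phylo"
  phy <- ape::collapse.singles(phy)
  stats::reorder(phy)
}

#' Write a parsimony tree as Newick with mutation annotations
#'
#' Edge mutations are encoded in comment blocks, e.g.
#' `[&mutations=A769G|T16189C]`, after the branch length.
#'
#' @param tree an `mp_tree`.
#' @param path optional output file; when NULL the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
mp_write_newick <- function(tree, path = NULL) {
  lab <- function(v) {
    if (tree$is_tip[v]) paste(tree$samples[[v]], collapse = "|")
    else ""
  }
  fmt <- function(v) {
    kids <- mp_children(tree, v)
    core <- if (length(kids))
      paste0("(", paste(vapply(kids, fmt, ""), collapse = ","), ")", lab(v))
    else lab(v)
    if (is.na(tree$parent[v])) return(paste0(core, ";"))
    tk <- tree$mutations[[v]]$token
    ann <- if (length(tk)) paste0("[&mutations=", paste(tk, collapse = "|"), "]")
           else ""
    paste0(core, ":", nrow(tree$mutations[[v]]), ann)
  }
  s <- fmt(tree$root)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' Write the flat edge table of a parsimony tree
#'
#' @param tree an `mp_tree`.
#' @param path output TSV path.
#' @return the data.frame, invisibly.
#' @export
mp_write_edge_table <- function(tree, path) {
  below <- mp_tips_below(tree)
  has_edge <- which(!is.na(tree$parent))
  out <- data.frame(
    child_node = has_edge,
    parent_node = tree$parent[has_edge],
    mutations = vapply(tree$mutations[has_edge], function(m)
      paste(m$token, collapse = "|"), ""),
    n_tips_below = below[has_edge],
    samples = vapply(tree$samples[has_edge], paste, "", collapse = "|"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
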