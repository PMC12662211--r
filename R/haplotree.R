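## Haplogroup classification against a PhyloTree-style reference motif tree.

#' Construct a reference haplogroup tree
#'
#' @param labels character vector of haplogroup labels (unique).
#' @param parents character vector of parent labels; `NA` or `""` for the
#'   single root.
#' @param motifs character vector of space-separated defining-mutation
#'   tokens in PhyloTree notation (e.g. `"A769G"`, `"T16189C!"`; the `!`
#'   suffix marks a back mutation cancelling the ancestral variant at that
#'   position). Motifs are relative to the parent node.
#' @return object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(labels, parents, motifs) {
  stopifnot(length(labels) == length(parents),
            length(labels) == length(motifs))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("haplogroup labels must be unique")
  parents <- as.character(parents)
  parents[!nzchar(parents) | is.na(parents)] <- NA_character_
  roots <- labels[is.na(parents)]
  if (length(roots) != 1L)
    stop("reference tree must have exactly one root, found ", length(roots))
  known <- parents[!is.na(parents)]
  if (!all(known %in% labels))
    stop("unknown parent labels: ",
         paste(setdiff(known, labels), collapse = ", "))
  parsed <- lapply(motifs, parse_motif)
  names(parsed) <- labels
  names(parents) <- labels
  ## depth by walking to the root; also detects cycles
  depth <- vapply(labels, function(l) {
    d <- 0L
    while (!is.na(parents[[l]])) {
      l <- parents[[l]]; d <- d + 1L
      if (d > length(labels)) stop("cycle in reference tree")
    }
    d
  }, integer(1L))
  structure(list(labels = labels, parents = parents, motifs = parsed,
                 root = roots, depth = depth),
            class = "haplogroup_tree")
}

## "A769G" -> substitution; "T16189C!" -> back mutation flag.
parse_motif <- function(motif) {
  toks <- strsplit(trimws(motif), "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), back = logical(),
                      stringsAsFactors = FALSE))
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)([A-Z])(!?)$", toks))
  bad <- toks[vapply(m, length, 1L) == 0L]
  if (length(bad)) stop("unparseable motif tokens: ",
                        paste(bad, collapse = ", "))
  data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
             ref = vapply(m, `[`, "", 2L),
             alt = vapply(m, `[`, "", 4L),
             back = vapply(m, `[`, "", 5L) == "!",
             stringsAsFactors = FALSE)
}

#' Read a reference haplogroup tree from TSV
#'
#' Columns `label`, `parent`, `motif` (space-separated PhyloTree tokens;
#' empty parent marks the root).
#' @param path TSV path.
#' @return a `haplogroup_tree`.
#' @export
read_haplogroup_tree <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("label", "parent", "motif") %in% names(tab)))
  tab$motif[is.na(tab$motif)] <- ""
  haplogroup_tree(tab$label, tab$parent, tab$motif)
}

#' Expected derived variants of a haplogroup
#'
#' Accumulates defining mutations along the root-to-node path; a back
#' mutation (`!`) cancels the accumulated variant at its position.
#'
#' @param tree a `haplogroup_tree`.
#' @param label haplogroup label.
#' @return data.frame with columns `position`, `ref`, `alt`.
#' @export
expected_variants <- function(tree, label) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (!label %in% tree$labels) stop("unknown haplogroup label: ", label)
  path <- label
  while (!is.na(tree$parents[[path[1L]]]))
    path <- c(tree$parents[[path[1L]]], path)
  acc <- data.frame(position = integer(), ref = character(),
                    alt = character(), stringsAsFactors = FALSE)
  for (l in path) {
    mot <- tree$motifs[[l]]
    for (i in seq_len(nrow(mot))) {
      if (mot$back[i]) {
        acc <- acc[acc$position != mot$position[i], , drop = FALSE]
      } else {
        acc <- rbind(acc, mot[i, c("position", "ref", "alt")])
      }
    }
  }
  acc <- acc[order(acc$position), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Classify a variant profile against the reference haplogroup tree
#'
#' Scores every node by (matched defining variants on the root-to-node path)
#' minus (expected variants absent from the profile) and returns the
#' maximizer; ties break toward greater depth, then lexicographically
#' smaller label. Matching is by position and alternate allele.
#'
#' @param profile a masked `variant_profile`.
#' @param ref_tree a `haplogroup_tree`.
#' @return object of class `haplogroup_call` with fields `sample_id`,
#'   `best_label`, `score` (fraction of expected variants observed, 1 at the
#'   root) and `path_depth`.
#' @export
classify <- function(profile, ref_tree) {
  stopifnot(inherits(profile, "variant_profile"))
  if (!inherits(ref_tree, "haplogroup_tree") || !length(ref_tree$labels))
    stop("reference haplogroup tree is empty or invalid")
  have <- paste0(profile$variants$position, ":", profile$variants$alt)
  best <- NULL
  for (l in ref_tree$labels) {
    exp_v <- expected_variants(ref_tree, l)
    keys <- paste0(exp_v$position, ":", exp_v$alt)
    matched <- sum(keys %in% have)
    stat <- matched - (length(keys) - matched)
    cand <- list(label = l, stat = stat, depth = ref_tree$depth[[l]],
                 frac = if (length(keys)) matched / length(keys) else 1)
    if (is.null(best) || cand$stat > best$stat ||
        (cand$stat == best$stat && cand$depth > best$depth) ||
        (cand$stat == best$stat && cand$depth == best$depth &&
         cand$label < best$label))
      best <- cand
  }
  structure(list(sample_id = profile$sample_id, best_label = best$label,
                 score = best$frac, path_depth = as.integer(best$depth)),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat("Sample ", x$sample_id, " -> ", x$best_label,
      " (score ", signif(x$score, 3), ", depth ", x$path_depth, ")\n",
      sep = "")
  invisible(x)
}
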