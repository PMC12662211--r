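## Variant profiles: a sample's differences from the rCRS, with site-type
## annotations, masking, and heteroplasmy calling.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Build a variant table
#'
#' Each row is one difference from the reference: a substitution
#' (`ref`/`alt` single bases), an insertion (`ref == "-"`, `alt` the inserted
#' bases, `position` the rCRS position after which they are inserted), or a
#' deletion (`alt == "-"`). The variant class and coding/control region are
#' derived from the alleles and position.
#'
#' @param position integer vector of 1-based rCRS coordinates.
#' @param ref,alt character vectors of reference and alternate alleles;
#'   `"-"` denotes a gap.
#' @return data.frame with columns `position`, `ref`, `alt`, `vclass`,
#'   `region`, sorted by position.
#' @export
variant_table <- function(position = integer(), ref = character(),
                          alt = character()) {
  stopifnot(length(position) == length(ref), length(ref) == length(alt))
  if (!length(position)) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), vclass = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  vclass <- mapply(classify_change, ref, alt, USE.NAMES = FALSE)
  out <- data.frame(position = position, ref = ref, alt = alt,
                    vclass = vclass, region = mito_region(position),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

classify_change <- function(ref, alt) {
  if (identical(ref, alt)) stop("ref and alt alleles are identical: ", ref)
  if (ref == "-") return("insertion")
  if (alt == "-") return("deletion")
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("substitutions must be single-base: ", ref, ">", alt)
  same_class <- (ref %in% PURINES && alt %in% PURINES) ||
    (ref %in% PYRIMIDINES && alt %in% PYRIMIDINES)
  if (same_class) "transition" else "transversion"
}

#' Construct a variant profile
#'
#' @param sample_id sample identifier.
#' @param variants a variant table from [variant_table()].
#' @param region_label optional sampling-region label.
#' @param masked_removed count of variants removed by masking so far.
#' @return object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, variants = variant_table(),
                            region_label = NA_character_,
                            masked_removed = 0L) {
  stopifnot(is.data.frame(variants))
  variants <- variants[order(variants$position, variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 region_label = as.character(region_label),
                 variants = variants,
                 masked_removed = as.integer(masked_removed)),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("Variant profile '", x$sample_id, "': ", nrow(x$variants),
      " variants (", x$masked_removed, " masked)\n", sep = "")
  if (nrow(x$variants)) print(utils::head(x$variants, 20L))
  invisible(x)
}

#' Compact mtDNA-style variant tokens
#'
#' Substitutions print as e.g. `"A769G"`, insertions as `"309+C"`, deletions
#' as `"C515d"`.
#'
#' @param variants a variant table.
#' @return character vector of tokens.
#' @export
variant_tokens <- function(variants) {
  if (!nrow(variants)) return(character())
  ifelse(variants$vclass == "insertion",
         paste0(variants$position, "+", variants$alt),
         ifelse(variants$vclass == "deletion",
                paste0(variants$ref, variants$position, "d"),
                paste0(variants$ref, variants$position, variants$alt)))
}

#' Call variants in a sample against the reference
#'
#' Equal-length sequences are compared position by position. Unequal lengths
#' trigger an affine-gap global alignment (match 1, mismatch -1, gap open 8,
#' gap extend 1 by default) before extraction. Indels are normalized to their
#' 3'-most equivalent placement, following forensic mtDNA nomenclature.
#' Unknown bases (`N`) in the sample generate no variants and are excluded
#' from the identity denominator.
#'
#' @param sample_seq nucleotide string for the sample.
#' @param ref a `mito_reference`.
#' @param sample_id sample identifier stored in the profile.
#' @param region_label optional sampling-region label.
#' @param min_identity minimum alignment identity (over non-N sites) below
#'   which the input is rejected as not a mitogenome. Default 0.95.
#' @param gap_opening,gap_extension positive alignment gap penalties.
#' @return a `variant_profile`.
#' @export
call_variants <- function(sample_seq, ref, sample_id = "sample",
                          region_label = NA_character_,
                          min_identity = 0.95,
                          gap_opening = 8, gap_extension = 1) {
  stopifnot(inherits(ref, "mito_reference"))
  if (!is.character(sample_seq) || !nzchar(sample_seq))
    stop("sample sequence must be a non-empty string")
  sample_seq <- toupper(sample_seq)
  schars <- strsplit(sample_seq, "", fixed = TRUE)[[1L]]

  if (length(schars) == ref$length) {
    rchars <- ref$chars
    informative <- schars != "N" & rchars != "N"
    diff <- which(informative & schars != rchars)
    ident <- 1 - length(diff) / max(sum(informative), 1L)
    if (ident < min_identity)
      stop("alignment identity ", signif(ident, 4), " below floor ",
           min_identity, ": not a mitogenome?")
    vt <- variant_table(diff, rchars[diff], schars[diff])
    return(variant_profile(sample_id, vt, region_label))
  }

  aln <- Biostrings::pairwiseAlignment(
    pattern = sample_seq, subject = ref$sequence, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  extract_from_alignment(pat, sub, ref, sample_id, region_label, min_identity)
}

## pat = aligned sample, sub = aligned reference (with '-' gaps)
extract_from_alignment <- function(pat, sub, ref, sample_id, region_label,
                                   min_identity) {
  stopifnot(length(pat) == length(sub))
  rpos <- cumsum(sub != "-")      # rCRS coordinate at each column
  informative <- pat != "N" & sub != "-" & pat != "-"
  n_mismatch <- sum(informative & pat != sub)
  ident <- 1 - n_mismatch / max(sum(informative), 1L)
  if (ident < min_identity)
    stop("alignment identity ", signif(ident, 4), " below floor ",
         min_identity, ": not a mitogenome?")

  pos <- integer(); rr <- character(); aa <- character()
  ## substitutions
  is_sub <- informative & pat != sub
  if (any(is_sub)) {
    pos <- rpos[is_sub]; rr <- sub[is_sub]; aa <- pat[is_sub]
  }
  ## indel runs
  gap <- sub == "-" | pat == "-"
  if (any(gap)) {
    runs <- rle(gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      cols <- starts[k]:ends[k]
      if (all(sub[cols] == "-")) {           # insertion in sample
        ins <- paste(pat[cols], collapse = "")
        p <- if (starts[k] == 1L) 0L else rpos[starts[k] - 1L]
        norm <- normalize_insertion(p, ins, ref$chars)
        pos <- c(pos, norm$position); rr <- c(rr, "-"); aa <- c(aa, norm$alt)
      } else if (all(pat[cols] == "-")) {    # deletion from reference
        p0 <- rpos[starts[k]]
        width <- length(cols)
        p0 <- normalize_deletion(p0, width, ref$chars)
        pos <- c(pos, p0:(p0 + width - 1L))
        rr <- c(rr, ref$chars[p0:(p0 + width - 1L)])
        aa <- c(aa, rep("-", width))
      }
    }
  }
  variant_profile(sample_id, variant_table(pos, rr, aa), region_label)
}

## Shift an insertion (after `position`) to its 3'-most equivalent placement:
## while the next reference base equals the first inserted base, slide right
## and rotate the inserted string.
normalize_insertion <- function(position, alt, ref_chars) {
  L <- length(ref_chars)
  while (position + 1L <= L &&
         ref_chars[position + 1L] == substr(alt, 1L, 1L)) {
    position <- position + 1L
    alt <- paste0(substring(alt, 2L), substring(alt, 1L, 1L))
  }
  list(position = position, alt = alt)
}

## Shift a deletion of `width` bases starting at `start` 3'-most: while the
## base following the deleted window equals the first deleted base, slide.
normalize_deletion <- function(start, width, ref_chars) {
  L <- length(ref_chars)
  while (start + width <= L && ref_chars[start + width] == ref_chars[start])
    start <- start + 1L
  start
}

#' Re-apply a variant profile to the reference
#'
#' Reconstructs the sample sequence implied by a profile. For
#' substitution-only profiles this inverts [call_variants()] exactly.
#'
#' @param profile a `variant_profile`.
#' @param ref a `mito_reference`.
#' @return nucleotide string.
#' @export
apply_variants <- function(profile, ref) {
  stopifnot(inherits(profile, "variant_profile"),
            inherits(ref, "mito_reference"))
  v <- profile$variants
  chars <- ref$chars
  subs <- v[v$vclass %in% c("transition", "transversion"), , drop = FALSE]
  if (nrow(subs)) {
    if (any(chars[subs$position] != subs$ref))
      stop("profile ref alleles disagree with the reference sequence")
    chars[subs$position] <- subs$alt
  }
  dels <- v$position[v$vclass == "deletion"]
  ins <- v[v$vclass == "insertion", , drop = FALSE]
  if (length(dels) || nrow(ins)) {
    pieces <- as.list(chars)
    for (i in seq_len(nrow(ins))) {
      p <- ins$position[i]
      if (p == 0L) pieces[[1L]] <- c(strsplit(ins$alt[i], "")[[1L]], pieces[[1L]])
      else pieces[[p]] <- c(pieces[[p]], strsplit(ins$alt[i], "")[[1L]])
    }
    if (length(dels)) for (p in dels) pieces[[p]] <- pieces[[p]][-1L]
    chars <- unlist(pieces)
  }
  paste(chars, collapse = "")
}

#' Default site mask
#'
#' Excludes the unreliable indels at positions 309, 315, 515-522 and 16,193,
#' the hotspots at 16,182, 16,183 and 16,519, and the allele-specific entries
#' 16182C and 16183C.
#'
#' @return object of class `site_mask` with components `excluded_positions`,
#'   `excluded_indel_positions` and `excluded_alleles`.
#' @export
default_site_mask <- function() {
  site_mask(excluded_positions = c(16182L, 16183L, 16519L),
            excluded_indel_positions = c(309L, 315L, 515:522, 16193L),
            excluded_alleles = data.frame(
              position = c(16182L, 16183L),
              allele = c("C", "C"), stringsAsFactors = FALSE))
}

#' Construct a site mask
#'
#' @param excluded_positions positions at which all variants are removed.
#' @param excluded_indel_positions positions at which insertions/deletions
#'   are removed.
#' @param excluded_alleles data.frame with columns `position`, `allele`;
#'   removes variants whose alternate allele matches at that position.
#' @return object of class `site_mask`.
#' @export
site_mask <- function(excluded_positions = integer(),
                      excluded_indel_positions = integer(),
                      excluded_alleles = NULL) {
  if (is.null(excluded_alleles))
    excluded_alleles <- data.frame(position = integer(), allele = character(),
                                   stringsAsFactors = FALSE)
  structure(list(excluded_positions = as.integer(excluded_positions),
                 excluded_indel_positions = as.integer(excluded_indel_positions),
                 excluded_alleles = excluded_alleles),
            class = "site_mask")
}

#' Read a site mask from a two-column TSV (kind, value)
#'
#' Rows with kind `position`, `indel` or `allele`; allele values are written
#' as `16182C`.
#' @param path TSV path.
#' @return a `site_mask`.
#' @export
read_site_mask <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "value") %in% names(tab)))
  al <- tab$value[tab$kind == "allele"]
  site_mask(
    excluded_positions = as.integer(tab$value[tab$kind == "position"]),
    excluded_indel_positions = as.integer(tab$value[tab$kind == "indel"]),
    excluded_alleles = data.frame(
      position = as.integer(sub("[A-Z-]+$", "", al)),
      allele = sub("^[0-9]+", "", al), stringsAsFactors = FALSE))
}

#' Apply a site mask to a variant profile
#'
#' Removes masked variants and counts them in `masked_removed`. Idempotent:
#' re-applying the same mask changes nothing.
#'
#' @param profile a `variant_profile`.
#' @param mask a `site_mask`; default [default_site_mask()].
#' @return the masked `variant_profile`.
#' @export
apply_mask <- function(profile, mask = default_site_mask()) {
  stopifnot(inherits(profile, "variant_profile"), inherits(mask, "site_mask"))
  v <- profile$variants
  if (!nrow(v)) return(profile)
  is_indel <- v$vclass %in% c("insertion", "deletion")
  drop <- v$position %in% mask$excluded_positions |
    (is_indel & v$position %in% mask$excluded_indel_positions) |
    paste0(v$position, ":", v$alt) %in%
      paste0(mask$excluded_alleles$position, ":", mask$excluded_alleles$allele)
  variant_profile(profile$sample_id, v[!drop, , drop = FALSE],
                  profile$region_label,
                  masked_removed = profile$masked_removed + sum(drop))
}

#' Call heteroplasmy from per-allele frequencies at one position
#'
#' A position is heteroplasmic when every allele with nonzero frequency lies
#' in the 31-70% band (both endpoints inclusive).
#'
#' @param allele_frequencies named numeric vector of allele fractions; must
#'   sum to 1 within `tol`.
#' @param lower,upper band endpoints (fractions), defaults 0.31 and 0.70.
#' @param tol tolerance on the frequency sum, default 1e-6.
#' @return logical scalar.
#' @export
call_heteroplasmy <- function(allele_frequencies, lower = 0.31, upper = 0.70,
                              tol = 1e-6) {
  f <- as.numeric(allele_frequencies)
  if (length(f) < 2L) stop("at least two alleles must be observed")
  if (any(f < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(f) - 1) > tol)
    stop("allele frequencies sum to ", sum(f), ", not 1")
  nz <- f[f > 0]
  all(nz >= lower & nz <= upper)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `region_label` and either `path`
#' (FASTA file per sample) or `name` (record name within a shared FASTA).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "region_label")
  if (!all(need %in% names(tab)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in sample sheet")
  tab
}

#' Write variant profiles to TSV
#'
#' One row per variant with columns `sample_id`, `position`, `ref`, `alt`,
#' `vclass`, `region`; rows ordered by sample then position.
#'
#' @param profiles list of `variant_profile`.
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_variant_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$variants)) return(NULL)
    cbind(sample_id = p$sample_id, p$variants, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      vclass = character(), region = character())
  out <- out[order(out$sample_id, out$position, out$alt), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
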