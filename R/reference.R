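## rCRS coordinate-system constants
MT_LENGTH <- 16569L
CODING_START <- 577L
CODING_END <- 16023L

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Assign mitochondrial region to rCRS positions
#'
#' The coding region spans positions 577 to 16,023; the control region is the
#' complement, wrapping the origin (16,024 to 16,569 and 1 to 576).
#'
#' @param position integer vector of 1-based rCRS positions.
#' @return character vector, `"coding"` or `"control"`.
#' @export
mito_region <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > MT_LENGTH))
    stop("positions must be in 1..", MT_LENGTH)
  ifelse(position >= CODING_START & position <= CODING_END, "coding", "control")
}

#' Construct a mitochondrial reference genome
#'
#' @param name reference name; when `"rCRS"` the sequence length must be
#'   exactly 16,569.
#' @param sequence nucleotide string (IUPAC alphabet); uppercased on input.
#' @param circular logical; mitogenomes are circular, so position arithmetic
#'   wraps modulo the length.
#' @return an object of class `mito_reference`.
#' @export
reference_genome <- function(name, sequence, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), IUPAC_CHARS)
  if (length(bad))
    stop("sequence contains non-IUPAC characters: ",
         paste(bad, collapse = ", "))
  if (identical(name, "rCRS") && length(chars) != MT_LENGTH)
    stop("a reference named 'rCRS' must be exactly ", MT_LENGTH,
         " bp, got ", length(chars))
  structure(list(name = name, sequence = sequence, circular = isTRUE(circular),
                 chars = chars, length = length(chars)),
            class = "mito_reference")
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("Mitochondrial reference '", x$name, "': ", x$length, " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

#' Load a reference genome from a single-record FASTA file
#'
#' @param path path to a FASTA file containing exactly one record.
#' @param name optional override of the record name (first word of the FASTA
#'   header is used by default).
#' @param circular logical, passed to [reference_genome()].
#' @return a `mito_reference`.
#' @export
load_reference <- function(path, name = NULL, circular = TRUE) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(recs))
  nm <- if (is.null(name)) strsplit(names(recs)[1L], "\\s+")[[1L]][1L] else name
  reference_genome(nm, as.character(recs[[1L]]), circular = circular)
}

#' Generate a synthetic rCRS-like reference sequence
#'
#' Produces a random 16,569-bp sequence carrying the rCRS coordinate system,
#' for simulation and testing. It is synthetic: it shares the length and
#' coordinate conventions of the rCRS, not its bases.
#'
#' @param seed integer seed for reproducibility.
#' @param base_frequencies stationary base frequencies (A, C, G, T) used to
#'   draw the sequence; defaults to human mtDNA-like composition.
#' @return a `mito_reference` named `"rCRS"` (synthetic bases).
#' @export
synthetic_rcrs <- function(seed = 1L,
                           base_frequencies = c(A = 0.309, C = 0.313,
                                                G = 0.131, T = 0.247)) {
  stopifnot(length(base_frequencies) == 4L)
  p <- base_frequencies / sum(base_frequencies)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  chars <- sample(c("A", "C", "G", "T"), MT_LENGTH, replace = TRUE, prob = p)
  reference_genome("rCRS", paste(chars, collapse = ""), circular = TRUE)
}

## Save/restore the global RNG state so helpers with their own seed do not
## disturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
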